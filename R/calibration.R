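# Iterative linear calibration loops. Both the mass axis (via the DAC count)
# and the mass resolution (via the OFFSET voltage) are corrected by the same
# first-order update
#     setting_m = setting_{m-1} + k * (target - measured_{m-1})
# which on a noiseless linear plant gives the error recurrence
#     e_m = (1 - k * slope) * e_{m-1},
# converging iff |1 - k * slope| < 1 and in a single step when k matches the
# inverse plant slope.

#' Calibration model
#'
#' @param coefficient Update gain `k` (setting units per u), or `NULL` to
#'   estimate it at startup by a two-point probe: perturb the setting by
#'   `probe_step`, measure, fit the local slope and invert it.
#' @param target Target value (u): the nominal peak mass for the mass axis,
#'   the desired FWHM (typically 0.7 u) for the resolution loop.
#' @param tolerance Termination tolerance (u), default 0.1.
#' @param max_iterations Maximum number of correction steps.
#' @param probe_step Setting perturbation used by the two-point probe.
#' @param n_average Measurements averaged per iteration (1 = single
#'   measurement per iteration, the default).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(coefficient = NULL, target = NULL,
                              tolerance = 0.1, max_iterations = 20L,
                              probe_step = NULL, n_average = 1L) {
  stopifnot(tolerance > 0, max_iterations >= 1, n_average >= 1)
  structure(
    list(coefficient = coefficient, target = target, tolerance = tolerance,
         max_iterations = as.integer(max_iterations),
         probe_step = probe_step, n_average = as.integer(n_average)),
    class = "calibration_model")
}

# Shared engine. `read` measures the controlled observable on the current
# instrument; `write` returns the instrument with the setting replaced.
calibrate_loop <- function(instrument, model, setting0, read, write, what) {
  avg_read <- function(inst) {
    mean(vapply(seq_len(model$n_average), function(j) read(inst), numeric(1L)))
  }
  k <- model$coefficient
  n_meas <- 0L
  if (is.null(k)) {
    # two-point probe: local slope of observable vs setting, inverted
    y0 <- avg_read(instrument)
    probed <- write(instrument, setting0 + model$probe_step)
    y1 <- avg_read(probed)
    slope <- (y1 - y0) / model$probe_step
    if (!is.finite(slope) || abs(slope) < 1e-12) {
      stop("two-point probe found no ", what, " response; cannot estimate ",
           "the calibration coefficient", call. = FALSE)
    }
    k <- 1 / slope
    instrument <- write(instrument, setting0)
    n_meas <- 2L * model$n_average
  }
  setting <- setting0
  history <- data.frame(iteration = integer(), setting = numeric(),
                        measured = numeric(), error = numeric())
  converged <- FALSE
  diverged <- FALSE
  grew <- 0L
  iterations <- 0L
  prev_abs <- Inf
  for (m in 0:model$max_iterations) {
    measured <- avg_read(instrument)
    err <- model$target - measured
    history <- rbind(history, data.frame(
      iteration = m, setting = setting, measured = measured, error = err))
    if (abs(err) <= model$tolerance) {
      converged <- TRUE
      iterations <- m
      break
    }
    grew <- if (abs(err) > prev_abs) grew + 1L else 0L
    prev_abs <- abs(err)
    if (grew >= 3L) {
      diverged <- TRUE
      iterations <- m
      break
    }
    if (m == model$max_iterations) {
      iterations <- m
      break
    }
    setting <- setting + k * err
    instrument <- write(instrument, setting)
  }
  structure(
    list(what = what, converged = converged, diverged = diverged,
         iterations = iterations, coefficient = k,
         measured = utils::tail(history$measured, 1L),
         setting = setting, history = history,
         n_measurements = n_meas + nrow(history) * model$n_average,
         instrument = instrument),
    class = "calibration_result")
}

#' Calibrate the mass axis of one peak via its DAC setting
#'
#' Iterates `DAC_m = DAC_{m-1} + k (mass_target - mass_{m-1})`, measuring the
#' centroid after every update, until the absolute mass error is within the
#' tolerance (0.1 u by default) or the iteration budget is exhausted.
#' Non-convergence and divergence (three consecutive error increases, the
#' signature of a sign-mismatched gain) are reported as status flags, not
#' errors, so an enclosing tuning loop can skip the candidate.
#'
#' @param instrument A [virtual_instrument()] (or any object supporting
#'   [measure_peak()] / [apply_settings()]).
#' @param peak Peak index.
#' @param model A [calibration_model()]; `target` defaults to the peak's
#'   nominal mass, `probe_step` to 8 DAC counts.
#' @return A `calibration_result`: `converged`, `diverged`, `iterations`
#'   (number of correction steps applied; 0 when the first measurement is
#'   already within tolerance), the gain `coefficient` used, the final
#'   `measured` value and `setting`, the iteration `history`, and the
#'   updated `instrument`.
#' @examples
#' vi <- virtual_instrument(noise_cv = 0)
#' res <- calibrate_mass_axis(vi, 1)
#' res$converged; res$measured
#' @export
calibrate_mass_axis <- function(instrument, peak = 1L,
                                model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.null(model$target)) model$target <- instrument$peaks$mass[peak]
  if (is.null(model$probe_step)) model$probe_step <- 8
  calibrate_loop(
    instrument, model,
    setting0 = instrument$peaks$dac[peak],
    read = function(inst) measure_peak(inst, peak)$centroid,
    write = function(inst, s) apply_settings(inst, peak, dac = s),
    what = "mass axis")
}

#' Calibrate the mass resolution of one peak via its OFFSET voltage
#'
#' Same first-order loop as [calibrate_mass_axis()] with the OFFSET voltage
#' as the setting and the FWHM as the observable; the default target
#' resolution is 0.7 u with termination tolerance 0.1 u.
#'
#' @inheritParams calibrate_mass_axis
#' @param model A [calibration_model()]; `target` defaults to 0.7 u,
#'   `probe_step` to 0.5 V.
#' @return A `calibration_result` (see [calibrate_mass_axis()]).
#' @export
calibrate_resolution <- function(instrument, peak = 1L,
                                 model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.null(model$target)) model$target <- 0.7
  if (is.null(model$probe_step)) model$probe_step <- 0.5
  calibrate_loop(
    instrument, model,
    setting0 = instrument$peaks$offset[peak],
    read = function(inst) measure_peak(inst, peak)$fwhm,
    write = function(inst, s) apply_settings(inst, peak, offset = s),
    what = "resolution")
}

#' @export
print.calibration_result <- function(x, ...) {
  status <- if (x$converged) "converged" else if (x$diverged) "DIVERGED"
            else "not converged"
  cat(sprintf("<calibration %s  %s in %d step(s)  measured = %.4f>\n",
              x$what, status, x$iterations, x$measured))
  invisible(x)
}

#' Write a calibration history as CSV
#'
#' One row per iteration: iteration index, setting, measured value, error.
#'
#' @param result A `calibration_result`.
#' @param file Output path.
#' @export
write_calibration_csv <- function(result, file) {
  utils::write.csv(result$history, file, row.names = FALSE)
  invisible(result$history)
}
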