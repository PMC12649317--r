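# Automatic tuning orchestrator: the reciprocal-intensity evaluation
# function, the univariate-search baseline, optimizer-in-the-loop tuning
# with embedded mass-axis/resolution calibration, and repeatability
# reporting.

#' Multi-objective evaluation specification
#'
#' @param peaks Indices of the instrument peaks entering the objective.
#' @param weights Per-peak weight coefficients, default `1e6` each.
#' @param floor Intensity floor (cps) guarding the reciprocal against
#'   division by zero.
#' @return An object of class `evaluation_spec`.
#' @export
evaluation_spec <- function(peaks = NULL, weights = NULL, floor = 1) {
  stopifnot(floor > 0)
  if (!is.null(weights)) stopifnot(all(weights > 0))
  structure(list(peaks = peaks, weights = weights, floor = floor),
            class = "evaluation_spec")
}

# Resolve defaults against a concrete instrument.
resolve_eval_spec <- function(spec, instrument) {
  if (is.null(spec$peaks)) spec$peaks <- seq_len(nrow(instrument$peaks))
  if (is.null(spec$weights)) spec$weights <- rep(1e6, length(spec$peaks))
  stopifnot(length(spec$weights) == length(spec$peaks))
  spec
}

#' Weighted reciprocal-intensity fitness
#'
#' Computes `f = sum_k lambda_k / max(I_k, floor)`; lower is better, so
#' maximizing every peak intensity minimizes `f`. With a single peak this
#' reduces to `lambda / I`. Doubling every intensity halves the fitness.
#'
#' @param intensities Non-negative intensities (cps), one per peak.
#' @param weights Weight coefficients `lambda_k`, default `1e6` each.
#' @param floor Intensity floor (cps).
#' @return The fitness value.
#' @examples
#' evaluation_function(c(1e6, 1e6, 1e6))  # 3
#' @export
evaluation_function <- function(intensities,
                                weights = rep(1e6, length(intensities)),
                                floor = 1) {
  if (any(intensities < 0)) stop("negative intensity", call. = FALSE)
  stopifnot(length(weights) == length(intensities))
  sum(weights / pmax(intensities, floor))
}

# Measure one candidate parameter set: clip to bounds, drive the instrument,
# optionally calibrate each peak (mass axis then resolution), then measure
# all peaks and score them. Returns the updated instrument so calibrated
# DAC/OFFSET settings persist across candidates. `counter` is an environment
# with a numeric `n` accumulating instrument measurements.
measure_candidate <- function(instrument, params, spec,
                              calibrate = TRUE, counter = NULL) {
  p <- instrument$parameters
  params <- clip_to_bounds(params, p$lower, p$upper)
  names(params) <- p$name
  instrument <- set_parameters(instrument, params)
  ok <- TRUE
  if (calibrate) {
    for (k in spec$peaks) {
      res_m <- calibrate_mass_axis(instrument, k)
      instrument <- res_m$instrument
      res_r <- calibrate_resolution(instrument, k)
      instrument <- res_r$instrument
      if (!is.null(counter)) {
        counter$n <- counter$n + res_m$n_measurements + res_r$n_measurements
      }
      if (!res_m$converged || !res_r$converged) ok <- FALSE
    }
  }
  meas <- lapply(spec$peaks, function(k) measure_peak(instrument, k))
  if (!is.null(counter)) counter$n <- counter$n + length(meas)
  fitness <- if (ok) {
    evaluation_function(vapply(meas, `[[`, numeric(1L), "intensity"),
                        spec$weights, spec$floor)
  } else Inf
  list(instrument = instrument, fitness = fitness, measurements = meas,
       calibration_ok = ok)
}

peaks_table <- function(measurements) {
  data.frame(
    mass = vapply(measurements, `[[`, numeric(1L), "mass"),
    intensity = vapply(measurements, `[[`, numeric(1L), "intensity"),
    fwhm = vapply(measurements, `[[`, numeric(1L), "fwhm"),
    mass_error = vapply(measurements, `[[`, numeric(1L), "mass_error"))
}

new_tuning_result <- function(method, par, fitness, measurements, history,
                              evaluations, n_measurements, failures = 0L) {
  structure(
    list(method = method, par = par, fitness = fitness,
         peaks = peaks_table(measurements), history = history,
         evaluations = evaluations, n_measurements = n_measurements,
         calibration_failures = failures),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result %s  fitness = %.6g  evaluations = %d>\n",
              x$method, x$fitness, x$evaluations))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = "; "), "\n")
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Univariate-search tuning baseline
#'
#' The traditional one-parameter-at-a-time procedure: for each parameter in
#' turn, evaluate `levels` uniformly spaced values across its feasible
#' interval (endpoints included) with all other parameters held at their
#' current values, lock in the best level, and move on. One pass over the
#' parameters; no interactions are explored.
#'
#' @param instrument A [virtual_instrument()].
#' @param levels Number of grid levels per parameter (default 10).
#' @param order Parameter optimization order; defaults to GS1, CUR, DP, EP
#'   (parameters absent from the instrument are skipped, extra instrument
#'   parameters are appended in declaration order).
#' @param spec An [evaluation_spec()].
#' @param calibrate Calibrate mass axis and resolution for every candidate.
#' @param start Named starting values; defaults to the range mid-points.
#' @param seed Optional seed for the measurement noise stream.
#' @return A `tuning_result`.
#' @export
univariate_search <- function(instrument, levels = 10L,
                              order = c("GS1", "CUR", "DP", "EP"),
                              spec = evaluation_spec(),
                              calibrate = TRUE, start = NULL, seed = NULL) {
  stopifnot(levels >= 2)
  if (!is.null(seed)) set.seed(seed)
  spec <- resolve_eval_spec(spec, instrument)
  p <- instrument$parameters
  order <- c(intersect(order, p$name), setdiff(p$name, order))
  current <- if (is.null(start)) {
    stats::setNames((p$lower + p$upper) / 2, p$name)
  } else {
    stats::setNames(start[p$name], p$name)
  }
  counter <- new.env()
  counter$n <- 0
  evals <- 0L
  history <- numeric(0)
  best_f <- Inf
  for (nm in order) {
    j <- match(nm, p$name)
    grid <- seq(p$lower[j], p$upper[j], length.out = levels)
    level_f <- numeric(levels)
    for (l in seq_len(levels)) {
      cand <- current
      cand[nm] <- grid[l]
      out <- measure_candidate(instrument, cand, spec, calibrate, counter)
      instrument <- out$instrument
      level_f[l] <- out$fitness
      evals <- evals + 1L
      best_f <- min(best_f, out$fitness)
      history <- c(history, best_f)
    }
    current[nm] <- grid[which.min(level_f)]
  }
  final <- measure_candidate(instrument, current, spec, calibrate, counter)
  new_tuning_result("univariate", current, final$fitness, final$measurements,
                    history, evals, counter$n)
}

#' Automatic tuning with an optimizer in the loop
#'
#' For every candidate parameter vector proposed by the optimizer the
#' instrument is driven to the (bound-clipped) candidate, the mass axis and
#' resolution of every evaluated peak are calibrated, the peak intensities
#' are measured, and the weighted reciprocal-intensity fitness is returned
#' to the optimizer. A candidate whose calibration fails receives infinite
#' fitness and is logged. After the final generation the best candidate is
#' re-applied, re-calibrated and re-measured for the report.
#'
#' @param instrument A [virtual_instrument()].
#' @param config An [optimizer_config()] whose dimension matches the number
#'   of instrument parameters (bounds are taken from the instrument when the
#'   config is built with [tuning_optimizer_config()]).
#' @param spec An [evaluation_spec()].
#' @param calibrate_every `"candidate"` re-runs both calibration loops for
#'   every candidate (default); `"generation"` calibrates only on the first
#'   candidate of each population sweep, an economy mode for plants whose
#'   peak positions do not drift with the tuning parameters.
#' @param seed Master seed for the whole run (optimizer draws and instrument
#'   noise share one stream).
#' @return A `tuning_result`: optimized parameters, per-peak intensity /
#'   FWHM / mass error, the optimizer's best-so-far fitness history, the
#'   number of candidate evaluations and of instrument measurements, and the
#'   count of calibration failures.
#' @examples
#' vi <- virtual_instrument(noise_cv = 0)
#' cfg <- tuning_optimizer_config(vi, strategy = "de_improved", G = 5)
#' autotune(vi, cfg, seed = 1)
#' @export
autotune <- function(instrument, config, spec = evaluation_spec(),
                     calibrate_every = c("candidate", "generation"),
                     seed = NULL) {
  calibrate_every <- match.arg(calibrate_every)
  spec <- resolve_eval_spec(spec, instrument)
  p <- instrument$parameters
  if (config$D != nrow(p)) {
    stop("optimizer dimension (", config$D, ") does not match the number of ",
         "instrument parameters (", nrow(p), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL  # one shared stream for optimizer and plant noise
  env <- new.env()
  env$instrument <- instrument
  env$counter <- new.env()
  env$counter$n <- 0
  env$calls <- 0L
  env$failures <- 0L
  objective <- function(x) {
    calibrate <- calibrate_every == "candidate" ||
      env$calls %% config$N == 0L
    out <- measure_candidate(env$instrument, x, spec, calibrate, env$counter)
    env$instrument <- out$instrument
    env$calls <- env$calls + 1L
    if (!out$calibration_ok) env$failures <- env$failures + 1L
    out$fitness
  }
  res <- run_optimizer(objective, config)
  final <- measure_candidate(env$instrument, res$par, spec,
                             calibrate = TRUE, counter = env$counter)
  new_tuning_result(config$strategy, stats::setNames(res$par, p$name),
                    final$fitness, final$measurements, res$curve,
                    res$evaluations, env$counter$n, env$failures)
}

#' Build an optimizer configuration over an instrument's parameter space
#'
#' Convenience wrapper around [optimizer_config()] taking dimension and
#' bounds from the instrument's parameter table.
#'
#' @param instrument A [virtual_instrument()].
#' @param ... Passed to [optimizer_config()].
#' @return An `optimizer_config`.
#' @export
tuning_optimizer_config <- function(instrument, ...) {
  p <- instrument$parameters
  optimizer_config(D = nrow(p), lower = p$lower, upper = p$upper, ...)
}

#' Repeatability report over repeated tuning runs
#'
#' Summarizes the final per-peak intensities of several independent tuning
#' runs: mean, sample standard deviation (n - 1 denominator) and the
#' coefficient of variation in percent.
#'
#' @param results List of `tuning_result` objects (at least 2).
#' @return Data frame with columns `mass`, `n`, `mean_intensity`,
#'   `sd_intensity`, `cv_percent`.
#' @export
repeatability_report <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1L), "tuning_result")))
  masses <- results[[1L]]$peaks$mass
  mat <- vapply(results, function(r) r$peaks$intensity,
                numeric(length(masses)))
  mat <- matrix(mat, nrow = length(masses))
  means <- rowMeans(mat)
  if (any(means == 0)) stop("zero mean intensity for at least one peak",
                            call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  data.frame(mass = masses, n = length(results), mean_intensity = means,
             sd_intensity = sds, cv_percent = 100 * sds / means)
}
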