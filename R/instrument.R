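# Virtual quadrupole mass spectrometer. The intensity response over the
# tuning parameters is a synthetic stand-in for the physical instrument: a
# (optionally correlated) Gaussian bump with a known optimum, so ground truth
# is available for parameter-recovery tests. Peak position follows a linear
# mass-DAC model and peak width a linear FWHM-OFFSET model, both with
# invented factory tables; detector noise is multiplicative.

#' Create a virtual quadrupole mass spectrometer
#'
#' The simulated plant exposes the same observables a real instrument reports
#' during tuning: per-peak centroid mass, FWHM and MCA-accumulated intensity.
#'
#' The single-scan intensity of peak \eqn{k} at tuning parameters \eqn{p} is
#' \deqn{I_k(p) = I_{max,k} \exp(-\tfrac12 u^\top C^{-1} u) (1 + \epsilon)}
#' where \eqn{u_j = (p_j - p^*_j)/\sigma_j} is the normalized deviation from
#' the ground-truth optimum, \eqn{C} is the identity in separable mode or
#' carries a correlation `interaction_rho` between the two parameters named
#' in `interaction_pair` (default DP and EP) in interaction mode, and
#' \eqn{\epsilon} is zero-mean Gaussian with standard deviation `noise_cv`
#' (negative intensities clip to 0). Interaction mode is the default: it is
#' the regime where one-parameter-at-a-time search is provably suboptimal and
#' population optimizers can do better.
#'
#' The measured centroid of peak \eqn{k} is the inverse of the true linear
#' mass-DAC table at the current DAC setting,
#' `(dac - dac_intercept) / dac_slope`, and the measured FWHM is the true
#' linear function of the current OFFSET, `fwhm_intercept + fwhm_slope *
#' offset` (floored at 0.05 u). With `noise_cv = 0` every observable is
#' deterministic; otherwise centroid and FWHM carry a small Gaussian
#' measurement error with standard deviation `0.15 * noise_cv` u.
#'
#' @param parameters Data frame with columns `name`, `lower`, `upper`, `opt`
#'   (ground-truth optimum, strictly inside the bounds) and `sigma`
#'   (sensitivity width, same units as the parameter). The default describes
#'   the four Q1-mode tuning parameters: curtain gas CUR, nebulizer gas GS1,
#'   de-clustering voltage DP and entrance voltage EP.
#' @param peaks Data frame with columns `mass` (u), `imax` (single-scan peak
#'   intensity at the optimum, cps), `dac_slope`/`dac_intercept` (true DAC
#'   counts per u and offset of the mass-DAC table), `fwhm_slope`/
#'   `fwhm_intercept` (u per volt and u), `dac` and `offset` (current
#'   settings). The default holds the three NaI/CsI calibrant peaks at m/z
#'   172.88, 622.57 and 922.36, with initial settings deliberately
#'   mis-calibrated (mass errors of about 0.1 u, widths of 0.8-1.9 u).
#' @param noise_cv Coefficient of variation of the multiplicative intensity
#'   noise. Default 0.06.
#' @param mca Number of accumulated scans per measurement (multiple channel
#'   acquisition). Default 5.
#' @param interaction Logical; correlate the `interaction_pair` parameters in
#'   the response surface (default `TRUE`).
#' @param interaction_rho Correlation coefficient in interaction mode.
#' @param interaction_pair Character vector of the two interacting parameter
#'   names.
#' @return An object of class `virtual_instrument`. Current tuning-parameter
#'   settings start at the mid-point of each range.
#' @examples
#' vi <- virtual_instrument(noise_cv = 0)
#' measure_peak(vi, 1)
#' @export
virtual_instrument <- function(parameters = default_parameters(),
                               peaks = default_peaks(),
                               noise_cv = 0.06, mca = 5L,
                               interaction = TRUE, interaction_rho = 0.6,
                               interaction_pair = c("DP", "EP")) {
  req <- c("name", "lower", "upper", "opt", "sigma")
  stopifnot(is.data.frame(parameters), all(req %in% names(parameters)))
  reqp <- c("mass", "imax", "dac_slope", "dac_intercept",
            "fwhm_slope", "fwhm_intercept", "dac", "offset")
  stopifnot(is.data.frame(peaks), all(reqp %in% names(peaks)))
  stopifnot(all(parameters$lower < parameters$opt),
            all(parameters$opt < parameters$upper),
            all(parameters$sigma > 0),
            all(peaks$imax > 0),
            noise_cv >= 0, mca >= 1)
  if (interaction && !all(interaction_pair %in% parameters$name)) {
    stop("interaction_pair names not found among the instrument parameters",
         call. = FALSE)
  }
  settings <- (parameters$lower + parameters$upper) / 2
  names(settings) <- parameters$name
  structure(
    list(parameters = parameters, peaks = peaks,
         settings = settings,
         noise_cv = noise_cv, mca = as.integer(mca),
         interaction = isTRUE(interaction),
         interaction_rho = interaction_rho,
         interaction_pair = interaction_pair),
    class = "virtual_instrument")
}

#' @rdname virtual_instrument
#' @export
default_parameters <- function() {
  data.frame(
    name  = c("CUR", "GS1", "DP", "EP"),
    lower = c(5,     5,     50,   2),
    upper = c(40,    40,    200,  15),
    opt   = c(20,    16,    160,  11),
    sigma = c(8.75,  8.75,  37.5, 3.25))
}

#' @rdname virtual_instrument
#' @export
default_peaks <- function() {
  masses <- c(172.88, 622.57, 922.36)
  dac_slope <- 32          # counts per u
  dac_intercept <- 500
  init_mass_err <- c(0.103, 0.15, -0.12)
  fwhm_slope <- 0.35       # u per volt
  fwhm_intercept <- 0.675
  init_offset <- c(0.4, 1.8, 3.6)
  data.frame(
    mass = masses,
    imax = c(5.6e6, 5.2e6, 1.6e6),
    dac_slope = dac_slope,
    dac_intercept = dac_intercept,
    fwhm_slope = fwhm_slope,
    fwhm_intercept = fwhm_intercept,
    dac = dac_intercept + dac_slope * (masses + init_mass_err),
    offset = init_offset)
}

#' @export
print.virtual_instrument <- function(x, ...) {
  cat(sprintf(
    "<virtual_instrument  %d parameters, %d peaks, CV = %g, MCA = %d, %s>\n",
    nrow(x$parameters), nrow(x$peaks), x$noise_cv, x$mca,
    if (x$interaction) "interaction surface" else "separable surface"))
  invisible(x)
}

#' Set tuning parameters on a virtual instrument
#'
#' @param instrument A [virtual_instrument()].
#' @param params Named numeric vector; names must match instrument
#'   parameters. Unnamed vectors of full length are matched positionally.
#' @return The updated instrument.
#' @export
set_parameters <- function(instrument, params) {
  stopifnot(inherits(instrument, "virtual_instrument"))
  nm <- instrument$parameters$name
  if (is.null(names(params))) {
    stopifnot(length(params) == length(nm))
    names(params) <- nm
  }
  unknown <- setdiff(names(params), nm)
  if (length(unknown)) {
    stop("unknown tuning parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  instrument$settings[names(params)] <- params
  instrument
}

#' Apply per-peak DAC and OFFSET settings
#'
#' Stores the mass-axis DAC count and the resolution OFFSET voltage for one
#' peak; other peaks are unaffected.
#'
#' @param instrument A [virtual_instrument()].
#' @param peak Peak index.
#' @param dac New DAC setting, or `NULL` to keep the current one.
#' @param offset New OFFSET setting, or `NULL` to keep the current one.
#' @return The updated instrument.
#' @export
apply_settings <- function(instrument, peak, dac = NULL, offset = NULL) {
  stopifnot(inherits(instrument, "virtual_instrument"),
            peak >= 1, peak <= nrow(instrument$peaks))
  if (!is.null(dac)) {
    stopifnot(is.finite(dac))
    instrument$peaks$dac[peak] <- dac
  }
  if (!is.null(offset)) {
    stopifnot(is.finite(offset))
    instrument$peaks$offset[peak] <- offset
  }
  instrument
}

# Quadratic form of the normalized deviation under the configured surface.
response_exponent <- function(instrument, params) {
  p <- instrument$parameters
  u <- (params[p$name] - p$opt) / p$sigma
  q <- sum(u^2)
  if (instrument$interaction) {
    pair <- match(instrument$interaction_pair, p$name)
    rho <- instrument$interaction_rho
    a <- u[pair[1L]]; b <- u[pair[2L]]
    q <- q - (a^2 + b^2) + (a^2 - 2 * rho * a * b + b^2) / (1 - rho^2)
  }
  -q / 2
}

#' Single-scan peak intensity at given tuning parameters
#'
#' Evaluates the ground-truth response surface for one peak and applies one
#' multiplicative noise draw. Deterministic when the instrument's
#' `noise_cv` is 0. Out-of-bounds parameters are an error (the plant cannot
#' be driven outside its feasible region).
#'
#' @param instrument A [virtual_instrument()].
#' @param params Named parameter vector (defaults to the current settings).
#' @param peak Peak index.
#' @return Intensity in cps (non-negative).
#' @export
peak_intensity_response <- function(instrument,
                                    params = instrument$settings,
                                    peak = 1L) {
  stopifnot(inherits(instrument, "virtual_instrument"))
  p <- instrument$parameters
  if (is.null(names(params))) {
    stopifnot(length(params) == nrow(p))
    names(params) <- p$name
  }
  vals <- params[p$name]
  if (any(!is.finite(vals)) || any(vals < p$lower) || any(vals > p$upper)) {
    bad <- p$name[!is.finite(vals) | vals < p$lower | vals > p$upper]
    stop("parameter(s) out of bounds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base <- instrument$peaks$imax[peak] * exp(response_exponent(instrument, vals))
  eps <- if (instrument$noise_cv > 0) {
    stats::rnorm(1L, 0, instrument$noise_cv)
  } else 0
  max(base * (1 + eps), 0)
}

#' Measure one mass spectral peak
#'
#' Reports what the acquisition software would report after one MCA-
#' accumulated acquisition: the peak centroid from the current DAC setting
#' through the inverted mass-DAC table, the FWHM from the current OFFSET
#' through the FWHM-OFFSET table, and the intensity as the sum of `mca`
#' independent single-scan draws of the response surface at the current
#' tuning parameters. Draw order per measurement: centroid error, FWHM
#' error, then the `mca` intensity draws.
#'
#' @param instrument A [virtual_instrument()].
#' @param peak Peak index.
#' @return An object of class `peak_measurement`: `mass` (nominal, u),
#'   `centroid` (u), `mass_error` (centroid - nominal, u), `fwhm` (u),
#'   `intensity` (cps).
#' @export
measure_peak <- function(instrument, peak = 1L) {
  stopifnot(inherits(instrument, "virtual_instrument"),
            peak >= 1, peak <= nrow(instrument$peaks))
  pk <- instrument$peaks[peak, ]
  meas_sd <- 0.15 * instrument$noise_cv
  centroid <- (pk$dac - pk$dac_intercept) / pk$dac_slope
  fwhm <- pk$fwhm_intercept + pk$fwhm_slope * pk$offset
  if (meas_sd > 0) {
    centroid <- centroid + stats::rnorm(1L, 0, meas_sd)
    fwhm <- fwhm + stats::rnorm(1L, 0, meas_sd)
  }
  fwhm <- max(fwhm, 0.05)
  intensity <- sum(vapply(seq_len(instrument$mca), function(s) {
    peak_intensity_response(instrument, instrument$settings, peak)
  }, numeric(1L)))
  structure(
    list(mass = pk$mass, centroid = centroid,
         mass_error = centroid - pk$mass,
         fwhm = fwhm, intensity = intensity),
    class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf(
    "<peak m/z %.2f  centroid %.3f (err %+.3f u)  FWHM %.3f u  I = %.4g cps>\n",
    x$mass, x$centroid, x$mass_error, x$fwhm, x$intensity))
  invisible(x)
}

#' Render a peak profile as a continuous spectrum
#'
#' Produces a Gaussian profile centred at the measured centroid whose width
#' matches the measured FWHM (`sigma = FWHM / (2 sqrt(2 ln 2))`) and whose
#' area equals the measured intensity, on a regular m/z grid spanning
#' `half_width` u either side of the centroid.
#'
#' @param instrument A [virtual_instrument()].
#' @param peak Peak index.
#' @param half_width Half-width of the rendered window (u).
#' @param points Number of grid points.
#' @return Data frame with columns `mz` and `intensity` (density, cps per u).
#' @export
render_spectrum <- function(instrument, peak = 1L, half_width = 3,
                            points = 601L) {
  m <- measure_peak(instrument, peak)
  sigma <- m$fwhm / (2 * sqrt(2 * log(2)))
  mz <- seq(m$centroid - half_width, m$centroid + half_width,
            length.out = points)
  data.frame(mz = mz,
             intensity = m$intensity * stats::dnorm(mz, m$centroid, sigma))
}

#' Write a rendered spectrum as two-column text
#'
#' @param spectrum Data frame from [render_spectrum()].
#' @param file Output path; format is whitespace-separated `m/z intensity`.
#' @export
write_spectrum <- function(spectrum, file) {
  utils::write.table(spectrum, file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(spectrum)
}
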