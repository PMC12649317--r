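test_that("the response surface peaks at the ground-truth optimum", {
  vi <- quiet_instrument(interaction = FALSE)
  p <- vi$parameters
  opt <- setNames(p$opt, p$name)
  expect_equal(peak_intensity_response(vi, opt, 1), vi$peaks$imax[1])
  # one-sigma displacement in a single coordinate: exp(-1/2) of the maximum
  for (j in seq_len(nrow(p))) {
    shifted <- opt
    shifted[j] <- shifted[j] + p$sigma[j]
    expect_equal(peak_intensity_response(vi, shifted, 1),
                 vi$peaks$imax[1] * exp(-1 / 2))
  }
})

test_that("moving any single parameter away from the optimum never helps", {
  for (mode in c(TRUE, FALSE)) {
    vi <- quiet_instrument(interaction = mode)
    p <- vi$parameters
    opt <- setNames(p$opt, p$name)
    for (j in seq_len(nrow(p))) {
      for (dir in c(-1, 1)) {
        steps <- seq(0, 1, length.out = 9)
        lim <- if (dir > 0) p$upper[j] else p$lower[j]
        vals <- sapply(steps, function(s) {
          x <- opt
          x[j] <- opt[j] + s * (lim - opt[j])
          peak_intensity_response(vi, x, 1)
        })
        expect_true(all(diff(vals) <= 1e-12))
      }
    }
  }
})

test_that("a 21-point grid locates the optimum within one grid step", {
  for (mode in c(FALSE, TRUE)) {
    vi <- tiny_instrument(interaction = mode)
    g <- seq(0, 9, length.out = 21)
    step <- diff(g)[1]
    resp <- outer(g, g, Vectorize(function(a, b)
      peak_intensity_response(vi, c(A = a, B = b), 1)))
    hit <- which(resp == max(resp), arr.ind = TRUE)
    expect_lte(abs(g[hit[1]] - 3), step)
    expect_lte(abs(g[hit[2]] - 7), step)
  }
})

test_that("intensity noise follows the configured CV", {
  vi <- virtual_instrument(noise_cv = 0.06, mca = 1L)
  p <- vi$parameters
  opt <- setNames(p$opt, p$name)
  set.seed(10)
  draws <- replicate(1e4, peak_intensity_response(vi, opt, 1))
  cv <- sd(draws) / mean(draws)
  expect_lt(abs(cv - 0.06) / 0.06, 0.1)
})

test_that("out-of-bounds parameters are refused", {
  vi <- quiet_instrument()
  bad <- setNames(vi$parameters$opt, vi$parameters$name)
  bad["CUR"] <- 1000
  expect_error(peak_intensity_response(vi, bad, 1), "CUR")
})

test_that("measurement combines the DAC, OFFSET and MCA models", {
  vi <- quiet_instrument()
  pk <- vi$peaks[1, ]
  m <- measure_peak(vi, 1)
  expect_equal(m$centroid, (pk$dac - pk$dac_intercept) / pk$dac_slope)
  expect_equal(m$fwhm, pk$fwhm_intercept + pk$fwhm_slope * pk$offset)
  # DAC set exactly on the true line: zero mass error
  vi0 <- apply_settings(vi, 1,
                        dac = pk$dac_intercept + pk$dac_slope * pk$mass)
  expect_equal(measure_peak(vi0, 1)$mass_error, 0)
  # noiseless MCA accumulation is exactly mca times one scan
  one <- peak_intensity_response(vi, peak = 1)
  expect_equal(m$intensity, vi$mca * one)
})

test_that("per-peak settings are isolated and read back", {
  vi <- quiet_instrument()
  before2 <- measure_peak(vi, 2)
  vi2 <- apply_settings(vi, 1, dac = 1234.5, offset = 0.9)
  expect_equal(vi2$peaks$dac[1], 1234.5)
  expect_equal(vi2$peaks$offset[1], 0.9)
  after2 <- measure_peak(vi2, 2)
  expect_identical(before2, after2)
  # positive configured slope: larger OFFSET widens the peak
  wider <- apply_settings(vi, 1, offset = vi$peaks$offset[1] + 1)
  expect_gt(measure_peak(wider, 1)$fwhm, measure_peak(vi, 1)$fwhm)
})

test_that("rendered profiles have the measured FWHM and integrate to intensity", {
  vi <- quiet_instrument()
  m <- measure_peak(vi, 1)
  sp <- render_spectrum(vi, 1, half_width = 4, points = 2001)
  # closed form: the profile at centroid +/- FWHM/2 is half the apex
  apex <- m$intensity * dnorm(0, 0, m$fwhm / (2 * sqrt(2 * log(2))))
  at_half <- approx(sp$mz, sp$intensity, m$centroid + m$fwhm / 2)$y
  expect_equal(at_half / apex, 0.5, tolerance = 1e-4)
  sigma <- m$fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(dnorm(sigma * sqrt(2 * log(2)), 0, sigma) / dnorm(0, 0, sigma),
               0.5, tolerance = 1e-9)
  # trapezoid integral within 1% of the measured intensity
  area <- sum(diff(sp$mz) * (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  expect_lt(abs(area - m$intensity) / m$intensity, 0.01)
  # two-column text export round-trips
  f <- tempfile()
  write_spectrum(sp, f)
  back <- read.table(f)
  expect_equal(back[[1]], sp$mz)
  expect_equal(back[[2]], sp$intensity)
  unlink(f)
})

test_that("zero-noise instruments are deterministic", {
  vi <- quiet_instrument()
  expect_identical(measure_peak(vi, 3), measure_peak(vi, 3))
})
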