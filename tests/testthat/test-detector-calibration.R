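test_that("Gaussian peak fitting recovers noiseless and noisy centroids", {
  ch <- 1:256
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  clean <- 50 + 2000 * exp(-(ch - 112)^2 / (2 * sigma^2))
  pf <- fit_peak(clean, 90:135)
  expect_equal(pf$centroid, 112, tolerance = 1e-8)
  expect_equal(pf$fwhm, 5, tolerance = 1e-6)
  expect_equal(pf$background, 50, tolerance = 1e-4)

  # Poisson noise at 1e5 peak counts: centroid lands within 0.05 channels
  # (repeat fits across seeds stay well inside; statistical error is
  # ~fwhm / (2.355 sqrt(N)) ~ 0.007 channels)
  strong <- 20 + 1e5 * exp(-(ch - 112)^2 / (2 * sigma^2))
  errs <- vapply(1:5, function(s) {
    noisy <- kedge:::with_seed(s, stats::rpois(256, strong))
    fit_peak(noisy, 90:135)$centroid - 112
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)

  expect_error(fit_peak(rep(7, 256), 90:135), "flat")
  expect_error(fit_peak(ch * 0.5, 90:135), "local maximum")  # monotone ramp
})

test_that("energy calibration line recovers gain and offset, flags outliers", {
  # two-point line: centroids 1 and 101 (channels 0 and 100 from the first)
  cal <- fit_energy_calibration(c(1, 101), c(5.0, 30.0))
  expect_equal(cal$gain, 0.25, tolerance = 1e-12)
  expect_equal(cal$offset, 5.0, tolerance = 1e-12)

  # collinear points: zero residuals
  cal3 <- fit_energy_calibration(c(1, 51, 101), c(5.0, 17.5, 30.0))
  expect_lt(max(abs(cal3$report$residual_kev)), 1e-12)

  # noiseless synthetic peaks through the full pipeline: <= 1e-9 relative
  ax <- energy_axis(256, 0.25, 5)
  peaks <- c(13.95, 26.35, 59.54)
  sim <- simulate_calibration_spectra(peaks, ax, detector = detector_model(1.0),
                                      poisson = FALSE)
  cents <- vapply(peaks, function(e) {
    k <- energy_to_channel(ax, e)
    fit_peak(sim$counts[1, ], (k - 15):(k + 15))$centroid
  }, numeric(1))
  cal_n <- fit_energy_calibration(cents, peaks)
  expect_equal(cal_n$gain, 0.25, tolerance = 1e-9)
  expect_equal(cal_n$offset, 5, tolerance = 1e-9)

  # centroid jitter sigma = 0.02 ch: gain recovered within 0.1%
  true_ch <- (peaks - 5) / 0.25 + 1
  many <- c(true_ch, (c(10, 35, 48) - 5) / 0.25 + 1)
  jit <- kedge:::with_seed(99, stats::rnorm(length(many), sd = 0.02))
  cal_j <- fit_energy_calibration(many + jit, c(peaks, 10, 35, 48))
  expect_lt(abs(cal_j$gain - 0.25) / 0.25, 0.001)

  # a grossly wrong peak is flagged and excluded
  cal_o <- fit_energy_calibration(c(true_ch, 150), c(peaks, 20))
  expect_true(cal_o$report$outlier[4])
  expect_equal(cal_o$gain, 0.25, tolerance = 1e-9)

  expect_error(fit_energy_calibration(1, 5), "at least 2")
  expect_error(fit_energy_calibration(c(50, 50), c(5, 6)), "distinct")

  expect_s3_class(tidy(cal3), "tbl_df")
  expect_equal(glance(cal_o)$n_outliers, 1)
})

test_that("resolution map recovers injected FWHM distributions and flags dead pixels", {
  ax <- energy_axis(256, 0.25, 5)
  # uniform noiseless 1.27 keV: mean exact, SD 0
  simu <- simulate_calibration_spectra(59.5, ax, n_pixels = 4,
                                       detector = detector_model(1.27),
                                       poisson = FALSE)
  rm_u <- resolution_map(simu$counts, ax)
  expect_equal(rm_u$mean_fwhm_kev, 1.27, tolerance = 1e-4)
  expect_equal(rm_u$sd_fwhm_kev, 0, tolerance = 1e-4)

  # per-pixel FWHM ~ uniform[0.8, 1.8] keV at 1e6 counts: mean within 2%
  n_px <- 24
  fw <- kedge:::with_seed(21, stats::runif(n_px, 0.8, 1.8))
  simr <- simulate_calibration_spectra(
    59.5, ax, n_pixels = n_px, counts_per_peak = 1e6, fwhm_kev = fw,
    detector = detector_model(seed = 22))
  rm_r <- resolution_map(simr$counts, ax)
  expect_equal(rm_r$n_failed, 0)
  expect_lt(abs(rm_r$mean_fwhm_kev - mean(fw)) / mean(fw), 0.02)

  # dead pixel (flat spectrum) is excluded and counted
  dead <- rbind(simu$counts, 0)
  rm_d <- resolution_map(dead, ax)
  expect_equal(rm_d$n_failed, 1)
  expect_false(rm_d$per_pixel$ok[5])
})

test_that("inter-pixel gain correction aligns spectra, conserves counts, is idempotent", {
  ax <- energy_axis(256, 0.25, 5)
  peaks <- c(20, 59.5)
  # pixel 1 on the global axis, pixel 2 with 1.05x gain
  sim <- simulate_calibration_spectra(peaks, ax, n_pixels = 2,
                                      pixel_gains = c(0.25, 0.25 * 1.05),
                                      detector = detector_model(1.0),
                                      poisson = FALSE)
  corr <- interpixel_gain_correct(sim$counts, ax, peaks)
  expect_false(any(corr$flagged))
  expect_equal(corr$pixel_axes$gain[2] / 0.25, 1.05, tolerance = 1e-4)

  # pixel already on the global axis passes through (near-)unchanged
  expect_equal(corr$spectra[1, ], sim$counts[1, ], tolerance = 1e-6)

  # corrected peak centroids land within 0.1 channel of global positions
  for (e in peaks) {
    k <- energy_to_channel(ax, e)
    cent <- fit_peak(corr$spectra[2, ], (k - 15):(k + 15))$centroid
    expect_lt(abs(cent - ((e - 5) / 0.25 + 1)), 0.1)
  }

  # counts conservation within 0.1%
  expect_lt(abs(sum(corr$spectra[2, ]) - sum(sim$counts[2, ])) /
              sum(sim$counts[2, ]), 0.001)

  # idempotency: a second pass changes spectra by < 1e-6 relative
  corr2 <- interpixel_gain_correct(corr$spectra, ax, peaks)
  expect_lt(max(abs(corr2$spectra - corr$spectra)) / max(corr$spectra), 1e-6)

  # unresolvable pixel is passed through and flagged
  flat <- rbind(sim$counts, 1)
  corr3 <- interpixel_gain_correct(flat, ax, peaks)
  expect_true(corr3$flagged[3])
  expect_equal(corr3$spectra[3, ], flat[3, ])
})
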