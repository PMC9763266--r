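test_that("phase measurement averages slices with the sample SD convention", {
  ax <- make_axis(25, 45)
  iod <- element_record("I")
  # hand-built map: 3 slices whose per-slice means are 1, 2, 3
  arr <- array(0, dim = c(3, 4, 4))
  for (z in 1:3) arr[z, , ] <- z
  em <- structure(list(delta_mu0 = arr,
                       valid = array(TRUE, dim = c(3, 4, 4)),
                       element = "I", params = kes_params(),
                       windows = NULL),
                  class = "edge_height_map")
  m <- measure_phases(em, list(p = roi_box(1:3, 1:4, 1:4)), 50,
                      slices = 1:3)
  expect_equal(m$mean_delta_mu0, 2)
  expect_equal(m$sd_delta_mu0, 1)   # sample (n-1) SD
  expect_equal(m$n_slices, 3)

  # homogeneous noiseless phase: SD across slices is 0; default 6 slices
  fx <- make_calibration_fixture("I2KI", nz = 12L)
  emx <- edge_height_map(fx$built$volume, iod)
  mm <- measure_phases(emx, fx$rois, fx$concentrations)
  expect_equal(unique(mm$n_slices), 6L)
  expect_equal(max(mm$sd_delta_mu0), 0, tolerance = 1e-12)

  expect_error(measure_phases(emx, fx$rois, fx$concentrations, slices = 99),
               "depth")
})

test_that("calibration fitting is exact on noiseless phantoms and warns on defects", {
  fx <- make_calibration_fixture("BaSO4", nz = 8L, n_channels = 81L,
                                 offset_kev = 30)
  ba <- element_record("Ba")
  em <- edge_height_map(fx$built$volume, ba)
  m <- measure_phases(em, fx$rois, fx$concentrations)
  curve <- fit_calibration(m, element = "Ba")
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
  # slope matches the per-unit edge height the estimator produces,
  # intercept ~ 0 (medium curvature only)
  per_unit <- edge_height(make_phase_spectrum("Ba", 1, fx$axis,
                                              medium = medium_model(0, 35, "flat")),
                          ba)$delta_mu0
  expect_equal(curve$slope, per_unit, tolerance = 1e-6)
  expect_lt(abs(curve$intercept), 1e-3 * max(m$mean_delta_mu0))

  # two phases: exact interpolating line
  c2 <- fit_calibration(m[1:2, ], element = "Ba")
  expect_equal(c2$r_squared, 1)
  expect_equal(predict_concentration(c2, m$mean_delta_mu0[1]), 100,
               tolerance = 1e-9)

  expect_error(fit_calibration(m[c(1, 1), ]), "distinct")
  m_bad <- m; m_bad$mean_delta_mu0 <- rev(m$mean_delta_mu0)
  expect_warning(fit_calibration(m_bad), "not positive")

  expect_s3_class(tidy(curve), "tbl_df")
  expect_equal(glance(curve)$n_phases, 3)
})

test_that("concentration maps invert the calibration with clamping and masking", {
  fx <- make_calibration_fixture("PTA", nz = 8L, n_channels = 121L,
                                 offset_kev = 55)
  w <- element_record("W")
  em <- edge_height_map(fx$built$volume, w)
  m <- measure_phases(em, fx$rois, fx$concentrations)
  curve <- fit_calibration(m, element = "W")
  cv <- concentration_map(em, curve)

  # noiseless round trip: each phase mean within 1% relative
  for (i in seq_along(fx$rois)) {
    vox <- kedge:::roi_voxel_indices(fx$rois[[i]], dim(cv$concentration))
    expect_equal(mean(cv$concentration[vox]), fx$concentrations[i],
                 tolerance = 0.01)
  }
  # background (no stain) recovers ~0 after clamping
  bg <- cv$concentration[, 2, 2]
  expect_lt(max(bg), 1)
  expect_true(all(cv$concentration >= 0))

  # a voxel below the calibration intercept keeps its negative pre-clamp
  # value in the diagnostics array but clamps to 0 in the map
  em_neg <- em; em_neg$delta_mu0[1, 1, 1] <- curve$intercept - 0.01
  cv_neg <- concentration_map(em_neg, curve)
  expect_lt(cv_neg$raw[1, 1, 1], 0)
  expect_identical(cv_neg$concentration[1, 1, 1], 0)

  # delta-mu0 = intercept everywhere -> c = 0 everywhere
  em0 <- em; em0$delta_mu0[] <- curve$intercept
  cv0 <- concentration_map(em0, curve)
  expect_equal(max(abs(cv0$concentration)), 0)

  # monotone in delta-mu0
  em_hi <- em; em_hi$delta_mu0 <- em$delta_mu0 + 0.01
  cv_hi <- concentration_map(em_hi, curve)
  expect_true(all(cv_hi$concentration >= cv$concentration - 1e-12))

  # element mismatch rejected
  curve_I <- curve; curve_I$element <- "I"
  expect_error(concentration_map(em, curve_I), "mismatch")
})

test_that("concentration histograms conserve counts and find phase modes", {
  fx <- make_calibration_fixture("BaSO4", nz = 6L, n_channels = 81L,
                                 offset_kev = 30)
  ba <- element_record("Ba")
  em <- edge_height_map(fx$built$volume, ba)
  curve <- fit_calibration(measure_phases(em, fx$rois, fx$concentrations),
                           element = "Ba")
  cv <- concentration_map(em, curve)
  h <- concentration_histogram(cv, bin_width = 10)
  expect_equal(sum(h$histogram$count), h$n_voxels)
  expect_equal(h$n_voxels, sum(cv$valid))
  # modes at ~100, 200, 400 mg/ml: those bins are locally dominant
  for (cc in c(100, 200, 400)) {
    bin <- max(which(h$histogram$bin_lo <= cc))
    near <- max(1, bin - 2):min(nrow(h$histogram), bin + 2)
    expect_gt(sum(h$histogram$count[near]),
              sum(fx$built$concentration$Ba == cc) * 0.9)
  }

  # uniform volume occupies a single bin
  cvu <- cv
  cvu$concentration[] <- 42; cvu$valid[] <- TRUE
  hu <- concentration_histogram(cvu, bin_width = 10)
  expect_equal(sum(hu$histogram$count > 0), 1)
})

test_that("overlap reports label multi-stained voxels exactly", {
  ax <- make_axis(25, 80, gain = 0.5)
  grid <- phantom_grid(20, 20, 2, 500)
  phases <- list(
    phantom_phase(-2, -2, 1.2, "I", 60),
    phantom_phase(2, 2, 1.2, "W", 100),
    phantom_phase(0, 0, 0.8, "I", 40),   # co-stained block:
    phantom_phase(0, 0, 0.8, "W", 50)    # same cylinder, both stains
  )
  built <- build_phantom_volume(phases, grid, ax)
  cvols <- lapply(c("I", "W"), function(s) {
    el <- element_record(s)
    em <- edge_height_map(built$volume, el)
    m <- tibble::tibble(concentration = c(20, 120),
                        mean_delta_mu0 = c(20, 120) *
                          edge_height(make_phase_spectrum(s, 1, ax,
                                        medium = medium_model(0, 35, "flat")),
                                      el)$delta_mu0)
    concentration_map(em, fit_calibration(m, element = s))
  })
  rep_ <- overlap_report(cvols, threshold = 5)
  both <- built$concentration$I > 0 & built$concentration$W > 0
  expect_equal(rep_$labels == "I+W", both)
  expect_true(all(c("I", "W", "I+W", "background") %in% rep_$table$label))

  # disjoint phases only: no multi-element labels
  rep_d <- overlap_report(cvols[1], threshold = 5)
  expect_false(any(grepl("\\+", rep_d$table$label)))

  # empty volume: all background
  em_e <- edge_height_map(build_phantom_volume(list(), grid, ax)$volume,
                          element_record("I"))
  cv_e <- concentration_map(em_e, fit_calibration(
    tibble::tibble(concentration = c(0, 100), mean_delta_mu0 = c(0, 0.3)),
    element = "I"))
  rep_e <- overlap_report(list(cv_e), threshold = 5)
  expect_equal(rep_e$table$label, "background")
})

test_that("standardised intensity anchors air to 0 and agarose to 1", {
  # single-energy volume: air ~0.0, agarose 0.02, phases linear in c
  arr <- array(0, dim = c(2, 10, 10))
  arr[, , 1:2] <- 0.0        # air column
  arr[, , 3:4] <- 0.02       # agarose column
  concs <- c(100, 200, 400)
  for (i in seq_along(concs)) arr[, , 4 + 2 * i] <- 0.02 + 1e-4 * concs[i]
  si <- standardised_intensity(arr, air_roi = roi_box(1:2, 1:10, 1:2),
                               agarose_roi = roi_box(1:2, 1:10, 3:4))
  expect_equal(mean(si$intensity[, , 1:2]), 0)
  expect_equal(mean(si$intensity[, , 3:4]), 1)

  rois <- lapply(seq_along(concs), function(i) roi_box(1:2, 1:10, 4 + 2 * i))
  fitc <- fit_intensity_calibration(si, rois, concs)
  expect_equal(fitc$r_squared, 1, tolerance = 1e-12)
  # affine invariance: intensity slope = mu slope / (agarose - air)
  expect_equal(fitc$slope, 1e-4 / 0.02, tolerance = 1e-9)

  expect_error(standardised_intensity(arr, roi_box(1:2, 1:10, 1:2),
                                      roi_box(1:2, 1:10, 1:2)), "equal")
})
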