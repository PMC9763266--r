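test_that("KES window convention matches the hand-computed step example", {
  # axis with edge channel k for iodine; step spectrum 0.2 below k, 0.5 at
  # and above k; width 5, separation 2 -> delta-mu = 0.3 exactly
  ax <- make_axis(25, 45)
  iod <- element_record("I")
  k <- which(axis_energies(ax) >= iod$k_edge_kev)[1]
  mu <- ifelse(seq_len(ax$n_channels) >= k, 0.5, 0.2)
  vol <- hyperspectral_volume(array(mu, dim = c(1, 1, 1, ax$n_channels)),
                              ax, 100)
  m <- kes_map(vol, iod, kes_params(5, 2))
  expect_identical(m$delta_mu[1, 1, 1], 0.3)
  expect_identical(m$windows$pre, (k - 7):(k - 3))
  expect_identical(m$windows$post, (k + 2):(k + 6))

  # element-free flat spectrum: delta-mu = 0
  vol0 <- hyperspectral_volume(array(0.4, dim = c(1, 1, 1, ax$n_channels)),
                               ax, 100)
  expect_identical(kes_map(vol0, iod)$delta_mu[1, 1, 1], 0)

  # default windows: 5 channels per window ~ 1.25 keV at 0.25 keV/channel
  expect_equal(length(m$windows$pre) * ax$gain, 1.25)

  # windows out of range are rejected naming the element
  ax_short <- make_axis(33, 40)
  vol_s <- hyperspectral_volume(array(0.4, dim = c(1, 1, 1, ax_short$n_channels)),
                                ax_short, 100)
  expect_error(kes_map(vol_s, iod), "I")
})

test_that("edge height matches the two-line closed form to 1e-9", {
  ax <- make_axis(25, 45)
  iod <- element_record("I")
  e <- axis_energies(ax)
  # spectrum exactly on two lines: below 0.8 - 0.01 E, above 1.1 - 0.01 E
  mu <- ifelse(e >= iod$k_edge_kev, 1.1 - 0.01 * e, 0.8 - 0.01 * e)
  spec <- attenuation_spectrum(mu, ax)
  eh <- edge_height(spec, iod)
  expect_equal(eh$delta_mu0, 0.3, tolerance = 1e-9)
  expect_equal(eh$slope_pre, -0.01, tolerance = 1e-9)
  expect_equal(eh$slope_post, -0.01, tolerance = 1e-9)
  expect_lt(eh$rss_pre + eh$rss_post, 1e-18)
  expect_true(eh$valid)

  # element-free smooth power law: |delta-mu0| at the noise floor
  med <- medium_model()
  mu_bg <- medium_mu_fixture(med, e)
  eh0 <- edge_height(attenuation_spectrum(mu_bg, ax), iod)
  expect_lt(abs(eh0$delta_mu0), 1e-4)

  expect_error(edge_height(spec, iod, kes_params(1, 2)), "width >= 2")
})

test_that("edge height is exactly linear in concentration and near the analytic step", {
  ax <- make_axis(25, 45)
  iod <- element_record("I")
  concs <- c(10, 25.3, 50.6, 101.2, 400)
  dmu0 <- vapply(concs, function(cc) {
    edge_height(make_phase_spectrum("I", cc, ax), iod)$delta_mu0
  }, numeric(1))
  # exactly affine in c (the medium contributes a constant offset, the
  # solute a term proportional to c): line-fit residuals at machine level
  fit <- stats::lm(dmu0 ~ concs)
  expect_lt(max(abs(stats::resid(fit))) / diff(range(dmu0)), 1e-9)
  # and the solute part alone is exactly proportional to c
  base <- edge_height(make_phase_spectrum("I", 0, ax), iod)$delta_mu0
  per_unit <- (dmu0 - base) / concs
  expect_lt(diff(range(per_unit)) / mean(per_unit), 1e-9)
  # close to the closed-form step; the two-line extrapolation on a curved
  # power-law spectrum carries a small second-order curvature bias
  expect_equal(dmu0[4], elemental_edge_step(iod, 101.2), tolerance = 0.01)

  # voxel-wise map equals the per-spectrum estimator
  grid <- phantom_grid(8, 8, 2, 500)
  built <- build_phantom_volume(list(phantom_phase(0, 0, 1.6, "I", 50.6)),
                                grid, ax)
  em <- edge_height_map(built$volume, iod)
  centre_spec <- attenuation_spectrum(built$volume$data[1, 4, 4, ], ax)
  expect_equal(em$delta_mu0[1, 4, 4],
               edge_height(centre_spec, iod)$delta_mu0, tolerance = 1e-12)
  expect_true(all(em$valid))
})

test_that("KES and edge height agree exactly on an ideal step with flat flanks", {
  ax <- make_axis(25, 45)
  iod <- element_record("I")
  k <- which(axis_energies(ax) >= iod$k_edge_kev)[1]
  mu <- ifelse(seq_len(ax$n_channels) >= k, 0.75, 0.25)
  vol <- hyperspectral_volume(array(mu, dim = c(1, 1, 1, ax$n_channels)), ax, 100)
  spec <- attenuation_spectrum(mu, ax)
  expect_equal(kes_map(vol, iod)$delta_mu[1, 1, 1],
               edge_height(spec, iod)$delta_mu0, tolerance = 1e-12)
})

test_that("multi-element voxels: per-element edge heights are additive within 1%", {
  ax <- make_axis(25, 45)
  iod <- element_record("I"); ba <- element_record("Ba")
  e <- axis_energies(ax)
  med <- medium_mu_fixture(medium_model(), e)
  mu_I <- med + elemental_mu(iod, e, 40)
  mu_Ba <- med + elemental_mu(ba, e, 150)
  mu_mix <- mu_I + elemental_mu(ba, e, 150)
  dI_single <- edge_height(attenuation_spectrum(mu_I, ax), iod)$delta_mu0
  dBa_single <- edge_height(attenuation_spectrum(mu_Ba, ax), ba)$delta_mu0
  dI_mix <- edge_height(attenuation_spectrum(mu_mix, ax), iod)$delta_mu0
  dBa_mix <- edge_height(attenuation_spectrum(mu_mix, ax), ba)$delta_mu0
  expect_lt(abs(dI_mix - dI_single) / dI_single, 0.01)
  expect_lt(abs(dBa_mix - dBa_single) / dBa_single, 0.01)
})

test_that("edge detection localises K-edges and stays silent on edge-free spectra", {
  # flat spectrum: nothing detected
  ax <- make_axis(25, 45)
  flat <- attenuation_spectrum(rep(0.3, ax$n_channels), ax)
  expect_equal(nrow(detect_edges(flat)), 0)

  # noiseless iodine phase: detected within one channel of 33.17 keV
  det_I <- detect_edges(make_phase_spectrum("I", 50, ax))
  expect_true("I" %in% det_I$symbol)
  expect_lte(abs(det_I$detected_kev[det_I$symbol == "I"] - 33.17),
             ax$gain + 1e-12)

  # two-element voxel: both detected, magnitudes within 5% of singles
  e <- axis_energies(ax)
  med <- medium_mu_fixture(medium_model(), e)
  iod <- element_record("I"); ba <- element_record("Ba")
  mix <- attenuation_spectrum(
    med + elemental_mu(iod, e, 40) + elemental_mu(ba, e, 150), ax)
  d_mix <- detect_edges(mix)
  expect_setequal(intersect(d_mix$symbol, c("I", "Ba")), c("I", "Ba"))
  for (sym in c("I", "Ba")) {
    single <- detect_edges(make_phase_spectrum(
      sym, if (sym == "I") 40 else 150, ax))
    expect_equal(d_mix$step_magnitude[d_mix$symbol == sym],
                 single$step_magnitude[single$symbol == sym],
                 tolerance = 0.05)
  }

  # decreasing edge-free spectrum: no detections
  d_bg <- detect_edges(attenuation_spectrum(med, ax))
  expect_equal(nrow(d_bg), 0)

  expect_error(detect_edges(flat, tolerance_kev = 0.1), "one channel")
})

test_that("element segmentation matches rasterised ground truth and supports overlap", {
  ax <- make_axis(25, 80, gain = 0.5)
  grid <- phantom_grid(24, 24, 2, 500)
  phases <- list(
    phantom_phase(-2, 0, 1.5, "Ba", 200),   # barium cylinder
    phantom_phase(2, 0, 1.5, "I", 60),      # iodine cylinder
    phantom_phase(2, 0, 1.0, "W", 80)       # tungsten inside the iodine one
  )
  built <- build_phantom_volume(phases, grid, ax)
  # single-stain case first: the default MAD threshold separates exactly
  built_ba <- build_phantom_volume(phases[1], grid, ax)
  seg_ba <- segment_elements(
    list(edge_height_map(built_ba$volume, element_record("Ba"))))
  expect_equal(seg_ba$masks$Ba, built_ba$concentration$Ba > 0)

  # multi-stain fixture: edge-height maps (slope-free) with explicit
  # thresholds above the curvature cross-talk other stains leave at a
  # foreign K-edge (~1% of a typical in-phase step here)
  maps <- lapply(c("Ba", "I", "W"), function(s) {
    edge_height_map(built$volume, element_record(s))
  })
  seg <- segment_elements(maps, vol = built$volume,
                          thresholds = c(Ba = 0.02, I = 0.02, W = 0.01))
  expect_equal(seg$masks$Ba, built$concentration$Ba > 0)
  expect_equal(seg$masks$I, built$concentration$I > 0)
  expect_equal(seg$masks$W, built$concentration$W > 0)
  # overlap region: W voxels are all inside the I mask here
  expect_true(all(seg$masks$I[seg$masks$W]))
  expect_false(any(seg$masks$Ba & seg$masks$I))

  # all-zero maps: empty masks
  zero <- maps
  zero[[1]]$delta_mu0[] <- 0
  seg0 <- segment_elements(zero[1])
  expect_false(any(seg0$masks$Ba))

  m_bad <- kes_map(build_phantom_volume(list(), phantom_grid(8, 8, 1, 500),
                                        ax)$volume, element_record("I"))
  expect_error(segment_elements(list(maps[[1]], m_bad)), "mismatch")
})
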