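# Seeded noisy end-to-end pipeline on the iodine calibration phantom:
# simulate -> Poisson counts -> ring/COR preprocessing -> FBP -> edge
# height -> calibrate on the three lowest phases -> quantify the highest.
# Kept at one z slice / 40 channels so the full chain runs in seconds.
run_noisy_pipeline <- function(seed) {
  axis <- energy_axis(40, 0.25, 28)        # 28-37.75 keV around the I edge
  grid <- phantom_grid(64, 64, 1, 200)
  ph <- calibration_phantom("I2KI", grid)
  built <- build_phantom_volume(ph$phases, grid, axis,
                                medium = medium_model(0, type = "flat"))
  slice <- aperm(built$volume$data[1, , , , drop = FALSE][1, , , ], c(1, 2, 3))

  gains <- rep(1, 64); gains[20] <- 1.05   # one miscalibrated column
  det <- detector_model(energy_fwhm_kev = 1.27, i0 = 2e4,
                        pixel_gain_errors = gains, cor_shift = 0.6,
                        seed = seed)
  ang <- seq(0, 180, by = 2)
  counts <- project(slice, ang, axis, 0.2, det, mode = "counts")
  p <- sinogram_to_line_integrals(counts, det$i0)
  pp <- preprocess_sinogram(p)
  vol <- reconstruct_volume(pp$sino, voxel_size_um = 200)

  iod <- element_record("I")
  em <- edge_height_map(vol, iod)
  vs <- 0.2
  rois <- lapply(seq_along(ph$concentrations), function(i) {
    roi_cylinder(1, cx = ph$centres_mm[i, 1] / vs + 32.5,
                 cy = ph$centres_mm[i, 2] / vs + 32.5,
                 radius = 0.6 * ph$container_radius_mm / vs)
  })
  names(rois) <- paste0("phase", 1:4)
  meas <- measure_phases(em, rois, ph$concentrations, slices = 1)
  curve <- fit_calibration(meas[1:3, ], element = "I")
  cv <- concentration_map(em, curve)

  vox4 <- kedge:::roi_voxel_indices(rois[[4]], dim(cv$concentration))
  list(
    median_c4 = stats::median(cv$concentration[vox4]),
    truth_c4 = ph$concentrations[4],
    concentration = cv$concentration,
    cor_offset = pp$cor_offset
  )
}
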