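# Shared fixtures: built in code, sized for seconds-scale tests.

# axis with 0.25 keV channels covering [lo, hi] keV
make_axis <- function(lo, hi, gain = 0.25) {
  energy_axis(round((hi - lo) / gain) + 1L, gain = gain, offset = lo)
}

# noiseless single-element phase spectrum on a given axis
make_phase_spectrum <- function(symbol, conc, axis,
                                medium = medium_model()) {
  elem <- element_record(symbol)
  mu <- medium_mu_fixture(medium, axis_energies(axis)) +
    elemental_mu(elem, axis_energies(axis), conc)
  attenuation_spectrum(mu, axis)
}

# medium attenuation (mirrors the package's internal model; used to build
# spectra without going through build_phantom_volume)
medium_mu_fixture <- function(medium, e) {
  if (medium$type == "flat") rep(medium$mu_ref, length(e))
  else medium$mu_ref * (e / medium$e_ref)^-3
}

# calibration phantom volume + per-phase ROIs (slightly shrunk so ROIs stay
# inside the rasterised cylinders)
make_calibration_fixture <- function(agent, nz = 12L, n_channels = 200L,
                                     offset_kev = 5, gain = 0.25,
                                     nx = 64L, voxel_um = 200) {
  grid <- phantom_grid(nx, nx, nz, voxel_um)
  axis <- energy_axis(n_channels, gain, offset_kev)
  ph <- calibration_phantom(agent, grid)
  built <- build_phantom_volume(ph$phases, grid, axis,
                                medium = medium_model(0, type = "flat"))
  vs <- voxel_um / 1000
  rois <- lapply(seq_along(ph$concentrations), function(i) {
    roi_cylinder(1:nz,
                 cx = ph$centres_mm[i, 1] / vs + (nx + 1) / 2,
                 cy = ph$centres_mm[i, 2] / vs + (nx + 1) / 2,
                 radius = 0.6 * ph$container_radius_mm / vs)
  })
  names(rois) <- paste0("phase", seq_along(rois))
  list(grid = grid, axis = axis, phantom = ph, built = built, rois = rois,
       element = ph$element, concentrations = ph$concentrations)
}

# annulus-mean ring metric: mean squared radial profile of an error image,
# computed by brute force over integer-radius annuli
ring_metric <- function(err_img) {
  n <- nrow(err_img)
  c0 <- (n + 1) / 2
  r <- round(sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")))
  keep <- r <= floor(n / 2) - 1
  prof <- tapply(err_img[keep], r[keep], mean)
  mean(prof^2)
}

# uniform disk slice fixture: (n x n x nch) array, mu inside the disk
make_disk_slice <- function(n = 64, nch = 2, mu = 0.1, radius_mm = 5,
                            voxel_mm = 0.2) {
  co <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  img <- outer(co, co, function(y, x) as.numeric(x^2 + y^2 <= radius_mm^2)) * mu
  array(rep(img, nch), dim = c(n, n, nch))
}

# smooth asymmetric slice (two Gaussian blobs): the kind of object the
# wavelet-Fourier stripe filter is designed for (no razor-sharp edges,
# no rotational symmetry). 128 columns, 0.1 mm voxels.
make_smooth_slice <- function(n = 128, nch = 2, voxel_mm = 0.1) {
  co <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  img <- outer(co, co, function(y, x) {
    0.1 * exp(-((x - 1.5)^2 + (y - 1)^2) / 8) +
      0.07 * exp(-((x + 2.5)^2 + (y + 2)^2) / 4.5)
  })
  array(rep(img, nch), dim = c(n, n, nch))
}
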