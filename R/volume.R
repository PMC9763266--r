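#' Hyperspectral attenuation volume
#'
#' The substrate of all spectral analysis: a 4D array of linear attenuation
#' coefficients (mm^-1) with axis order `(z, y, x, energy)`, an isotropic
#' voxel size in micrometres, and an [energy_axis()] describing the fourth
#' dimension.
#'
#' @param data 4D numeric array, axis order `(z, y, x, energy)`, values in
#'   mm^-1. Slightly negative values are allowed (reconstruction noise), but
#'   all values must be finite.
#' @param axis An [energy_axis()]; its channel count must match `dim(data)[4]`.
#' @param voxel_size_um Isotropic voxel edge length in micrometres (> 0).
#'
#' @return An object of class `hyperspectral_volume`.
#' @export
hyperspectral_volume <- function(data, axis, voxel_size_um) {
  stopifnot(inherits(axis, "energy_axis"))
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("`data` must be a 4D array with axis order (z, y, x, energy)")
  }
  if (dim(data)[4] != axis$n_channels) {
    stop(sprintf("energy extent (%d) does not match axis$n_channels (%d)",
                 dim(data)[4], axis$n_channels))
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a positive number")
  }
  structure(
    list(data = data, axis = axis, voxel_size_um = as.numeric(voxel_size_um)),
    class = "hyperspectral_volume"
  )
}

#' @export
print.hyperspectral_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyperspectral_volume> %d x %d x %d voxels (z,y,x), %d channels, %.3g um voxels\n",
    d[1], d[2], d[3], d[4], x$voxel_size_um
  ))
  invisible(x)
}

#' @export
dim.hyperspectral_volume <- function(x) dim(x$data)

#' Attenuation spectrum
#'
#' A per-channel linear attenuation profile mu(E) in mm^-1 on an energy axis,
#' e.g. the spectrum of one voxel or the ROI-averaged spectrum of a phase.
#'
#' @param mu Numeric vector of linear attenuation values (mm^-1), one per
#'   channel. May dip slightly negative (reconstruction noise) but must be
#'   finite.
#' @param axis An [energy_axis()] with `n_channels == length(mu)`.
#' @return An object of class `attenuation_spectrum`.
#' @export
attenuation_spectrum <- function(mu, axis) {
  stopifnot(inherits(axis, "energy_axis"))
  mu <- as.numeric(mu)
  if (length(mu) != axis$n_channels) {
    stop("length(mu) must equal axis$n_channels")
  }
  if (!all(is.finite(mu))) stop("spectrum contains non-finite values")
  structure(list(mu = mu, axis = axis), class = "attenuation_spectrum")
}

#' Tidy an attenuation spectrum into a tibble
#'
#' @param x An [attenuation_spectrum()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `energy_kev`, `mu`.
#' @export
as_tibble.attenuation_spectrum <- function(x, ...) {
  tibble::tibble(
    channel = seq_len(x$axis$n_channels),
    energy_kev = axis_energies(x$axis),
    mu = x$mu
  )
}

#' @export
print.attenuation_spectrum <- function(x, ...) {
  cat(sprintf("<attenuation_spectrum> %d channels, mu in [%.4g, %.4g] mm^-1\n",
              x$axis$n_channels, min(x$mu), max(x$mu)))
  invisible(x)
}

#' Regions of interest in voxel coordinates
#'
#' `roi_box()` selects an axis-aligned box of voxels by inclusive 1-based
#' index ranges; `roi_voxels()` selects an explicit set of voxels given as a
#' matrix of `(z, y, x)` indices; `roi_cylinder()` selects voxels whose
#' (x, y) centre lies inside a circle over a range of z slices.
#'
#' @param z,y,x Integer ranges (inclusive) of voxel indices for `roi_box()`,
#'   or for `roi_cylinder()` `z` an integer range and `cx`, `cy`, `radius`
#'   the circle centre and radius in voxel units.
#' @return An object of class `kedge_roi`.
#' @export
roi_box <- function(z, y, x) {
  structure(list(kind = "box", z = range(as.integer(z)),
                 y = range(as.integer(y)), x = range(as.integer(x))),
            class = "kedge_roi")
}

#' @rdname roi_box
#' @param vox Integer matrix with three columns `(z, y, x)`.
#' @export
roi_voxels <- function(vox) {
  vox <- as.matrix(vox)
  if (ncol(vox) != 3L || nrow(vox) < 1L) {
    stop("`vox` must be a non-empty matrix with columns (z, y, x)")
  }
  structure(list(kind = "voxels", vox = matrix(as.integer(vox), ncol = 3L)),
            class = "kedge_roi")
}

#' @rdname roi_box
#' @param cx,cy Circle centre in voxel units (x and y index coordinates).
#' @param radius Circle radius in voxel units.
#' @export
roi_cylinder <- function(z, cx, cy, radius) {
  stopifnot(radius > 0)
  structure(list(kind = "cylinder", z = range(as.integer(z)),
                 cx = cx, cy = cy, radius = radius),
            class = "kedge_roi")
}

# resolve an ROI to a (n x 3) matrix of (z, y, x) voxel indices, validated
# against the spatial dimensions `d` = dim(data)[1:3]
roi_voxel_indices <- function(roi, d) {
  stopifnot(inherits(roi, "kedge_roi"))
  vox <- switch(roi$kind,
    box = {
      as.matrix(expand.grid(z = roi$z[1]:roi$z[2],
                            y = roi$y[1]:roi$y[2],
                            x = roi$x[1]:roi$x[2]))
    },
    voxels = roi$vox,
    cylinder = {
      g <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
      inside <- (g$x - roi$cx)^2 + (g$y - roi$cy)^2 <= roi$radius^2
      g <- g[inside, , drop = FALSE]
      if (nrow(g) == 0L) stop("ROI is empty: cylinder covers no voxel centres")
      zs <- roi$z[1]:roi$z[2]
      cbind(z = rep(zs, each = nrow(g)),
            y = rep(g$y, length(zs)), x = rep(g$x, length(zs)))
    }
  )
  if (nrow(vox) == 0L) stop("ROI is empty")
  if (any(vox < 1L) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
      any(vox[, 3] > d[3])) {
    stop("ROI extends outside the volume bounds")
  }
  vox
}

#' Average the spectra of an ROI
#'
#' Extracts the per-channel arithmetic mean attenuation over all voxels of a
#' region of interest, the standard way phase spectra are measured before
#' edge analysis (averaging cancels within-phase inhomogeneity and noise).
#'
#' @param vol A [hyperspectral_volume()].
#' @param roi A [roi_box()], [roi_voxels()] or [roi_cylinder()].
#' @return An [attenuation_spectrum()] on `vol$axis`.
#' @export
extract_roi_spectrum <- function(vol, roi) {
  stopifnot(inherits(vol, "hyperspectral_volume"))
  d <- dim(vol$data)
  vox <- roi_voxel_indices(roi, d[1:3])
  nch <- d[4]
  # gather the (n_vox x n_channels) matrix with one vectorised index build
  flat <- as.vector(
    outer(
      (vox[, 1] - 1L) + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2],
      (seq_len(nch) - 1L) * d[1] * d[2] * d[3],
      "+"
    ) + 1L
  )
  m <- matrix(vol$data[flat], nrow = nrow(vox), ncol = nch)
  attenuation_spectrum(colMeans(m), vol$axis)
}
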