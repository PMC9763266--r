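#' Detector acquisition model
#'
#' Parameters of the emulated photon-counting acquisition: Gaussian energy
#' blur (the detector's finite energy resolution, ~1.27 keV FWHM for the
#' emulated system), incident counts per detector element and channel,
#' per-detector-column multiplicative gain errors (the cause of ring
#' artifacts), a sub-pixel centre-of-rotation offset, and an RNG seed.
#'
#' @param energy_fwhm_kev Gaussian FWHM of the energy response, keV (>= 0;
#'   0 disables the blur).
#' @param i0 Incident photon counts per detector element per channel (> 0).
#' @param pixel_gain_errors Numeric vector of per-detector-column
#'   multiplicative factors (> 0), recycled across columns; `NULL` for a
#'   perfectly flat detector.
#' @param cor_shift Centre-of-rotation offset in detector columns (may be
#'   fractional).
#' @param seed Integer RNG seed for Poisson sampling; `NULL` leaves the
#'   global RNG state alone.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(energy_fwhm_kev = 1.27, i0 = 1e4,
                           pixel_gain_errors = NULL, cor_shift = 0,
                           seed = NULL) {
  stopifnot(energy_fwhm_kev >= 0, i0 > 0)
  if (!is.null(pixel_gain_errors) && any(pixel_gain_errors <= 0)) {
    stop("pixel gain factors must be positive")
  }
  structure(list(energy_fwhm_kev = energy_fwhm_kev, i0 = i0,
                 pixel_gain_errors = pixel_gain_errors,
                 cor_shift = cor_shift, seed = seed),
            class = "detector_model")
}

# evaluate code with a temporary RNG seed, restoring global state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spectral sinogram container
#'
#' @param data 3D array `(angle, detector column, energy channel)`, either
#'   photon counts or line integrals depending on `mode`.
#' @param angles_deg Strictly increasing projection angles in degrees.
#' @param pitch_mm Detector element pitch in mm.
#' @param axis An [energy_axis()].
#' @param mode `"counts"` or `"line_integral"`.
#' @return An object of class `spectral_sinogram`.
#' @export
spectral_sinogram <- function(data, angles_deg, pitch_mm, axis,
                              mode = c("line_integral", "counts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(axis, "energy_axis"),
            is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] != length(angles_deg)) {
    stop("first dimension of data must match length(angles_deg)")
  }
  if (dim(data)[3] != axis$n_channels) {
    stop("third dimension of data must match axis$n_channels")
  }
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
  if (mode == "counts" && any(data < 0)) stop("counts must be >= 0")
  structure(list(data = data, angles_deg = as.numeric(angles_deg),
                 pitch_mm = pitch_mm, axis = axis, mode = mode),
            class = "spectral_sinogram")
}

#' @export
print.spectral_sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_sinogram> %d angles x %d detectors x %d channels (%s)\n",
              d[1], d[2], d[3], x$mode))
  invisible(x)
}

# Gaussian blur along the last (energy) dimension of a matrix of spectra,
# rows = measurements, cols = channels; sigma in channel units.
# Kernel renormalised at the edges so flat spectra stay flat.
blur_energy <- function(m, sigma_ch) {
  if (sigma_ch <= 0) return(m)
  half <- max(1L, ceiling(4 * sigma_ch))
  k <- stats::dnorm(seq(-half, half), sd = sigma_ch)
  nch <- ncol(m)
  out <- matrix(0, nrow(m), nch)
  wsum <- numeric(nch)
  for (j in seq(-half, half)) {
    src <- seq_len(nch) + j
    ok <- src >= 1L & src <= nch
    w <- k[j + half + 1L]
    out[, ok] <- out[, ok] + w * m[, src[ok]]
    wsum[ok] <- wsum[ok] + w
  }
  sweep(out, 2, wsum, "/")
}

# bilinear sampling stencil for the rotated grid of one projection angle:
# detector coordinate t (columns), ray parameter s (rows). Returns linear
# indices and weights into a flattened (ny x nx) image; out-of-image
# samples get weight 0. Shared across energy channels.
radon_stencil <- function(ny, nx, theta_deg) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- theta_deg * pi / 180
  tt <- seq_len(nx) - cx
  ss <- seq_len(ny) - cy
  ct <- cos(th); st <- sin(th)
  xs <- outer(ss, tt, function(s, t) t * ct - s * st) + cx
  ys <- outer(ss, tt, function(s, t) t * st + s * ct) + cy
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  corner <- function(yy, xx, w) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    idx <- ifelse(ok, (xx - 1L) * ny + yy, 1L)
    list(idx = idx, w = w * ok)
  }
  list(
    corner(y0, x0, (1 - fy) * (1 - fx)),
    corner(y0 + 1, x0, fy * (1 - fx)),
    corner(y0, x0 + 1, (1 - fy) * fx),
    corner(y0 + 1, x0 + 1, fy * fx)
  )
}

# parallel-beam line integrals of one 2D image (rows = y, cols = x) at one
# angle; stencil from radon_stencil(). Units: mu * mm.
radon_apply <- function(img, stencil, ny, nx, pitch_mm) {
  v <- stencil[[1]]$w * img[stencil[[1]]$idx] +
    stencil[[2]]$w * img[stencil[[2]]$idx] +
    stencil[[3]]$w * img[stencil[[3]]$idx] +
    stencil[[4]]$w * img[stencil[[4]]$idx]
  dim(v) <- c(ny, nx)
  colSums(v) * pitch_mm
}

# sub-pixel shift of each row of a matrix along its columns (linear
# interpolation, edge replication)
shift_rows <- function(m, shift) {
  if (shift == 0) return(m)
  n <- ncol(m)
  pos <- seq_len(n) - shift
  i0 <- floor(pos); f <- pos - i0
  i0c <- pmin(pmax(i0, 1L), n)
  i1c <- pmin(pmax(i0 + 1L, 1L), n)
  m[, i0c, drop = FALSE] * rep(1 - f, each = nrow(m)) +
    m[, i1c, drop = FALSE] * rep(f, each = nrow(m))
}

#' Forward-project a hyperspectral slice into a spectral sinogram
#'
#' Parallel-beam Beer-Lambert forward model: per energy channel, line
#' integrals `p = integral of mu ds` are computed by image rotation, then
#' (optionally) converted to photon counts `Poisson(i0 * exp(-p))`. The
#' detector model's energy blur, per-column gain errors and
#' centre-of-rotation shift are applied if configured.
#'
#' @param slice_mu 3D array `(y, x, energy)` of linear attenuation (mm^-1);
#'   must be square in-plane. The detector has one column per image column.
#' @param angles_deg Projection angles in degrees (>= 1 angle, strictly
#'   increasing).
#' @param axis An [energy_axis()] matching `dim(slice_mu)[3]`.
#' @param pitch_mm Detector pitch = in-plane voxel size, mm.
#' @param detector A [detector_model()].
#' @param mode `"counts"` for Poisson photon counts, `"line_integral"` for
#'   noiseless line integrals.
#' @return A [spectral_sinogram()].
#' @export
project <- function(slice_mu, angles_deg, axis, pitch_mm,
                    detector = detector_model(),
                    mode = c("line_integral", "counts")) {
  mode <- match.arg(mode)
  stopifnot(is.array(slice_mu), length(dim(slice_mu)) == 3L)
  d <- dim(slice_mu)
  if (d[1] != d[2]) stop("slice must be square in-plane")
  if (d[3] != axis$n_channels) stop("energy extent must match the axis")
  if (length(angles_deg) < 1L) stop("need at least one projection angle")

  n_ang <- length(angles_deg); n_det <- d[2]; nch <- d[3]
  p <- array(0, dim = c(n_ang, n_det, nch))
  for (a in seq_len(n_ang)) {
    st <- radon_stencil(d[1], d[2], angles_deg[a])
    for (ch in seq_len(nch)) {
      p[a, , ch] <- radon_apply(slice_mu[, , ch], st, d[1], d[2], pitch_mm)
    }
  }
  if (detector$cor_shift != 0) {
    for (ch in seq_len(nch)) {
      p[, , ch] <- shift_rows(matrix(p[, , ch], nrow = n_ang),
                              detector$cor_shift)
    }
  }

  sigma_ch <- detector$energy_fwhm_kev / (2 * sqrt(2 * log(2))) / axis$gain
  gains <- if (is.null(detector$pixel_gain_errors)) rep(1, n_det) else
    rep_len(detector$pixel_gain_errors, n_det)

  if (mode == "line_integral") {
    if (sigma_ch > 0) {
      flat <- matrix(p, nrow = n_ang * n_det, ncol = nch)
      # blur the transmitted intensity, the physical quantity the detector
      # sees, then convert back to line integrals
      flat <- -log(blur_energy(exp(-flat), sigma_ch))
      p <- array(flat, dim = dim(p))
    }
    if (any(gains != 1)) {
      # a column gain error biases -log(I/I0) additively
      p <- p - rep(log(gains), each = n_ang)
    }
    spectral_sinogram(p, angles_deg, pitch_mm, axis, mode = "line_integral")
  } else {
    lambda <- detector$i0 * exp(-p)
    if (sigma_ch > 0) {
      flat <- matrix(lambda, nrow = n_ang * n_det, ncol = nch)
      lambda <- array(blur_energy(flat, sigma_ch), dim = dim(p))
    }
    lambda <- lambda * rep(gains, each = n_ang)
    counts <- with_seed(detector$seed,
                        array(stats::rpois(length(lambda), lambda),
                              dim = dim(lambda)))
    spectral_sinogram(counts, angles_deg, pitch_mm, axis, mode = "counts")
  }
}

#' Convert a counts sinogram to line integrals
#'
#' Beer-Lambert inversion `p = -log(counts / i0)`; zero counts are floored
#' at half a count to keep the log finite.
#'
#' @param sino A [spectral_sinogram()] in counts mode.
#' @param i0 Incident counts per detector element per channel.
#' @return A [spectral_sinogram()] in line-integral mode.
#' @export
sinogram_to_line_integrals <- function(sino, i0) {
  stopifnot(inherits(sino, "spectral_sinogram"))
  if (sino$mode != "counts") return(sino)
  p <- -log(pmax(sino$data, 0.5) / i0)
  spectral_sinogram(p, sino$angles_deg, sino$pitch_mm, sino$axis,
                    mode = "line_integral")
}

#' Simulate per-pixel fluorescence calibration spectra
#'
#' Emulates the detector calibration acquisition: each pixel records a sum
#' of Gaussian photopeaks at known energies, positioned in channel space
#' under that pixel's own (perturbed) channel-to-energy response, with
#' Poisson counting noise. The per-pixel truth (gain, offset, FWHM) is
#' returned for use as ground truth.
#'
#' @param peak_energies_kev Photopeak energies in keV; all must lie within
#'   the axis range.
#' @param true_axis The global [energy_axis()].
#' @param n_pixels Number of detector pixels to simulate.
#' @param detector A [detector_model()] (supplies the default FWHM and the
#'   seed).
#' @param counts_per_peak Expected counts under each photopeak.
#' @param pixel_gains,pixel_offsets Optional per-pixel true gain (keV/ch)
#'   and offset (keV) vectors; default to the global axis values.
#' @param fwhm_kev Optional per-pixel energy resolution (FWHM, keV);
#'   defaults to `detector$energy_fwhm_kev`.
#' @param poisson Apply Poisson counting noise?
#' @return A list with `counts` (matrix, pixels x channels), `truth` (a
#'   tibble with per-pixel gain, offset and FWHM), and `axis`.
#' @export
simulate_calibration_spectra <- function(peak_energies_kev, true_axis,
                                         n_pixels = 1L,
                                         detector = detector_model(),
                                         counts_per_peak = 1e5,
                                         pixel_gains = NULL,
                                         pixel_offsets = NULL,
                                         fwhm_kev = NULL,
                                         poisson = TRUE) {
  stopifnot(inherits(true_axis, "energy_axis"))
  e_lo <- true_axis$offset
  e_hi <- true_axis$offset + true_axis$gain * (true_axis$n_channels - 1)
  if (any(peak_energies_kev < e_lo | peak_energies_kev > e_hi)) {
    stop("peak energy outside the axis range")
  }
  gains <- if (is.null(pixel_gains)) rep(true_axis$gain, n_pixels) else
    rep_len(pixel_gains, n_pixels)
  offsets <- if (is.null(pixel_offsets)) rep(true_axis$offset, n_pixels) else
    rep_len(pixel_offsets, n_pixels)
  fwhm <- if (is.null(fwhm_kev)) rep(detector$energy_fwhm_kev, n_pixels) else
    rep_len(fwhm_kev, n_pixels)

  nch <- true_axis$n_channels
  chans <- seq_len(nch)
  lambda <- matrix(0, n_pixels, nch)
  for (px in seq_len(n_pixels)) {
    sigma_ch <- fwhm[px] / (2 * sqrt(2 * log(2))) / gains[px]
    for (e in peak_energies_kev) {
      centre_ch <- (e - offsets[px]) / gains[px] + 1
      dens <- stats::dnorm(chans, mean = centre_ch, sd = max(sigma_ch, 1e-9))
      lambda[px, ] <- lambda[px, ] + counts_per_peak * dens /
        max(sum(dens), .Machine$double.eps)
    }
  }
  counts <- if (poisson) {
    with_seed(detector$seed,
              matrix(stats::rpois(length(lambda), lambda),
                     n_pixels, nch))
  } else lambda
  list(
    counts = counts,
    truth = tibble::tibble(pixel = seq_len(n_pixels), gain = gains,
                           offset = offsets, fwhm_kev = fwhm),
    axis = true_axis
  )
}
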