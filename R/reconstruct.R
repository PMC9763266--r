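#' Filtered back-projection of one sinogram
#'
#' Standard parallel-beam FBP: each projection is ramp-filtered in the
#' Fourier domain (optionally with a Shepp-Logan window) and back-projected
#' with linear interpolation. This is the package's deterministic
#' reconstruction stage; externally reconstructed volumes (e.g. from an
#' iterative TV-regularised pipeline) can be imported through the volume
#' container and analysed identically.
#'
#' @param sino Numeric matrix of line integrals, angles x detector columns.
#'   Counts must be converted first (see [sinogram_to_line_integrals()]).
#' @param angles_deg Projection angles in degrees.
#' @param pitch_mm Detector pitch in mm.
#' @param filter `"ramp"` (Ram-Lak) or `"shepp-logan"`.
#' @param output_size Side length of the reconstructed square image;
#'   defaults to the detector width.
#' @return Numeric matrix (y, x) of linear attenuation in mm^-1.
#' @export
fbp_slice <- function(sino, angles_deg, pitch_mm,
                      filter = c("ramp", "shepp-logan"),
                      output_size = ncol(sino)) {
  filter <- match.arg(filter)
  stopifnot(is.matrix(sino), nrow(sino) == length(angles_deg))
  if (min(sino) >= 0 && max(sino) > 100) {
    stop("sinogram looks like raw counts; convert to line integrals ",
         "(-log(I/I0)) before reconstruction")
  }
  n_det <- ncol(sino)
  n_ang <- nrow(sino)
  # zero-pad to the next power of two (>= 2 * n_det) for the FFT filter
  npad <- 2^ceiling(log2(2 * n_det))
  # ramp filter built from the spatial-domain Ram-Lak kernel (avoids the DC
  # bias of sampling |f| directly)
  kern <- numeric(npad)
  kern[1] <- 0.25
  odd <- seq(1, npad / 2, by = 2)
  kern[odd + 1] <- -1 / (pi * odd)^2
  kern[npad - odd + 1] <- -1 / (pi * odd)^2
  f_resp <- 2 * Re(stats::fft(kern))
  if (filter == "shepp-logan") {
    freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
    nz <- freq != 0
    f_resp[nz] <- f_resp[nz] * sin(pi * freq[nz]) / (pi * freq[nz])
  }
  padded <- matrix(0, npad, n_ang)
  padded[seq_len(n_det), ] <- t(sino)
  filtered <- Re(stats::mvfft(stats::mvfft(padded) * f_resp,
                              inverse = TRUE)) / npad
  filtered <- filtered[seq_len(n_det), , drop = FALSE]  # det x angle

  n <- output_size
  centre_img <- (n + 1) / 2
  centre_det <- (n_det + 1) / 2
  xs <- (seq_len(n) - centre_img)   # pixel units (pitch = voxel size)
  recon <- matrix(0, n, n)
  th <- angles_deg * pi / 180
  for (a in seq_len(n_ang)) {
    tpos <- outer(xs, xs, function(y, x) x * cos(th[a]) + y * sin(th[a])) +
      centre_det
    i0 <- floor(tpos); f <- tpos - i0
    i0c <- pmin(pmax(i0, 1L), n_det); i1c <- pmin(pmax(i0 + 1L, 1L), n_det)
    q <- filtered[, a]
    recon <- recon + q[i0c] * (1 - f) + q[i1c] * f
  }
  # pi / (2 n_ang) angular quadrature; 1/pitch converts the filtered
  # projections (sampled per detector element) back to mm^-1
  recon * pi / (2 * n_ang) / pitch_mm
}

#' Reconstruct a hyperspectral volume from per-slice spectral sinograms
#'
#' Loops [fbp_slice()] over z slices and energy channels. Deterministic:
#' the same input always yields the same volume.
#'
#' @param sinos A single [spectral_sinogram()] (one z slice) or a list of
#'   them (one per slice) with identical axes, angles and pitch.
#' @param voxel_size_um Voxel size recorded in the output volume; defaults
#'   to the detector pitch.
#' @param filter Passed to [fbp_slice()].
#' @param verbose Log per-channel progress?
#' @return A [hyperspectral_volume()] of shape (n_slice, n, n, channels).
#' @export
reconstruct_volume <- function(sinos, voxel_size_um = NULL,
                               filter = "ramp", verbose = FALSE) {
  if (inherits(sinos, "spectral_sinogram")) sinos <- list(sinos)
  s1 <- sinos[[1]]
  for (i in seq_along(sinos)) {
    si <- sinos[[i]]
    if (!inherits(si, "spectral_sinogram")) stop("slice ", i, ": not a spectral_sinogram")
    if (si$mode != "line_integral") {
      stop("slice ", i, ": convert counts to line integrals first")
    }
    if (!identical(dim(si$data), dim(s1$data)) ||
        !isTRUE(all.equal(si$angles_deg, s1$angles_deg)) ||
        si$axis$n_channels != s1$axis$n_channels) {
      stop("slice ", i, ": shape/angles/axis inconsistent with slice 1")
    }
  }
  n_det <- dim(s1$data)[2]
  nch <- s1$axis$n_channels
  nz <- length(sinos)
  vol <- array(0, dim = c(nz, n_det, n_det, nch))
  for (z in seq_len(nz)) {
    for (ch in seq_len(nch)) {
      vol[z, , , ch] <- fbp_slice(sinos[[z]]$data[, , ch], s1$angles_deg,
                                  s1$pitch_mm, filter = filter)
      if (verbose && ch %% 25 == 0) {
        message(sprintf("slice %d/%d: channel %d/%d", z, nz, ch, nch))
      }
    }
  }
  if (is.null(voxel_size_um)) voxel_size_um <- s1$pitch_mm * 1000
  hyperspectral_volume(vol, s1$axis, voxel_size_um)
}
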