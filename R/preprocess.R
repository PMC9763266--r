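#' Ring filter parameters
#'
#' Parameters of the combined wavelet-Fourier stripe suppression filter:
#' detector-axis wavelet decomposition depth, the width (in angle-frequency
#' index units) of the Gaussian used to damp stripe components, and the
#' wavelet family.
#'
#' @param decomposition_levels Wavelet levels (integer >= 1); the detector
#'   width must be divisible by `2^levels`.
#' @param damping_sigma Gaussian damping width along the angle-frequency
#'   axis (> 0). Larger values remove broader (slowly varying) stripes at
#'   the cost of more distortion of genuine structure.
#' @param wavelet One of `"db5"`, `"db2"`, `"haar"`.
#' @return An object of class `ring_filter_params`.
#' @export
ring_filter_params <- function(decomposition_levels = 3L, damping_sigma = 2.0,
                               wavelet = "db5") {
  stopifnot(decomposition_levels >= 1L, damping_sigma > 0)
  structure(list(decomposition_levels = as.integer(decomposition_levels),
                 damping_sigma = damping_sigma, wavelet = wavelet),
            class = "ring_filter_params")
}

# damp low angle-frequency components of a coefficient band (rows = angles)
damp_low_freq <- function(band, sigma) {
  n <- nrow(band)
  f_idx <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  damp <- 1 - exp(-f_idx^2 / (2 * sigma^2))
  ft <- stats::mvfft(band)
  Re(stats::mvfft(ft * damp, inverse = TRUE)) / n
}

#' Wavelet-Fourier ring-artifact suppression
#'
#' Removes stripe artifacts (the sinogram signature of miscalibrated
#' detector columns, which reconstruct as rings) from a single-channel
#' sinogram. Each angle row is wavelet-decomposed along the detector axis;
#' within each level's detail band, components that are nearly constant
#' along the angle axis — the fingerprint of a stripe — are damped by
#' `1 - exp(-f^2 / (2 sigma^2))` in angle-frequency space; the sinogram is
#' then reassembled by the inverse transforms.
#'
#' @param sino Numeric matrix, angles x detector columns (>= 8 angles).
#' @param params A [ring_filter_params()].
#' @return Filtered sinogram, same shape.
#' @export
remove_rings <- function(sino, params = ring_filter_params()) {
  stopifnot(is.matrix(sino))
  if (nrow(sino) < 8L) stop("ring filter needs at least 8 angles")
  n_det <- ncol(sino)
  L <- params$decomposition_levels
  if (n_det %% 2^L != 0 || n_det / 2^L < length(daubechies_filters(params$wavelet)$dec_lo) / 2) {
    stop(sprintf(
      "detector width %d incompatible with %d decomposition levels", n_det, L))
  }
  n_ang <- nrow(sino)
  # decompose every angle row once, collecting per-level detail matrices
  details <- vector("list", L)
  approx <- matrix(0, n_ang, n_det / 2^L)
  det_mats <- lapply(seq_len(L), function(l) matrix(0, n_ang, n_det / 2^l))
  for (a in seq_len(n_ang)) {
    w <- dwt_multilevel(sino[a, ], L, params$wavelet)
    approx[a, ] <- w$approx
    for (l in seq_len(L)) det_mats[[l]][a, ] <- w$details[[l]]
  }
  det_mats <- lapply(det_mats, damp_low_freq, sigma = params$damping_sigma)
  out <- matrix(0, n_ang, n_det)
  for (a in seq_len(n_ang)) {
    w <- list(approx = approx[a, ],
              details = lapply(det_mats, function(m) m[a, ]),
              wavelet = params$wavelet, levels = L)
    out[a, ] <- idwt_multilevel(w)
  }
  out
}

#' Estimate the centre-of-rotation offset of a sinogram
#'
#' The 0 degree projection and the mirrored 180 degree projection of the
#' same object coincide when the rotation axis projects onto the detector
#' centre; an axis offset `s` displaces them by `2s`. The offset is found
#' by maximising their cross-correlation over integer lags and refining
#' with parabolic sub-pixel interpolation.
#'
#' @param sino Numeric matrix, angles x detector columns, covering at least
#'   180 degrees.
#' @param angles_deg Projection angles in degrees, one per row.
#' @param max_shift Largest offset magnitude searched, detector columns.
#' @return Estimated offset in detector columns (positive = axis right of
#'   centre), sub-pixel.
#' @export
estimate_center_of_rotation <- function(sino, angles_deg,
                                        max_shift = floor(ncol(sino) / 4)) {
  stopifnot(is.matrix(sino), nrow(sino) == length(angles_deg))
  if (diff(range(angles_deg)) < 180) {
    stop("angle range must cover at least 180 degrees")
  }
  spacing <- if (length(angles_deg) > 1) stats::median(diff(angles_deg)) else Inf
  i0 <- which.min(abs(angles_deg - angles_deg[1]))
  target <- angles_deg[i0] + 180
  i180 <- which.min(abs(angles_deg - target))
  if (abs(angles_deg[i180] - target) > spacing / 2 + 1e-9) {
    stop("no projection at 180 degrees from the first angle; ",
         "interpolate the sinogram onto a grid containing an opposed pair")
  }
  p0 <- sino[i0, ]
  m <- rev(sino[i180, ])
  n <- length(p0)
  lags <- -(2 * max_shift):(2 * max_shift)
  cc <- vapply(lags, function(l) {
    # correlate p0 with m shifted right by l, over the overlap
    if (l >= 0) sum(p0[(1 + l):n] * m[1:(n - l)])
    else sum(p0[1:(n + l)] * m[(1 - l):n])
  }, numeric(1))
  b <- which.max(cc)
  lag <- lags[b]
  if (b > 1 && b < length(lags)) {
    den <- cc[b - 1] - 2 * cc[b] + cc[b + 1]
    if (den < 0) lag <- lag + 0.5 * (cc[b - 1] - cc[b + 1]) / den
  }
  lag / 2
}

#' Shift a sinogram along the detector axis
#'
#' Sub-pixel shift of every projection by linear interpolation; applying
#' `apply_cor_shift(sino, -estimate_center_of_rotation(...))` recentres the
#' rotation axis.
#'
#' @param sino Numeric matrix (angles x detector) or 3D spectral array.
#' @param shift Shift in detector columns (fractional allowed).
#' @return Shifted array, same shape.
#' @export
apply_cor_shift <- function(sino, shift) {
  if (is.matrix(sino)) return(shift_rows(sino, shift))
  stopifnot(length(dim(sino)) == 3L)
  out <- sino
  for (ch in seq_len(dim(sino)[3])) {
    out[, , ch] <- shift_rows(sino[, , ch], shift)
  }
  out
}

#' Preprocess a spectral sinogram
#'
#' Applies ring suppression (per energy channel, channels being
#' independent measurements) and optional centre-of-rotation correction to
#' a line-integral spectral sinogram.
#'
#' @param sino A [spectral_sinogram()] in line-integral mode.
#' @param ring_params A [ring_filter_params()], or `NULL` to skip.
#' @param correct_cor Estimate (on the energy-summed sinogram) and correct
#'   the centre-of-rotation offset?
#' @return A list: `sino` (processed [spectral_sinogram()]), `cor_offset`
#'   (estimated offset in columns, 0 when not corrected).
#' @export
preprocess_sinogram <- function(sino, ring_params = ring_filter_params(),
                                correct_cor = TRUE) {
  stopifnot(inherits(sino, "spectral_sinogram"))
  if (sino$mode != "line_integral") {
    stop("convert counts to line integrals first (sinogram_to_line_integrals)")
  }
  data <- sino$data
  if (!is.null(ring_params)) {
    for (ch in seq_len(dim(data)[3])) {
      data[, , ch] <- remove_rings(data[, , ch], ring_params)
    }
  }
  cor_offset <- 0
  if (correct_cor) {
    summed <- apply(data, c(1, 2), sum)
    cor_offset <- estimate_center_of_rotation(summed, sino$angles_deg)
    if (abs(cor_offset) > 1e-3) data <- apply_cor_shift(data, -cor_offset)
  }
  list(
    sino = spectral_sinogram(data, sino$angles_deg, sino$pitch_mm, sino$axis,
                             mode = "line_integral"),
    cor_offset = cor_offset
  )
}
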