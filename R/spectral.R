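#' K-edge subtraction window parameters
#'
#' KES uses two windows of `width` channels placed either side of the
#' K-edge channel, separated from it by `separation` guard channels. With
#' the edge channel `k` (the first channel whose centre energy reaches the
#' K-edge), the pre-edge window covers channels `(k - separation - width)`
#' to `(k - separation - 1)` and the post-edge window covers
#' `(k + separation)` to `(k + separation + width - 1)`, both inclusive.
#' The guard gap absorbs the finite width of measured absorption edges
#' (energy blur spreads the theoretical discontinuity over a few
#' channels). Defaults follow the values found optimal for iodine and
#' barium; for the broader measured tungsten edge use `separation = 10`
#' (see [default_kes_params()]).
#'
#' @param width Channels integrated per window (integer >= 1).
#' @param separation Guard channels between the edge channel and each
#'   window (integer >= 0).
#' @return An object of class `kes_params`.
#' @export
kes_params <- function(width = 5L, separation = 2L) {
  width <- as.integer(width); separation <- as.integer(separation)
  stopifnot(width >= 1L, separation >= 0L)
  structure(list(width = width, separation = separation),
            class = "kes_params")
}

#' Default KES parameters per element
#'
#' Width 5 / separation 2 channels for all elements except tungsten, whose
#' measured absorption edge is broader and gets separation 10.
#'
#' @param symbol Element symbol.
#' @return A [kes_params()].
#' @export
default_kes_params <- function(symbol) {
  if (identical(symbol, "W")) kes_params(5L, 10L) else kes_params(5L, 2L)
}

# channel index ranges of the pre/post windows around the edge channel k
kes_windows <- function(axis, k_edge_kev, params, what = "element") {
  k <- first_channel_at_or_above(axis, k_edge_kev)
  pre <- (k - params$separation - params$width):(k - params$separation - 1L)
  post <- (k + params$separation):(k + params$separation + params$width - 1L)
  if (min(pre) < 1L || max(post) > axis$n_channels) {
    stop(sprintf(
      "KES windows for %s (edge %.2f keV) fall outside the energy axis",
      what, k_edge_kev))
  }
  list(k = k, pre = pre, post = post)
}

#' K-edge subtraction map
#'
#' For every voxel, subtracts the mean attenuation in a narrow window just
#' below the element's K-edge from the mean in a window just above it.
#' Voxels containing the element show a positive attenuation change
#' (delta-mu); element-free voxels scatter around zero (slightly negative
#' for decreasing edge-free spectra). The output is signed — thresholding
#' into masks happens later, in [segment_elements()].
#'
#' @param vol A [hyperspectral_volume()].
#' @param elem An [element_record()].
#' @param params A [kes_params()]; defaults to the element's
#'   [default_kes_params()].
#' @return An object of class `element_map`: `delta_mu` (3D array, same
#'   attenuation units as the volume), `element`, `params`, `windows`.
#' @export
kes_map <- function(vol, elem, params = default_kes_params(elem$symbol)) {
  stopifnot(inherits(vol, "hyperspectral_volume"))
  w <- kes_windows(vol$axis, elem$k_edge_kev, params, elem$symbol)
  d <- dim(vol$data)
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  dm <- rowMeans(flat[, w$post, drop = FALSE]) -
    rowMeans(flat[, w$pre, drop = FALSE])
  structure(
    list(delta_mu = array(dm, dim = d[1:3]), element = elem$symbol,
         params = params, windows = w),
    class = "element_map"
  )
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s, delta-mu in [%.4g, %.4g] mm^-1\n",
              x$element, min(x$delta_mu), max(x$delta_mu)))
  invisible(x)
}

# OLS evaluation weights: weights w s.t. fitted line through (e, mu) points,
# evaluated at e0, equals sum(w * mu)
line_eval_weights <- function(e, e0) {
  n <- length(e)
  eb <- mean(e)
  sxx <- sum((e - eb)^2)
  if (sxx == 0) return(NULL)  # degenerate (single distinct abscissa)
  1 / n + (e0 - eb) * (e - eb) / sxx
}

#' Absorption-edge height of one spectrum
#'
#' Fits ordinary least-squares lines to the attenuation profile on each
#' side of the element's K-edge (over the same windows KES uses) and
#' extrapolates both to the K-edge energy. The difference between the
#' upper and lower line at the edge is the edge height, the
#' concentration-proportional quantity used for absolute quantification.
#'
#' @param spec An [attenuation_spectrum()].
#' @param elem An [element_record()].
#' @param params A [kes_params()] giving the fit window (`width`, >= 2
#'   channels so a line is determined) and guard separation.
#' @return A tibble (one row): `delta_mu0`, `lower_at_edge`,
#'   `upper_at_edge`, `slope_pre`, `slope_post`, `rss_pre`, `rss_post`,
#'   `valid`.
#' @export
edge_height <- function(spec, elem,
                        params = default_kes_params(elem$symbol)) {
  stopifnot(inherits(spec, "attenuation_spectrum"))
  if (params$width < 2L) stop("fit window needs width >= 2 (a line needs 2 points)")
  w <- kes_windows(spec$axis, elem$k_edge_kev, params, elem$symbol)
  e <- axis_energies(spec$axis)
  fit_side <- function(idx) {
    x <- e[idx]; y <- spec$mu[idx]
    f <- stats::lm.fit(cbind(1, x), y)
    list(at_edge = sum(f$coefficients * c(1, elem$k_edge_kev)),
         slope = f$coefficients[2], rss = sum(f$residuals^2))
  }
  lo <- fit_side(w$pre); hi <- fit_side(w$post)
  valid <- is.finite(lo$at_edge) && is.finite(hi$at_edge)
  tibble::tibble(
    delta_mu0 = hi$at_edge - lo$at_edge,
    lower_at_edge = lo$at_edge, upper_at_edge = hi$at_edge,
    slope_pre = unname(lo$slope), slope_post = unname(hi$slope),
    rss_pre = lo$rss, rss_post = hi$rss,
    valid = valid
  )
}

#' Voxel-wise edge-height map
#'
#' Applies the two-line edge-height estimator of [edge_height()] to every
#' voxel of a volume. Because the fit windows are fixed, the per-voxel OLS
#' extrapolations reduce to fixed linear weights over the window channels,
#' so the whole map is two matrix products. Voxels with non-finite results
#' are masked invalid, not zeroed.
#'
#' @inheritParams kes_map
#' @return An object of class `edge_height_map`: `delta_mu0` (3D array),
#'   `valid` (3D logical), `element`, `params`, `windows`.
#' @export
edge_height_map <- function(vol, elem,
                            params = default_kes_params(elem$symbol)) {
  stopifnot(inherits(vol, "hyperspectral_volume"))
  if (params$width < 2L) stop("fit window needs width >= 2")
  w <- kes_windows(vol$axis, elem$k_edge_kev, params, elem$symbol)
  e <- axis_energies(vol$axis)
  w_pre <- line_eval_weights(e[w$pre], elem$k_edge_kev)
  w_post <- line_eval_weights(e[w$post], elem$k_edge_kev)
  d <- dim(vol$data)
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  dm0 <- as.vector(flat[, w$post, drop = FALSE] %*% w_post -
                   flat[, w$pre, drop = FALSE] %*% w_pre)
  valid <- is.finite(dm0)
  structure(
    list(delta_mu0 = array(dm0, dim = d[1:3]),
         valid = array(valid, dim = d[1:3]),
         element = elem$symbol, params = params, windows = w),
    class = "edge_height_map"
  )
}

#' @export
print.edge_height_map <- function(x, ...) {
  cat(sprintf("<edge_height_map> %s, delta-mu0 in [%.4g, %.4g] mm^-1 (%d invalid voxels)\n",
              x$element, min(x$delta_mu0), max(x$delta_mu0), sum(!x$valid)))
  invisible(x)
}

#' Detect absorption edges in a spectrum
#'
#' Matches attenuation steps to the known K-edge positions of a table of
#' candidate elements. The spectrum is lightly smoothed (moving average),
#' forward-differenced, and for each element the candidate channel is the
#' largest positive difference within `tolerance_kev` of its K-edge. The
#' step counts as detected when its magnitude exceeds `mad_k` times the
#' MAD of the differences outside all edge search windows (a noise floor).
#'
#' @param spec An [attenuation_spectrum()].
#' @param table An [element_table()].
#' @param tolerance_kev Half-width of the search window around each
#'   K-edge, keV (must be at least one channel).
#' @param smooth_width Moving-average width in channels (odd).
#' @param mad_k Noise-threshold multiplier.
#' @return A tibble with one row per detected element: `symbol`,
#'   `k_edge_kev`, `detected_kev` (channel-centre energy of the step),
#'   `step_magnitude`, `threshold`.
#' @export
detect_edges <- function(spec, table = element_table(), tolerance_kev = 1.0,
                         smooth_width = 3L, mad_k = 5) {
  stopifnot(inherits(spec, "attenuation_spectrum"), tolerance_kev > 0)
  axis <- spec$axis
  if (tolerance_kev < axis$gain) {
    stop("tolerance smaller than one channel width")
  }
  mu <- spec$mu
  if (smooth_width > 1L) {
    k <- rep(1 / smooth_width, smooth_width)
    mu <- as.numeric(stats::filter(mu, k, sides = 2))
    # edges of the series: shrink the window instead of dropping channels
    half <- smooth_width %/% 2
    for (i in seq_len(half)) {
      mu[i] <- mean(spec$mu[1:(i + half)])
      j <- length(mu) - i + 1L
      mu[j] <- mean(spec$mu[(j - half):length(mu)])
    }
  }
  d <- diff(mu)  # d[i] = mu[i+1] - mu[i], the step onto channel i+1
  d_raw <- diff(spec$mu)
  e <- axis_energies(axis)
  in_any_window <- rep(FALSE, length(d))
  cand <- integer(nrow(table)); mag <- numeric(nrow(table))
  half <- max(1L, smooth_width %/% 2)
  for (i in seq_len(nrow(table))) {
    win <- which(abs(e[-1] - table$k_edge_kev[i]) <= tolerance_kev)
    in_any_window[win] <- TRUE
    if (length(win) == 0) { cand[i] <- NA_integer_; next }
    best <- win[which.max(d[win])]
    # smoothing spreads a sharp step over neighbouring differences; refine
    # the step channel on the raw differences near the smoothed candidate
    nb <- max(1L, best - half):min(length(d_raw), best + half)
    best <- nb[which.max(d_raw[nb])]
    cand[i] <- best
    mag[i] <- d[best]
  }
  noise <- d[!in_any_window]
  thr <- mad_k * stats::mad(noise)
  keep <- !is.na(cand) & mag > thr & mag > 0
  tibble::tibble(
    symbol = table$symbol[keep],
    k_edge_kev = table$k_edge_kev[keep],
    detected_kev = e[cand[keep] + 1L],
    step_magnitude = mag[keep],
    threshold = thr
  )
}

#' Segment element masks from KES or edge-height maps
#'
#' Thresholds each element's map into a voxel mask (default threshold:
#' `mad_k` times the MAD of the map, a robust background noise scale;
#' override with absolute values). Masks may overlap — multi-stained
#' voxels belong to several elements. The residual phase collects voxels
#' whose broadband mean attenuation is high (e.g. bone mineral) but that
#' belong to no element mask.
#'
#' @param maps List of `element_map` or `edge_height_map` objects with
#'   identical spatial shapes.
#' @param vol Optional [hyperspectral_volume()] used for the residual
#'   phase (its broadband mean attenuation); `NULL` skips the residual.
#' @param thresholds Optional named numeric vector of absolute thresholds
#'   per element symbol; defaults to the MAD rule per map.
#' @param mad_k MAD multiplier for the default thresholds.
#' @param residual_quantile Broadband attenuation quantile above which an
#'   unassigned voxel joins the residual phase.
#' @return A list: `masks` (named list of 3D logical arrays),
#'   `residual` (3D logical or `NULL`), `thresholds` (named numeric).
#' @export
segment_elements <- function(maps, vol = NULL, thresholds = NULL, mad_k = 5,
                             residual_quantile = 0.90) {
  vals <- lapply(maps, function(m) {
    if (inherits(m, "element_map")) m$delta_mu
    else if (inherits(m, "edge_height_map")) m$delta_mu0
    else stop("maps must be element_map or edge_height_map objects")
  })
  shp <- dim(vals[[1]])
  for (v in vals) if (!identical(dim(v), shp)) stop("maps have mismatched shapes")
  syms <- vapply(maps, function(m) m$element, character(1))
  thr <- vapply(seq_along(maps), function(i) {
    if (!is.null(thresholds) && syms[i] %in% names(thresholds)) {
      thresholds[[syms[i]]]
    } else {
      mad_k * stats::mad(as.vector(vals[[i]]), center = 0)
    }
  }, numeric(1))
  names(thr) <- syms
  masks <- lapply(seq_along(maps), function(i) vals[[i]] > thr[i])
  names(masks) <- syms
  residual <- NULL
  if (!is.null(vol)) {
    stopifnot(identical(dim(vol$data)[1:3], shp))
    broad <- apply(vol$data, c(1, 2, 3), mean)
    cut <- stats::quantile(broad, residual_quantile)
    any_elem <- Reduce(`|`, masks)
    residual <- broad > cut & !any_elem
  }
  list(masks = masks, residual = residual, thresholds = thr)
}
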