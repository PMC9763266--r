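#' Per-phase edge-height measurements
#'
#' Measures each calibration-phantom phase the way phantom data are
#' analysed: the mean edge height within the phase ROI is computed per z
#' slice (default: six slices through the phase depth), then averaged
#' across slices; the across-slice sample standard deviation becomes the
#' error bar.
#'
#' @param emap An [edge_height_map()].
#' @param rois Named list of [roi_box()]/[roi_cylinder()]/[roi_voxels()],
#'   one per phase; names identify the phases.
#' @param concentrations Known phase concentrations in mg/ml, same order
#'   as `rois`.
#' @param slices Integer z indices to measure; defaults to 6 slices spread
#'   evenly through the map depth (or all slices if fewer).
#' @return A tibble with one row per phase: `phase`, `concentration`,
#'   `mean_delta_mu0`, `sd_delta_mu0`, `n_slices`.
#' @export
measure_phases <- function(emap, rois, concentrations, slices = NULL) {
  stopifnot(inherits(emap, "edge_height_map"),
            length(rois) == length(concentrations))
  d <- dim(emap$delta_mu0)
  if (is.null(slices)) {
    n <- min(6L, d[1])
    slices <- unique(round(seq(1, d[1], length.out = n)))
  }
  slices <- as.integer(slices)
  if (length(slices) < 1L || any(slices < 1L | slices > d[1])) {
    stop("slice indices outside the map depth")
  }
  phase_names <- names(rois)
  if (is.null(phase_names)) phase_names <- paste0("phase", seq_along(rois))
  rows <- purrr::map2(rois, seq_along(rois), function(roi, i) {
    vox <- roi_voxel_indices(roi, d)
    per_slice <- vapply(slices, function(z) {
      sel <- vox[vox[, 1] == z, , drop = FALSE]
      if (nrow(sel) == 0L) {
        stop(sprintf("phase '%s': ROI empty in slice %d", phase_names[i], z))
      }
      vals <- emap$delta_mu0[sel]
      ok <- emap$valid[sel]
      if (!any(ok)) {
        stop(sprintf("phase '%s': no valid voxels in slice %d",
                     phase_names[i], z))
      }
      mean(vals[ok])
    }, numeric(1))
    tibble::tibble(
      phase = phase_names[i],
      concentration = concentrations[i],
      mean_delta_mu0 = mean(per_slice),
      sd_delta_mu0 = if (length(per_slice) > 1) stats::sd(per_slice) else 0,
      n_slices = length(per_slice)
    )
  })
  dplyr::bind_rows(rows)
}

#' Fit the concentration calibration line
#'
#' Ordinary least squares fit of edge height against known concentration,
#' `delta_mu0 = m * c + b`, across the phases of a calibration phantom.
#' The fitted line converts edge heights measured in a specimen into
#' absolute concentrations. The intercept is retained by default (set
#' `force_origin = TRUE` for the physically motivated zero-intercept
#' variant). A warning is issued for poor fits (R^2 < 0.95) or
#' non-positive slopes, which make the curve unusable for quantification.
#'
#' @param measurements A tibble from [measure_phases()] (columns
#'   `concentration`, `mean_delta_mu0`; >= 2 distinct concentrations).
#' @param element Element symbol recorded on the curve.
#' @param force_origin Force the intercept to zero?
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared`, `element`, `measurements` and the
#'   underlying `lm` fit.
#' @export
fit_calibration <- function(measurements, element = NA_character_,
                            force_origin = FALSE) {
  stopifnot(all(c("concentration", "mean_delta_mu0") %in% names(measurements)))
  c_ <- measurements$concentration
  y <- measurements$mean_delta_mu0
  if (length(unique(c_)) < 2L) {
    stop("need at least 2 distinct concentrations to fit a line")
  }
  fit <- if (force_origin) stats::lm(y ~ 0 + c_) else stats::lm(y ~ c_)
  cf <- stats::coef(fit)
  slope <- unname(cf["c_"])
  intercept <- if (force_origin) 0 else unname(cf["(Intercept)"])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  if (slope <= 0) warning("calibration slope is not positive; curve unusable")
  else if (r2 < 0.95) warning(sprintf("calibration fit is poor (R^2 = %.3f)", r2))
  structure(
    list(element = element, slope = slope, intercept = intercept,
         r_squared = r2, measurements = measurements, fit = fit,
         force_origin = force_origin),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: delta-mu0 = %.4g * c + %.4g (R^2 = %.4f, %d phases)\n",
    x$element, x$slope, x$intercept, x$r_squared, nrow(x$measurements)))
  invisible(x)
}

#' Tidy and summarise a calibration curve
#'
#' `tidy()` returns the per-phase measurements with fitted values and
#' residuals; `glance()` a one-row model summary.
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
tidy.calibration_curve <- function(x, ...) {
  dplyr::mutate(
    x$measurements,
    fitted = x$slope * .data$concentration + x$intercept,
    residual = .data$mean_delta_mu0 - .data$fitted
  )
}

#' @rdname tidy.calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    element = x$element, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_phases = nrow(x$measurements),
    force_origin = x$force_origin
  )
}

#' Predict concentration from edge height
#'
#' Inverts the calibration line: `c = (delta_mu0 - b) / m`.
#'
#' @param curve A [fit_calibration()] curve.
#' @param delta_mu0 Edge-height values (vectorised).
#' @return Concentrations in mg/ml (not clamped).
#' @export
predict_concentration <- function(curve, delta_mu0) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  (delta_mu0 - curve$intercept) / curve$slope
}

#' Voxel-wise absolute concentration map
#'
#' Applies a calibration curve to an edge-height map, converting every
#' valid voxel's edge height into mg/ml. Negative recovered
#' concentrations (noise voxels) are clamped to zero in the map, but the
#' pre-clamp values are kept in a diagnostics array so noise and
#' ring-artifact speckle remain inspectable. Invalid-fit voxels are
#' masked.
#'
#' @param emap An [edge_height_map()].
#' @param curve A [fit_calibration()] curve for the same element.
#' @return An object of class `concentration_volume`: `concentration` (3D
#'   array, mg/ml, clamped at 0), `raw` (pre-clamp values), `valid` (3D
#'   logical), `element`, `provenance`.
#' @export
concentration_map <- function(emap, curve) {
  stopifnot(inherits(emap, "edge_height_map"),
            inherits(curve, "calibration_curve"))
  if (!is.na(curve$element) && !identical(curve$element, emap$element)) {
    stop(sprintf("element mismatch: map is %s, curve is %s",
                 emap$element, curve$element))
  }
  raw <- (emap$delta_mu0 - curve$intercept) / curve$slope
  conc <- pmax(raw, 0)
  conc[!emap$valid] <- NA_real_
  structure(
    list(concentration = conc, raw = raw, valid = emap$valid,
         element = emap$element,
         provenance = list(
           curve = list(slope = curve$slope, intercept = curve$intercept,
                        r_squared = curve$r_squared),
           kes_params = emap$params)),
    class = "concentration_volume"
  )
}

#' @export
print.concentration_volume <- function(x, ...) {
  v <- x$concentration[x$valid]
  cat(sprintf("<concentration_volume> %s, %.4g-%.4g mg/ml (%d invalid voxels)\n",
              x$element, min(v), max(v), sum(!x$valid)))
  invisible(x)
}

#' Concentration distribution histogram and summary
#'
#' Voxel-by-voxel statistical breakdown of a concentration map: histogram
#' counts over unmasked voxels (counts always sum to the unmasked voxel
#' count) plus summary statistics.
#'
#' @param cvol A [concentration_map()] result.
#' @param bin_width Histogram bin width in mg/ml (> 0).
#' @param thresholds Concentrations for which the voxel fraction above
#'   each is reported.
#' @return A list: `histogram` (tibble `bin_lo`, `bin_hi`, `count`),
#'   `summary` (one-row tibble with min/max/median/mean and
#'   `frac_above_<t>` columns), `n_voxels`.
#' @export
concentration_histogram <- function(cvol, bin_width = 10,
                                    thresholds = numeric(0)) {
  stopifnot(inherits(cvol, "concentration_volume"), bin_width > 0)
  v <- cvol$concentration[cvol$valid]
  n_bins <- max(1L, ceiling((max(v) + 1e-12) / bin_width))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  h <- hist(v, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  # hist(right = FALSE) drops nothing, but the top edge is open: count any
  # voxel sitting exactly on the last break into the last bin
  counts <- h$counts
  counts[length(counts)] <- counts[length(counts)] + sum(v == max(breaks))
  s <- tibble::tibble(min = min(v), max = max(v), median = stats::median(v),
                      mean = mean(v))
  for (t in thresholds) s[[sprintf("frac_above_%g", t)]] <- mean(v > t)
  list(
    histogram = tibble::tibble(bin_lo = breaks[-length(breaks)],
                               bin_hi = breaks[-1], count = counts),
    summary = s,
    n_voxels = length(v)
  )
}

#' Multi-element stain-overlap report
#'
#' Labels every voxel with the set of elements whose concentration
#' exceeds a threshold and tabulates co-occurrence, quantifying where
#' stains overlap (e.g. iodine and tungsten co-staining in muscle).
#'
#' @param cvols List of co-registered [concentration_map()] results.
#' @param threshold Concentration threshold in mg/ml (scalar or named per
#'   element).
#' @return A list: `labels` (3D character array, elements joined by `+`,
#'   `""` for background), `table` (tibble `label`, `n_voxels`).
#' @export
overlap_report <- function(cvols, threshold = 1) {
  stopifnot(length(cvols) >= 1L)
  shp <- dim(cvols[[1]]$concentration)
  syms <- vapply(cvols, function(v) v$element, character(1))
  thr <- if (length(threshold) == 1L) stats::setNames(rep(threshold, length(syms)), syms)
  else threshold[syms]
  above <- lapply(seq_along(cvols), function(i) {
    cv <- cvols[[i]]
    if (!identical(dim(cv$concentration), shp)) {
      stop("concentration volumes have mismatched shapes")
    }
    a <- cv$concentration > thr[i]
    a[!cv$valid] <- FALSE
    a
  })
  labels <- array("", dim = shp)
  for (i in seq_along(above)) {
    labels[above[[i]]] <- ifelse(labels[above[[i]]] == "", syms[i],
                                 paste(labels[above[[i]]], syms[i], sep = "+"))
  }
  tab <- table(labels)
  list(
    labels = labels,
    table = tibble::tibble(
      label = ifelse(names(tab) == "", "background", names(tab)),
      n_voxels = as.integer(tab)
    )
  )
}

#' Standardised intensity rescaling and its concentration fit
#'
#' Conventional-CT style intensity calibration referenced to agarose and
#' air rather than water and air: a two-point affine rescale maps the air
#' ROI mean to 0 and the agarose ROI mean to `scale` (default 1).
#' `fit_intensity_calibration()` then fits intensity against phase
#' concentration by OLS, the single-energy analogue of the edge-height
#' calibration.
#'
#' @param vol3d 3D array of single-energy reconstructed intensities.
#' @param air_roi,agarose_roi [roi_box()]-style ROIs over pure air and
#'   pure agarose.
#' @param scale Value assigned to the agarose mean.
#' @return For `standardised_intensity()`: a list with `intensity` (3D
#'   array) and the two reference means. For
#'   `fit_intensity_calibration()`: a `calibration_curve` (with
#'   `mean_delta_mu0` holding mean standardised intensity).
#' @export
standardised_intensity <- function(vol3d, air_roi, agarose_roi, scale = 1) {
  stopifnot(is.array(vol3d), length(dim(vol3d)) == 3L)
  d <- dim(vol3d)
  air <- mean(vol3d[roi_voxel_indices(air_roi, d)])
  aga <- mean(vol3d[roi_voxel_indices(agarose_roi, d)])
  if (isTRUE(all.equal(air, aga))) {
    stop("air and agarose reference means are equal; cannot rescale")
  }
  list(intensity = (vol3d - air) / (aga - air) * scale,
       air_mean = air, agarose_mean = aga)
}

#' @rdname standardised_intensity
#' @param si A `standardised_intensity()` result.
#' @param rois Named list of phase ROIs.
#' @param concentrations Phase concentrations, mg/ml.
#' @export
fit_intensity_calibration <- function(si, rois, concentrations) {
  d <- dim(si$intensity)
  means <- vapply(rois, function(roi) {
    mean(si$intensity[roi_voxel_indices(roi, d)])
  }, numeric(1))
  m <- tibble::tibble(
    phase = if (is.null(names(rois))) paste0("phase", seq_along(rois))
            else names(rois),
    concentration = concentrations,
    mean_delta_mu0 = means, sd_delta_mu0 = 0, n_slices = d[1]
  )
  fit_calibration(m, element = NA_character_)
}
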