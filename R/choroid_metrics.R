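#' Extract choroid boundaries from a region mask
#'
#' Keeps the largest connected component of the mask, then traces the
#' RPE-C (upper) and C-S (lower) junctions per column with a half-pixel edge
#' convention: `upper = topmost region row - 0.5`,
#' `lower = bottommost region row + 0.5`, so a band occupying `t` rows has
#' `lower - upper = t` pixels of vertical extent. A 15-column moving-average
#' copy of the upper trace is retained for tangent estimation; the raw
#' traces are kept unchanged.
#'
#' @param region_mask logical/binary matrix.
#' @return An object of class `boundaries`: list with numeric vectors
#'   `upper`, `lower`, `upper_smooth` (NA outside `valid_columns`) and
#'   integer `valid_columns`.
#' @export
extract_boundaries <- function(region_mask) {
  region_mask <- as_mask(region_mask)
  if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(region_mask)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  W <- ncol(mask)
  upper <- rep(NA_real_, W)
  lower <- rep(NA_real_, W)
  for (j in seq_len(W)) {
    rows <- which(mask[, j])
    if (length(rows) > 0) {
      upper[j] <- min(rows) - 0.5
      lower[j] <- max(rows) + 0.5
    }
  }
  valid <- which(!is.na(upper))
  upper_smooth <- rep(NA_real_, W)
  half <- 7L  # 15-column moving average
  for (j in valid) {
    win <- intersect((j - half):(j + half), valid)
    upper_smooth[j] <- mean(upper[win])
  }
  structure(list(upper = upper, lower = lower, upper_smooth = upper_smooth,
                 valid_columns = valid, mask = mask),
            class = "boundaries")
}

#' Define the fovea-centred ETDRS region of interest
#'
#' Converts the 3-mm temporal and nasal half-width of the ETDRS macular grid
#' to pixels (`round(half_width_um / scale_x)`, half away from zero) and
#' clips the window to the image. Volume scans, which carry no fovea
#' annotation, are centred at the middle column.
#'
#' @param fovea_col 1-based fovea column (ignored for volume scans).
#' @param scale_x lateral microns per pixel.
#' @param width image width in columns.
#' @param scan_type scan type string; `"volume"` centres at the middle.
#' @param half_width_um ROI half-width in microns (default 3000, the ETDRS
#'   6000 x 6000 um grid).
#' @return An object of class `roi_window`: list with `center_col`,
#'   `col_lo`, `col_hi` (inclusive) and `half_width_um`.
#' @export
define_roi <- function(fovea_col, scale_x, width, scan_type = "hline",
                       half_width_um = 3000) {
  if (scale_x <= 0) stop("scale_x must be positive", call. = FALSE)
  center <- if (identical(scan_type, "volume")) width %/% 2L + 1L
            else as.integer(fovea_col)
  half_px <- as.integer(round_half_away(half_width_um / scale_x))
  structure(list(center_col = center,
                 col_lo = max(1L, center - half_px),
                 col_hi = min(as.integer(width), center + half_px),
                 half_width_um = half_width_um),
            class = "roi_window")
}

#' Choroidal thickness at three fovea-centred locations
#'
#' Measures point-source micron distances between the RPE-C and C-S
#' junctions, locally perpendicular to the RPE-C junction, at the ROI's
#' temporal edge, centre and nasal edge. The upper-boundary tangent is
#' estimated by a linear fit over +/-15 columns of the smoothed trace in
#' micron space; the inward normal ray is intersected with the linearly
#' interpolated lower boundary.
#'
#' @param bounds a [extract_boundaries()] result.
#' @param roi a [define_roi()] window.
#' @param scale_x,scale_y microns per pixel.
#' @return numeric vector of three thicknesses in microns (temporal, centre,
#'   nasal); a location with no measurable region yields 0, a ray that never
#'   meets the lower boundary yields NA with a warning.
#' @export
compute_thickness <- function(bounds, roi, scale_x, scale_y) {
  locs <- c(roi$col_lo, roi$center_col, roi$col_hi)
  valid <- bounds$valid_columns
  lower_x <- valid * scale_x
  lower_y <- bounds$lower[valid] * scale_y
  nv <- length(lower_x)
  # linear extrapolation beyond the valid span (end-segment slopes)
  interp_lower <- function(xs) {
    y <- approx(lower_x, lower_y, xout = xs, rule = 2)$y
    if (nv >= 2) {
      k <- min(15L, nv)
      sl_l <- unname(coef(lm(lower_y[1:k] ~ lower_x[1:k]))[2])
      sl_r <- unname(coef(lm(lower_y[(nv - k + 1):nv] ~
                               lower_x[(nv - k + 1):nv]))[2])
      left <- xs < lower_x[1]
      right <- xs > lower_x[nv]
      y[left] <- lower_y[1] + sl_l * (xs[left] - lower_x[1])
      y[right] <- lower_y[nv] + sl_r * (xs[right] - lower_x[nv])
    }
    y
  }
  vapply(locs, function(col) {
    if (!(col %in% valid)) return(0)
    win <- intersect((col - 15L):(col + 15L), valid)
    xf <- win * scale_x
    yf <- bounds$upper_smooth[win] * scale_y
    m <- if (length(win) >= 2 && var(xf) > 0) unname(coef(lm(yf ~ xf))[2]) else 0
    nvec <- c(-m, 1) / sqrt(1 + m^2)   # inward (downward) unit normal
    x0 <- col * scale_x
    y0 <- bounds$upper[col] * scale_y
    g <- function(s) {
      xs <- x0 + s * nvec[1]
      ys <- y0 + s * nvec[2]
      ys - interp_lower(xs)
    }
    smax <- sqrt((max(lower_x) - min(lower_x))^2 +
                   (max(lower_y, y0) - min(lower_y, y0))^2) + scale_y
    if (g(0) >= 0) return(max(0, bounds$lower[col] - bounds$upper[col]) * scale_y)
    if (g(smax) < 0) {
      warning("normal ray does not intersect the lower boundary at column ",
              col)
      return(NA_real_)
    }
    uniroot(g, c(0, smax), tol = 1e-9)$root
  }, numeric(1))
}

#' Choroidal area within the ROI
#'
#' Pixel counting: region pixels in the ROI columns times the physical pixel
#' area, in mm^2.
#'
#' @param region_mask logical/binary matrix.
#' @param roi a [define_roi()] window.
#' @param scale_x,scale_y microns per pixel.
#' @return area in mm^2.
#' @export
compute_area <- function(region_mask, roi, scale_x, scale_y) {
  region_mask <- as_mask(region_mask)
  n <- sum(region_mask[, roi$col_lo:roi$col_hi])
  n * scale_x * scale_y * 1e-6
}

#' Choroidal vascularity index within the ROI
#'
#' Hard mode binarizes both maps at their thresholds and returns the ratio
#' of vessel pixels to total choroid pixels in the ROI columns. Soft mode
#' keeps the probabilities:
#' `sum(vessel_prob * region_prob) / sum(region_prob)`, which reduces
#' exactly to the hard index on binary maps. `literal = TRUE` instead
#' divides by the nonvessel pixel count (vessel : nonvessel ratio), which is
#' unbounded above.
#'
#' @param region,vessel numeric matrices (probabilities or binary).
#' @param roi a [define_roi()] window.
#' @param mode `"hard"` or `"soft"`.
#' @param region_threshold,vessel_threshold binarization thresholds.
#' @param literal use the vessel : nonvessel ratio instead of vessel : total.
#' @return vascularity index (in `[0, 1]` unless `literal`).
#' @export
compute_vascular_index <- function(region, vessel, roi,
                                   mode = c("hard", "soft"),
                                   region_threshold = 0.5,
                                   vessel_threshold = 0.5,
                                   literal = FALSE) {
  mode <- match.arg(mode)
  if (!all(dim(region) == dim(vessel)))
    stop("region and vessel must have the same shape", call. = FALSE)
  cols <- roi$col_lo:roi$col_hi
  r <- region[, cols, drop = FALSE]
  v <- vessel[, cols, drop = FALSE]
  if (mode == "hard") {
    rb <- r >= region_threshold
    vb <- (v >= vessel_threshold) & rb
    if (sum(rb) == 0)
      stop("vascular index undefined: no choroid pixels in the ROI",
           call. = FALSE)
    if (literal) return(sum(vb) / sum(rb & !vb))
    sum(vb) / sum(rb)
  } else {
    denom <- sum(r)
    if (denom == 0)
      stop("vascular index undefined: no choroid probability mass in the ROI",
           call. = FALSE)
    if (literal) return(sum(v * r) / (denom - sum(v * r)))
    sum(v * r) / denom
  }
}

#' Derive all fovea-centred choroid metrics from a segmentation
#'
#' Extracts the fovea column from the fovea channel (falling back to the
#' image centre with a warning if the map is all zero), defines the ETDRS
#' ROI, binarizes the region and vessel maps, and computes three-point
#' perpendicular thickness, area, and hard plus soft vascularity index.
#' Peripapillary scans have no fovea-centred ROI: only the binarized masks
#' are returned, with the vessel channel thresholded at 0.25.
#'
#' @param scan a [bscan()].
#' @param seg a `segmentation_output` (fields `region_prob`, `vessel_prob`,
#'   `fovea_prob`).
#' @param region_threshold,vessel_threshold binarization thresholds for
#'   fovea-centred scans.
#' @param peripapillary_vessel_threshold vessel threshold for peripapillary
#'   scans.
#' @param cvi_literal report the vessel : nonvessel ratio instead of
#'   vessel : total.
#' @return For fovea-centred scans an object of class `choroid_metrics`:
#'   `thickness_um` (temporal/centre/nasal), `thickness_mean_um`,
#'   `area_mm2`, `cvi`, `soft_cvi`, `fovea_col`, `roi`, `flags`. For
#'   peripapillary scans a list with the binarized masks only.
#' @export
analyze_scan <- function(scan, seg,
                         region_threshold = 0.5, vessel_threshold = 0.5,
                         peripapillary_vessel_threshold = 0.25,
                         cvi_literal = FALSE) {
  stopifnot(inherits(scan, "bscan"))
  if (scan$scan_type == "peripapillary") {
    return(list(region_mask = seg$region_prob >= region_threshold,
                vessel_mask = (seg$vessel_prob >= peripapillary_vessel_threshold) &
                  (seg$region_prob >= region_threshold),
                metrics = NULL))
  }
  flags <- character(0)
  fovea_col <- tryCatch(extract_fovea_column(seg$fovea_prob),
                        error = function(e) {
                          warning("no fovea detected; falling back to the centre column")
                          NA_integer_
                        })
  if (is.na(fovea_col)) {
    fovea_col <- ncol(scan$image) %/% 2L + 1L
    flags <- c(flags, "fovea_fallback_center")
  }
  roi <- define_roi(fovea_col, scan$scale_x, ncol(scan$image), scan$scan_type)
  region_bin <- seg$region_prob >= region_threshold
  if (!any(region_bin))
    stop("empty region segmentation at threshold ", region_threshold,
         call. = FALSE)
  bounds <- extract_boundaries(region_bin)
  thickness <- compute_thickness(bounds, roi, scan$scale_x, scan$scale_y)
  area <- compute_area(bounds$mask, roi, scan$scale_x, scan$scale_y)
  cvi <- compute_vascular_index(region_bin, seg$vessel_prob >= vessel_threshold,
                                roi, mode = "hard", literal = cvi_literal)
  soft <- compute_vascular_index(seg$region_prob, seg$vessel_prob, roi,
                                 mode = "soft", literal = cvi_literal)
  structure(list(thickness_um = thickness,
                 thickness_mean_um = mean(thickness, na.rm = TRUE),
                 area_mm2 = area, cvi = cvi, soft_cvi = soft,
                 fovea_col = fovea_col, roi = roi, flags = flags),
            class = "choroid_metrics")
}

#' @export
print.choroid_metrics <- function(x, ...) {
  cat(sprintf("choroid metrics (fovea col %d, ROI cols %d..%d)\n",
              x$fovea_col, x$roi$col_lo, x$roi$col_hi))
  cat(sprintf("  thickness T/C/N: %.1f / %.1f / %.1f um (mean %.1f)\n",
              x$thickness_um[1], x$thickness_um[2], x$thickness_um[3],
              x$thickness_mean_um))
  cat(sprintf("  area: %.4f mm^2   CVI: %.4f   soft CVI: %.4f\n",
              x$area_mm2, x$cvi, x$soft_cvi))
  invisible(x)
}
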