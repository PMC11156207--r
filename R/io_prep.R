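DEVICES <- c("heidelberg_standard", "heidelberg_flex", "topcon_triton",
             "unknown")
SCAN_TYPES <- c("hline", "vline", "radial", "volume", "peripapillary")

#' Construct a B-scan object
#'
#' Bundles an intensity matrix with its physical pixel scaling and
#' acquisition metadata. Images are stored in `[0, 1]` with row 1 at the top
#' (vitreous side).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param scale_x,scale_y microns per pixel, lateral/axial.
#' @param device one of `"heidelberg_standard"`, `"heidelberg_flex"`,
#'   `"topcon_triton"`, `"unknown"`.
#' @param scan_type one of `"hline"`, `"vline"`, `"radial"`, `"volume"`,
#'   `"peripapillary"`.
#' @param eye optional `"OD"` or `"OS"`.
#' @return An object of class `bscan`.
#' @export
bscan <- function(image, scale_x = 9000 / 768, scale_y = 3.87,
                  device = "unknown", scan_type = "hline", eye = NULL) {
  stop_if_not_image(image)
  device <- match.arg(device, DEVICES)
  scan_type <- match.arg(scan_type, SCAN_TYPES)
  if (scale_x <= 0 || scale_y <= 0)
    stop("pixel scales must be positive", call. = FALSE)
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  if (scan_type == "peripapillary" && ncol(image) < nrow(image))
    stop("peripapillary scans must have width >= height", call. = FALSE)
  structure(list(image = image, scale_x = scale_x, scale_y = scale_y,
                 device = device, scan_type = scan_type, eye = eye,
                 zero_range = isTRUE(attr(image, "zero_range"))),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan %d x %d px, %.2f x %.2f um/px, %s (%s)\n",
              nrow(x$image), ncol(x$image), x$scale_x, x$scale_y,
              x$device, x$scan_type))
  invisible(x)
}

#' Load a B-scan from a PNG or TIFF file
#'
#' Reads an 8- or 16-bit grayscale or RGB raster, converts to luminance if
#' needed, and min-max scales intensities to `[0, 1]` per image. A constant
#' (zero-dynamic-range) image loads as all zeros with a warning and carries a
#' `zero_range` flag.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @inheritParams bscan
#' @return A [bscan()] object.
#' @export
load_bscan <- function(path, scale_x = 9000 / 768, scale_y = 3.87,
                       device = "unknown", scan_type = "hline", eye = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 3) {
    # luminance (Rec. 601) from the first three channels
    raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
  }
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("image has zero dynamic range; loaded as all zeros")
    img <- matrix(0, nrow(raw), ncol(raw))
    attr(img, "zero_range") <- TRUE
  } else {
    img <- (raw - rng[1]) / diff(rng)
  }
  bscan(img, scale_x, scale_y, device, scan_type, eye)
}

#' Gamma-correct an image to a target mean brightness
#'
#' Finds the exponent `gamma > 0` such that `mean(image^gamma)` equals
#' `target_mean`, by bisection on `log(gamma)`. The transform fixes 0 and 1,
#' so images taking only those values cannot be adjusted and are returned
#' unchanged when their mean already equals the target.
#'
#' @param image numeric matrix in `[0, 1]`, not constant.
#' @param target_mean desired mean in `(0, 1)`.
#' @param tol tolerance on the achieved mean.
#' @return The gamma-adjusted image, with the solved exponent attached as
#'   attribute `"gamma"`.
#' @export
gamma_to_target_mean <- function(image, target_mean, tol = 1e-4) {
  stop_if_not_image(image)
  if (target_mean <= 0 || target_mean >= 1)
    stop("target_mean must lie in (0, 1)", call. = FALSE)
  rng <- range(image)
  if (diff(rng) == 0) {
    if (abs(mean(image) - target_mean) <= tol) return(image)
    stop("constant image cannot be gamma-adjusted to a different mean",
         call. = FALSE)
  }
  f <- function(lg) mean(image^exp(lg)) - target_mean
  lo <- log(1e-3); hi <- log(1e3)
  flo <- f(lo); fhi <- f(hi)
  # mean(image^g) decreases in g; if the target is unreachable (e.g. an image
  # of pure 0s and 1s), return the closest endpoint
  if (flo <= 0) g <- 1e-3
  else if (fhi >= 0) g <- 1e3
  else g <- exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
  out <- image^g
  if (abs(mean(out) - target_mean) > max(tol, 1e-4) &&
      flo > 0 && fhi < 0)
    warning("gamma solve did not reach requested tolerance")
  attr(out, "gamma") <- g
  out
}

#' Adjust image contrast about its mean
#'
#' `clip(mean + factor * (image - mean), 0, 1)`, with the mean computed over
#' the whole image. `factor = 1` is the identity; constant images are
#' unchanged for any factor.
#'
#' @param image numeric matrix.
#' @param factor positive contrast factor.
#' @return The contrast-adjusted image.
#' @export
adjust_contrast <- function(image, factor) {
  stop_if_not_image(image)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  m <- mean(image)
  clip01(m + factor * (image - m))
}

#' Preprocess a Topcon 992 x 1024 B-scan to the common 768 x 768 geometry
#'
#' Removes 32 columns (16 from each side by default) and bilinearly resizes
#' to 768 x 768, rescaling the pixel sizes so the physical field of view is
#' preserved.
#'
#' @param image numeric matrix, 992 rows x 1024 columns.
#' @param scale_x,scale_y microns per pixel of the input.
#' @param crop_side `"both"` (16 left + 16 right), `"left"` or `"right"`
#'   (all 32 from one side).
#' @return A [bscan()] with a 768 x 768 image and updated scales. The column
#'   coordinate transform is attached as attribute `"col_transform"`, a
#'   function mapping input column indices to output column indices.
#' @export
preprocess_topcon <- function(image, scale_x = 9000 / 1024, scale_y = 2.6,
                              crop_side = c("both", "left", "right")) {
  stop_if_not_image(image)
  crop_side <- match.arg(crop_side)
  if (nrow(image) != 992 || ncol(image) != 1024)
    stop("expected a 992 x 1024 Topcon B-scan, got ",
         nrow(image), " x ", ncol(image), call. = FALSE)
  keep <- switch(crop_side,
                 both = 17:1008,
                 left = 33:1024,
                 right = 1:992)
  cropped <- image[, keep, drop = FALSE]
  out <- resize_bilinear(cropped, 768L, 768L)
  left_off <- switch(crop_side, both = 16L, left = 32L, right = 0L)
  col_transform <- function(col) (col - left_off - 0.5) * 768 / 992 + 0.5
  sx <- scale_x * 992 / 768
  sy <- scale_y * 992 / 768
  b <- bscan(clip01(out), sx, sy, device = "topcon_triton",
             scan_type = "radial")
  attr(b, "col_transform") <- col_transform
  b
}

# bilinear resize via EBImage (images are transposed to its x/y convention)
resize_bilinear <- function(image, h, w) {
  res <- EBImage::resize(EBImage::Image(t(image)), w = w, h = h,
                         filter = "bilinear")
  t(EBImage::imageData(res))
}
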