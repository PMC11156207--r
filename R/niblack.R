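#' Niblack configuration
#'
#' Parameters of the Niblack local-thresholding vessel baseline: a pixel is
#' vessel where its intensity falls strictly below
#' `local mean + k * local standard deviation` over a centred square window.
#' The defaults (window 51, k = -0.05) follow common practice for choroidal
#' vessel segmentation.
#'
#' @param window odd window size in pixels (>= 3).
#' @param k standard-deviation offset (typically negative).
#' @return An object of class `niblack_config`.
#' @export
niblack_config <- function(window = 51L, k = -0.05) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3", call. = FALSE)
  structure(list(window = window, k = k), class = "niblack_config")
}

#' Local windowed mean and standard deviation
#'
#' Per-pixel mean and population standard deviation over a centred
#' `window x window` neighbourhood, with reflection padding at the borders.
#' Computed with integral images, so cost is independent of window size.
#'
#' @param image numeric matrix.
#' @param window odd window size, at most `min(dim(image))`.
#' @return list with matrices `mean` and `sd`.
#' @export
local_stats <- function(image, window) {
  stop_if_not_image(image)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > min(dim(image)))
    stop("window larger than image", call. = FALSE)
  r <- (window - 1L) %/% 2L
  pad <- pad_reflect(image, r)
  # centre on the global mean so near-constant windows do not suffer
  # catastrophic cancellation in the sum-of-squares formula
  gm <- mean(pad)
  pad <- pad - gm
  n <- window^2
  s1 <- box_sum(pad, window)
  s2 <- box_sum(pad * pad, window)
  mu <- s1 / n
  varr <- pmax(s2 / n - mu^2, 0)
  list(mean = mu + gm, sd = sqrt(varr))
}

# reflect-pad a matrix by r pixels on every side (edge pixel not repeated)
pad_reflect <- function(x, r) {
  if (r == 0) return(x)
  H <- nrow(x); W <- ncol(x)
  ri <- c((r + 1):2, 1:H, (H - 1):(H - r))
  ci <- c((r + 1):2, 1:W, (W - 1):(W - r))
  x[ri, ci, drop = FALSE]
}

# sum over every window x window block of a padded matrix, via integral image
box_sum <- function(pad, window) {
  S <- matrix(0, nrow(pad) + 1, ncol(pad) + 1)
  S[-1, -1] <- apply(apply(pad, 2, cumsum), 1, cumsum) |> t()
  H <- nrow(pad) - window + 1L
  W <- ncol(pad) - window + 1L
  S[(1 + window):(H + window), (1 + window):(W + window)] -
    S[(1 + window):(H + window), 1:W] -
    S[1:H, (1 + window):(W + window)] +
    S[1:H, 1:W]
}

#' Niblack vessel segmentation
#'
#' Thresholds each pixel at `T = mean + k * sd` over the local window and
#' labels pixels with intensity strictly below `T` as vessel, restricted to
#' the choroidal region mask.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param region_mask logical/binary matrix of the choroidal region.
#' @param config a [niblack_config()].
#' @return logical vessel mask (subset of `region_mask`).
#' @export
segment_vessels_niblack <- function(image, region_mask,
                                    config = niblack_config()) {
  stop_if_not_image(image)
  region_mask <- as_mask(region_mask)
  st <- local_stats(image, config$window)
  thr <- st$mean + config$k * st$sd
  (image < thr) & region_mask
}
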