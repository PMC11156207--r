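#' Fovea target configuration
#'
#' Geometry of the smoothed fovea training target and of the triangular
#' filter used to read a fovea column back from a predicted probability map.
#' The target is a `target_height x target_width` window centred on the
#' fovea: the exact fovea pixel is 1, its whole column 0.95, and a column at
#' distance `d` gets `0.95 - d * column_decay`, floored at the one-sided
#' label-smoothing `background` value that fills the rest of the map.
#'
#' @param target_height,target_width window size in pixels (width odd).
#' @param peak value at the exact fovea pixel.
#' @param column_base value of the fovea column inside the window.
#' @param column_decay decrease per column of distance from the fovea.
#' @param background value of all pixels outside the window.
#' @param filter_width width of the triangular extraction filter (odd).
#' @return An object of class `fovea_target_config`.
#' @export
fovea_target_config <- function(target_height = 51L, target_width = 19L,
                                peak = 1.0, column_base = 0.95,
                                column_decay = 0.1, background = 0.01,
                                filter_width = 21L) {
  if (target_width %% 2 == 0) stop("target_width must be odd", call. = FALSE)
  if (filter_width %% 2 == 0) stop("filter_width must be odd", call. = FALSE)
  structure(list(target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 peak = peak, column_base = column_base,
                 column_decay = column_decay, background = background,
                 filter_width = as.integer(filter_width)),
            class = "fovea_target_config")
}

#' Build the smoothed fovea training target
#'
#' @param shape `c(H, W)` of the output grid.
#' @param fovea_col,fovea_row 1-based fovea coordinates.
#' @param config a [fovea_target_config()].
#' @return H x W numeric matrix.
#' @export
build_fovea_target <- function(shape, fovea_col, fovea_row,
                               config = fovea_target_config()) {
  H <- shape[1]; W <- shape[2]
  if (fovea_col < 1 || fovea_col > W || fovea_row < 1 || fovea_row > H)
    stop("fovea coordinates out of range", call. = FALSE)
  cfg <- config
  out <- matrix(cfg$background, H, W)
  half_w <- (cfg$target_width - 1L) %/% 2L
  half_h <- (cfg$target_height - 1L) %/% 2L
  cols <- max(1L, fovea_col - half_w):min(W, fovea_col + half_w)
  rows <- max(1L, fovea_row - half_h):min(H, fovea_row + half_h)
  for (j in cols) {
    d <- abs(j - fovea_col)
    out[rows, j] <- max(cfg$column_base - d * cfg$column_decay,
                        cfg$background)
  }
  out[fovea_row, fovea_col] <- cfg$peak
  out
}

# symmetric triangular kernel of odd width, normalized to sum 1
triangular_kernel <- function(width) {
  half <- (width + 1L) %/% 2L
  k <- c(seq_len(half), rev(seq_len(half - 1L)))
  k / sum(k)
}

#' Extract the fovea column from a predicted fovea probability map
#'
#' Sums each column, convolves the column sums with a symmetric triangular
#' filter (zero padding, same-length output) and returns the argmax; ties
#' break to the lowest index.
#'
#' @param fovea_prob numeric matrix of fovea probabilities.
#' @param config a [fovea_target_config()] (only `filter_width` is used).
#' @return 1-based column index.
#' @export
extract_fovea_column <- function(fovea_prob, config = fovea_target_config()) {
  stop_if_not_image(fovea_prob)
  if (all(fovea_prob == 0)) stop("all-zero fovea map: no fovea detected",
                                 call. = FALSE)
  cs <- colSums(fovea_prob)
  filt <- filter_same(cs, triangular_kernel(config$filter_width))
  which.max(filt)
}

#' Extract the fovea row from a predicted fovea probability map
#'
#' Companion to [extract_fovea_column()]: applies the same triangular filter
#' to the row-wise sums and takes the argmax. The row is needed only to
#' centre the target window during training.
#'
#' @inheritParams extract_fovea_column
#' @return 1-based row index.
#' @export
extract_fovea_row <- function(fovea_prob, config = fovea_target_config()) {
  stop_if_not_image(fovea_prob)
  if (all(fovea_prob == 0)) stop("all-zero fovea map: no fovea detected",
                                 call. = FALSE)
  rs <- rowSums(fovea_prob)
  filt <- filter_same(rs, triangular_kernel(config$filter_width))
  which.max(filt)
}

# 1-D convolution with zero padding and same-length output
filter_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  padded <- c(rep(0, half), x, rep(0, half))
  out <- numeric(length(x))
  for (i in seq_along(x))
    out[i] <- sum(padded[i:(i + length(kernel) - 1L)] * kernel)
  out
}
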