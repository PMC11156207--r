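#' Dice coefficient between a probability map and a binary mask
#'
#' `2 TP / (2 TP + FP + FN)` after thresholding the prediction. When both
#' masks are empty the score is defined as 1 (perfect agreement on the empty
#' segmentation).
#'
#' @param pred numeric probability matrix (or binary mask).
#' @param gt binary ground-truth matrix.
#' @param threshold binarization threshold for `pred`.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(pred, gt, threshold = 0.5) {
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt must have the same shape", call. = FALSE)
  p <- pred >= threshold
  g <- as_mask(gt)
  tp <- sum(p & g)
  denom <- 2 * tp + sum(p & !g) + sum(!p & g)
  if (denom == 0) return(1.0)
  2 * tp / denom
}

#' Area under the ROC curve over pixels
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param pred numeric probability matrix.
#' @param gt binary ground-truth matrix containing both classes.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt must have the same shape", call. = FALSE)
  g <- as.vector(as_mask(gt))
  p <- as.vector(pred)
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: ground truth contains a single class", call. = FALSE)
  r <- rank(p, ties.method = "average")
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Agreement statistics between two paired measurement series
#'
#' Pearson and Spearman correlations, mean and median absolute error,
#' intraclass correlation ICC(2,1) (two-way random effects, absolute
#' agreement, single measurement) and Bland-Altman mean difference with 95%
#' limits of agreement (`mean difference +/- 1.96 SD`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `agreement_report` with fields `pearson`,
#'   `spearman`, `mae`, `median_ae`, `icc`, and `bland_altman`
#'   (`mean_diff`, `lower`, `upper`). Correlation fields are `NA` when
#'   either series has zero variance.
#' @export
agreement_stats <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  zero_var <- sd(x) == 0 || sd(y) == 0
  pearson <- if (zero_var) NA_real_ else cor(x, y)
  spearman <- if (zero_var) NA_real_ else cor(x, y, method = "spearman")
  d <- y - x
  icc <- if (zero_var && sd(x) == 0 && sd(y) == 0 && all(d == d[1])) {
    if (all(d == 0)) 1.0 else NA_real_
  } else icc21(x, y)
  out <- list(pearson = pearson, spearman = spearman,
              mae = mean(abs(d)), median_ae = median(abs(d)),
              icc = icc,
              bland_altman = list(mean_diff = mean(d),
                                  lower = mean(d) - 1.96 * sd(d),
                                  upper = mean(d) + 1.96 * sd(d)))
  class(out) <- "agreement_report"
  out
}

# ICC(2,1), two-way random effects, absolute agreement, single measurement
icc21 <- function(x, y) {
  n <- length(x)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("pearson %.4f  spearman %.4f  MAE %.4g  median AE %.4g  ICC %.4f\n",
              x$pearson, x$spearman, x$mae, x$median_ae, x$icc))
  cat(sprintf("Bland-Altman: mean diff %.4g [%.4g, %.4g]\n",
              x$bland_altman$mean_diff, x$bland_altman$lower,
              x$bland_altman$upper))
  invisible(x)
}
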