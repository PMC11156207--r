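#' MMCQ configuration
#'
#' Parameters of multiscale median-cut quantization (MMCQ) vessel
#' segmentation: patchwise local contrast enhancement (median-cut
#' quantization followed by histogram equalization) at several scales, then
#' a single global median cut over the enhanced choroidal pixels with the
#' darkest clusters labelled as vasculature.
#'
#' `n_vessel_clusters / n_global_clusters` acts as the prior vessel fraction:
#' clusters are selected dark-to-bright until their cumulative pixel count
#' best approaches that fraction of the region.
#'
#' @param patch_sizes patch edge lengths in pixels, coarse to fine.
#' @param quant_bits median-cut depth per patch (2^bits clusters).
#' @param n_global_clusters clusters in the global cut.
#' @param n_vessel_clusters darkest clusters labelled vessel.
#' @param blend_mode how per-scale enhanced maps are combined.
#' @return An object of class `mmcq_config`.
#' @export
mmcq_config <- function(patch_sizes = c(192L, 96L, 48L), quant_bits = 3L,
                        n_global_clusters = 8L, n_vessel_clusters = 4L,
                        blend_mode = "mean_across_scales") {
  patch_sizes <- as.integer(patch_sizes)
  if (length(patch_sizes) == 0 || any(diff(patch_sizes) >= 0))
    stop("patch_sizes must be nonempty and strictly descending", call. = FALSE)
  if (n_vessel_clusters < 1 || n_vessel_clusters >= n_global_clusters)
    stop("need 1 <= n_vessel_clusters < n_global_clusters", call. = FALSE)
  if (2^quant_bits < 2) stop("quant_bits must be >= 1", call. = FALSE)
  structure(list(patch_sizes = patch_sizes, quant_bits = as.integer(quant_bits),
                 n_global_clusters = as.integer(n_global_clusters),
                 n_vessel_clusters = as.integer(n_vessel_clusters),
                 blend_mode = match.arg(blend_mode, "mean_across_scales")),
            class = "mmcq_config")
}

#' Ensemble configuration for vessel ground-truth generation
#'
#' The 25-variant perturbation ensemble: five linearly spaced gamma-target
#' mean brightnesses in `[0.2, 0.5]` crossed with five linearly spaced
#' contrast factors in `[0.5, 3]`. A pixel is labelled vessel when at least
#' `vote_threshold` of the 25 variants vote for it; the default 15/25 reads
#' the 3:2 majority as a 60% vote ratio.
#'
#' @param brightness_targets gamma-target means.
#' @param contrast_factors contrast factors.
#' @param vote_threshold votes required for a vessel label.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(brightness_targets = seq(0.2, 0.5, length.out = 5),
                            contrast_factors = seq(0.5, 3, length.out = 5),
                            vote_threshold = 15L) {
  n <- length(brightness_targets) * length(contrast_factors)
  if (vote_threshold < 1 || vote_threshold > n)
    stop("vote_threshold must lie in [1, ", n, "]", call. = FALSE)
  structure(list(brightness_targets = brightness_targets,
                 contrast_factors = contrast_factors,
                 vote_threshold = as.integer(vote_threshold)),
            class = "ensemble_config")
}

#' Median-cut quantization of a value set
#'
#' Recursively splits the bucket with the largest intensity range at its
#' median (values `<=` median go left; if that would leave the right side
#' empty, the split is strict) until `2^bits` buckets exist or no bucket with
#' at least two values and positive range remains.
#'
#' @param values nonempty numeric vector.
#' @param bits split depth (>= 1); at most `2^bits` clusters.
#' @return list with `labels` (per-value cluster index, in creation order),
#'   `cluster_means`, and `cluster_order` (cluster indices sorted by
#'   ascending mean).
#' @export
median_cut <- function(values, bits) {
  if (length(values) == 0) stop("values must be nonempty", call. = FALSE)
  if (bits < 1) stop("bits must be >= 1", call. = FALSE)
  n_target <- 2^bits
  buckets <- list(seq_along(values))
  ranges <- diff(range(values))
  repeat {
    if (length(buckets) >= n_target) break
    splittable <- which(vapply(buckets, length, 1L) >= 2 & ranges > 0)
    if (length(splittable) == 0) break
    bi <- splittable[which.max(ranges[splittable])]
    idx <- buckets[[bi]]
    v <- values[idx]
    m <- median(v)
    left <- v <= m
    if (all(left)) left <- v < m
    buckets[[bi]] <- idx[left]
    buckets[[length(buckets) + 1]] <- idx[!left]
    ranges[bi] <- diff(range(values[buckets[[bi]]]))
    ranges[length(buckets)] <- diff(range(values[buckets[[length(buckets)]]]))
  }
  labels <- integer(length(values))
  for (i in seq_along(buckets)) labels[buckets[[i]]] <- i
  means <- vapply(buckets, function(ix) mean(values[ix]), numeric(1))
  list(labels = labels, cluster_means = means,
       cluster_order = order(means))
}

#' Histogram-equalize a patch
#'
#' Classical equalization through the empirical CDF: each value `v` maps to
#' the fraction of patch values `<= v`, so outputs lie in `(0, 1]` and are a
#' monotone nondecreasing transform of the input ranks. Constant patches are
#' returned unchanged (the CDF is degenerate).
#'
#' @param patch numeric matrix or vector.
#' @return equalized patch of the same shape.
#' @export
equalize_patch <- function(patch) {
  if (length(patch) == 0) stop("patch must be nonempty", call. = FALSE)
  if (diff(range(patch)) == 0) return(patch)
  out <- patch
  r <- rank(as.vector(patch), ties.method = "max") / length(patch)
  out[] <- r
  out
}

#' Multiscale patchwise contrast enhancement
#'
#' For each patch size, tiles the bounding box of the region with square
#' patches (edge patches truncated), quantizes the region pixels of each
#' patch by median cut and histogram-equalizes the quantized values, then
#' averages the enhanced maps across scales. Pixels outside `region_mask`
#' are returned unchanged.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param region_mask logical/binary region mask, nonempty.
#' @param config an [mmcq_config()].
#' @return enhanced image in `[0, 1]`.
#' @export
enhance_multiscale <- function(image, region_mask, config = mmcq_config()) {
  stop_if_not_image(image)
  region_mask <- as_mask(region_mask)
  if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
  rr <- range(which(rowSums(region_mask) > 0))
  cr <- range(which(colSums(region_mask) > 0))
  acc <- matrix(0, nrow(image), ncol(image))
  for (ps in config$patch_sizes) {
    scale_map <- image
    r_starts <- seq(rr[1], rr[2], by = ps)
    c_starts <- seq(cr[1], cr[2], by = ps)
    for (r0 in r_starts) {
      r1 <- min(r0 + ps - 1L, rr[2])
      for (c0 in c_starts) {
        c1 <- min(c0 + ps - 1L, cr[2])
        sub_mask <- region_mask[r0:r1, c0:c1, drop = FALSE]
        if (!any(sub_mask)) next
        vals <- image[r0:r1, c0:c1, drop = FALSE][sub_mask]
        if (diff(range(vals)) == 0) next
        mc <- median_cut(vals, config$quant_bits)
        quant <- mc$cluster_means[mc$labels]
        enh <- equalize_patch(quant)
        block <- scale_map[r0:r1, c0:c1, drop = FALSE]
        block[sub_mask] <- enh
        scale_map[r0:r1, c0:c1] <- block
      }
    }
    acc <- acc + scale_map
  }
  out <- acc / length(config$patch_sizes)
  out[!region_mask] <- image[!region_mask]
  clip01(out)
}

# select the darkest clusters whose cumulative pixel count best approaches
# the target fraction of region pixels (always at least one cluster)
select_dark_clusters <- function(mc, target_frac) {
  counts <- tabulate(mc$labels, nbins = length(mc$cluster_means))
  n <- sum(counts)
  ordered <- mc$cluster_order
  cum <- 0
  chosen <- integer(0)
  for (ci in ordered) {
    new_cum <- cum + counts[ci]
    if (length(chosen) > 0 &&
        abs(new_cum / n - target_frac) >= abs(cum / n - target_frac)) break
    chosen <- c(chosen, ci)
    cum <- new_cum
  }
  chosen
}

#' MMCQ vessel segmentation (single pass)
#'
#' Enhances the choroidal pixels with [enhance_multiscale()], clusters the
#' enhanced region pixels with one global median cut, and labels the darkest
#' clusters as vasculature. Cluster selection proceeds dark-to-bright until
#' the cumulative pixel count best approaches
#' `n_vessel_clusters / n_global_clusters` of the region.
#'
#' If the whole region has constant intensity, clustering is uninformative;
#' the leading region pixels (in column-major order) up to the target
#' fraction are returned, flagged with attribute `low_confidence`.
#'
#' @param image numeric matrix in `[0, 1]` (or a [bscan()]).
#' @param region_mask logical/binary region mask.
#' @param config an [mmcq_config()].
#' @return logical vessel mask (subset of `region_mask`).
#' @export
segment_vessels_mmcq <- function(image, region_mask, config = mmcq_config()) {
  if (inherits(image, "bscan")) image <- image$image
  stop_if_not_image(image)
  region_mask <- as_mask(region_mask)
  if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
  cfg <- config
  rr <- range(which(rowSums(region_mask) > 0))
  cr <- range(which(colSums(region_mask) > 0))
  reg_h <- diff(rr) + 1L; reg_w <- diff(cr) + 1L
  if (min(reg_h, reg_w) < min(cfg$patch_sizes)) {
    warning("region smaller than the smallest patch; using a single global pass")
    cfg$patch_sizes <- max(reg_h, reg_w)
  }
  target_frac <- cfg$n_vessel_clusters / cfg$n_global_clusters
  vals_raw <- image[region_mask]
  out <- matrix(FALSE, nrow(image), ncol(image))
  if (diff(range(vals_raw)) == 0) {
    k <- round(target_frac * length(vals_raw))
    idx <- which(region_mask)[seq_len(k)]
    out[idx] <- TRUE
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  enhanced <- enhance_multiscale(image, region_mask, cfg)
  vals <- enhanced[region_mask]
  bits <- ceiling(log2(cfg$n_global_clusters))
  mc <- median_cut(vals, bits)
  dark <- select_dark_clusters(mc, target_frac)
  out[region_mask] <- mc$labels %in% dark
  if (length(unique(round(mc$cluster_means, 12))) == 1)
    attr(out, "low_confidence") <- TRUE
  out
}

#' Perturbation-ensemble majority-vote vessel segmentation
#'
#' Runs MMCQ on every brightness/contrast variant of the scan (gamma
#' correction to each target mean, then contrast adjustment by each factor)
#' and labels a pixel vessel when at least `vote_threshold` variants agree.
#' The vote is monotone: adding a vessel vote at a pixel can never flip it
#' from vessel to background.
#'
#' @param image numeric matrix in `[0, 1]` (or a [bscan()]).
#' @param region_mask logical/binary region mask.
#' @param mmcq_config an [mmcq_config()].
#' @param ens an [ensemble_config()].
#' @return logical vessel mask with the per-pixel vote count attached as
#'   attribute `"votes"`.
#' @export
ensemble_majority_vote <- function(image, region_mask,
                                   mmcq_config = choroidseg::mmcq_config(),
                                   ens = ensemble_config()) {
  if (inherits(image, "bscan")) image <- image$image
  stop_if_not_image(image)
  region_mask <- as_mask(region_mask)
  votes <- matrix(0L, nrow(image), ncol(image))
  for (bt in ens$brightness_targets) {
    bright <- gamma_to_target_mean(image, bt)
    for (cf in ens$contrast_factors) {
      variant <- adjust_contrast(bright, cf)
      m <- segment_vessels_mmcq(variant, region_mask, mmcq_config)
      votes <- votes + m
    }
  }
  out <- votes >= ens$vote_threshold
  attr(out, "votes") <- votes
  out
}
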