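# Shared fixtures: small synthetic phantoms and brute-force oracles.

# 256 x 256 phantom with a ~90 px choroid band: the default study conditions
# of the generator at a reduced lateral field of view (vessel count scaled
# with width to keep the planted vessel fraction at ~0.5, as at full width)
make_phantom <- function(seed, speckle = 0.05, vessel_count = 50,
                         height = 256, width = 256, tilt = 0) {
  generate_bscan(generator_config(height = height, width = width,
                                  vessel_count = vessel_count,
                                  speckle_sigma = speckle,
                                  tilt_degrees = tilt, seed = seed))
}

# 128 x 128 training-scale generator config (thinner choroid so that the
# retina, band and sclera all fit in 128 rows)
train_fixture_config <- function(seed) {
  generator_config(height = 128, width = 128, choroid_mean_thickness = 180,
                   choroid_thickness_variation = 0.1, vessel_count = 25,
                   fovea_pit_depth = 80, speckle_sigma = 0.05, seed = seed)
}

# brute-force windowed mean/sd oracle (population sd, reflection padding)
oracle_local_stats <- function(image, window) {
  r <- (window - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  ri <- c((r + 1):2, 1:H, (H - 1):(H - r))
  ci <- c((r + 1):2, 1:W, (W - 1):(W - r))
  pad <- image[ri, ci, drop = FALSE]
  mu <- matrix(0, H, W); sdv <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    win <- pad[i:(i + 2 * r), j:(j + 2 * r)]
    mu[i, j] <- mean(win)
    sdv[i, j] <- sqrt(mean((win - mean(win))^2))
  }
  list(mean = mu, sd = sdv)
}

# brute-force reference for median_cut: repeatedly rescans all buckets for
# the widest intensity range (earliest bucket on ties), splits it at its
# median (<= median left, strict split if the right side would be empty),
# until 2^bits buckets exist or nothing splittable remains
oracle_median_cut <- function(values, bits) {
  buckets <- list(seq_along(values))
  repeat {
    if (length(buckets) >= 2^bits) break
    widths <- vapply(buckets, function(ix) {
      v <- values[ix]
      if (length(ix) < 2) -1 else max(v) - min(v)
    }, numeric(1))
    if (all(widths <= 0)) break
    bi <- which.max(widths)
    v <- values[buckets[[bi]]]
    m <- median(v)
    take <- v <= m
    if (all(take)) take <- v < m
    new_buckets <- list(buckets[[bi]][take], buckets[[bi]][!take])
    buckets <- append(buckets[-bi], new_buckets)
  }
  labels <- integer(length(values))
  for (i in seq_along(buckets)) labels[buckets[[i]]] <- i
  labels
}

# exhaustive pair-counting AUC oracle with half-credit for ties
oracle_auc <- function(pred, gt) {
  p <- as.vector(pred); g <- as.vector(gt) > 0.5
  pos <- p[g]; neg <- p[!g]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

expect_same_partition <- function(l1, l2) {
  # same partition up to label permutation
  expect_equal(length(l1), length(l2))
  key1 <- match(l1, unique(l1))
  key2 <- match(l2, unique(l2))
  expect_identical(key1, key2)
}

with_seed_for_tests <- function(seed, code) {
  choroidseg:::with_seed(seed, code)
}
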