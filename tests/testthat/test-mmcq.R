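test_that("median_cut handles canonical and degenerate inputs", {
  r <- median_cut(c(0, 0, 0, 1, 1, 1), bits = 1)
  expect_same_partition(r$labels, c(1, 1, 1, 2, 2, 2))
  expect_equal(sort(r$cluster_means), c(0, 1))
  expect_equal(r$cluster_means[r$cluster_order],
               sort(r$cluster_means))

  r2 <- median_cut(rep(0.4, 10), bits = 3)
  expect_equal(length(r2$cluster_means), 1)
  expect_true(all(r2$labels == 1))

  expect_error(median_cut(numeric(0), 1), "nonempty")
})

test_that("median_cut agrees with the recursive oracle on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    v <- runif(16)
    r <- median_cut(v, bits = 2)
    expect_same_partition(r$labels, oracle_median_cut(v, 2))
  }
  # larger random cases, varying sizes and depths
  for (i in 1:20) {
    n <- sample(8:64, 1)
    bits <- sample(1:3, 1)
    v <- runif(n)
    r <- median_cut(v, bits)
    expect_same_partition(r$labels, oracle_median_cut(v, bits))
    expect_lte(length(r$cluster_means), 2^bits)
    expect_true(all(r$labels >= 1 & r$labels <= length(r$cluster_means)))
  }
})

test_that("histogram equalization follows the empirical CDF", {
  p <- matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2)
  expect_equal(sort(unique(as.vector(equalize_patch(p)))), c(0.5, 1.0))

  const <- matrix(0.3, 3, 3)
  expect_identical(equalize_patch(const), const)

  set.seed(3)
  x <- matrix(runif(100), 10, 10)
  e <- equalize_patch(x)
  expect_identical(order(as.vector(x)), order(as.vector(e)))  # rank-preserving
})

test_that("multiscale enhancement respects the region mask", {
  s <- make_phantom(5, vessel_count = 20)
  cfg <- mmcq_config(patch_sizes = c(64L, 32L))
  enh <- enhance_multiscale(s$image, s$region_mask, cfg)
  expect_identical(enh[!s$region_mask], s$image[!s$region_mask])
  expect_gte(min(enh), 0)
  expect_lte(max(enh), 1)
  # contrast-enhancement property on a sparse-vessel phantom
  s2 <- make_phantom(6, vessel_count = 12)
  enh2 <- enhance_multiscale(s2$image, s2$region_mask, cfg)
  expect_gte(sd(enh2[s2$region_mask]), sd(s2$image[s2$region_mask]) - 1e-12)

  # constant choroid: identity inside the region
  img <- s$image
  img[s$region_mask] <- 0.6
  enh3 <- enhance_multiscale(img, s$region_mask, cfg)
  expect_equal(enh3[s$region_mask], rep(0.6, sum(s$region_mask)))
})

test_that("single-pass MMCQ segments separable phantoms", {
  s <- make_phantom(7, speckle = 0)
  v <- segment_vessels_mmcq(s$image, s$region_mask)
  expect_gte(dice_score(v * 1, s$vessel_mask), 0.95)
  expect_false(any(v & !s$region_mask))

  # constant region: darkest-cluster fraction, flagged low-confidence
  img <- s$image
  img[s$region_mask] <- 0.6
  vc <- segment_vessels_mmcq(img, s$region_mask)
  expect_true(isTRUE(attr(vc, "low_confidence")))
  expect_equal(sum(vc) / sum(s$region_mask), 0.5, tolerance = 0.01)
})

test_that("MMCQ warns and falls back when the region is tiny", {
  s <- make_phantom(8, vessel_count = 10)
  small <- matrix(FALSE, 256, 256)
  small[120:135, 100:130] <- s$region_mask[120:135, 100:130]
  small[120:135, 100:130] <- TRUE
  expect_warning(segment_vessels_mmcq(s$image, small, mmcq_config()),
                 "single global pass")
})

test_that("ensemble vote counts and monotone thresholds behave", {
  s <- make_phantom(9, vessel_count = 30)
  m15 <- ensemble_majority_vote(s$image, s$region_mask)
  votes <- attr(m15, "votes")
  expect_true(all(votes >= 0 & votes <= 25))
  # output is exactly the thresholded vote stack
  expect_identical(m15[, ], votes >= 15)
  if (any(votes == 15)) expect_true(all(m15[votes == 15]))
  if (any(votes == 14)) expect_false(any(m15[votes == 14]))

  # monotone: raising the threshold never adds vessel pixels
  m20 <- votes >= 20
  expect_false(any(m20 & !m15))

  # determinism
  m15b <- ensemble_majority_vote(s$image, s$region_mask)
  expect_identical(m15[, ], m15b[, ])
})

test_that("MMCQ keeps parity with Niblack on noise-free phantoms", {
  s <- make_phantom(10, speckle = 0)
  d_mmcq <- dice_score(segment_vessels_mmcq(s$image, s$region_mask) * 1,
                       s$vessel_mask)
  d_nib <- dice_score(segment_vessels_niblack(s$image, s$region_mask) * 1,
                      s$vessel_mask)
  expect_gte(d_mmcq, d_nib - 0.05)
})
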