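test_that("Dice matches hand-counted confusion tables", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_score(a, a), 1.0)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice_score(a, b), 0.0)

  pred <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3, 3)
  gt <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)  # 2 TP, 1 FP, 1 FN
  expect_equal(dice_score(pred, gt), 4 / 6)

  expect_equal(dice_score(matrix(0, 2, 2), matrix(0, 2, 2)), 1.0)
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")

  # symmetric in its binarized arguments
  set.seed(4)
  p <- matrix(runif(64) > 0.5, 8, 8) * 1
  g <- matrix(runif(64) > 0.5, 8, 8) * 1
  expect_equal(dice_score(p, g), dice_score(g, p))
})

test_that("AUC equals exhaustive pair counting", {
  pred <- matrix(c(.9, .8, .7, .6, .5, .4), 1, 6)
  gt <- matrix(c(1, 1, 0, 1, 0, 0), 1, 6)
  expect_equal(auc_score(pred, gt), 8 / 9, tolerance = 1e-12)

  expect_equal(auc_score(matrix(c(.9, .8, .2, .1), 1, 4),
                         matrix(c(1, 1, 0, 0), 1, 4)), 1.0)
  expect_equal(auc_score(matrix(0.5, 2, 4),
                         matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 2, 4)), 0.5)
  expect_error(auc_score(matrix(0.5, 2, 2), matrix(1, 2, 2)), "single class")

  set.seed(6)
  for (i in 1:5) {
    p <- matrix(round(runif(80), 2), 8, 10)   # rounded to force ties
    g <- matrix(runif(80) > 0.6, 8, 10) * 1
    expect_equal(auc_score(p, g), oracle_auc(p, g), tolerance = 1e-12)
  }
})

test_that("agreement statistics match direct formula evaluation", {
  x <- c(1, 5, 3, 7, 2)
  a <- agreement_stats(x, x)
  expect_equal(a$pearson, 1)
  expect_equal(a$spearman, 1)
  expect_equal(a$mae, 0)
  expect_equal(a$icc, 1)
  expect_equal(a$bland_altman$mean_diff, 0)

  b <- agreement_stats(x, x + 1)
  expect_equal(b$pearson, 1)
  expect_equal(b$mae, 1)
  expect_equal(b$bland_altman$mean_diff, 1)
  expect_equal(b$bland_altman$lower, 1)   # zero-variance differences

  x3 <- c(1, 2, 3, 4); y3 <- c(1.1, 1.9, 3.2, 3.8)
  cst <- agreement_stats(x3, y3)
  expect_equal(cst$pearson, cor(x3, y3), tolerance = 1e-6)
  expect_equal(cst$spearman, 1, tolerance = 1e-6)
  expect_equal(cst$mae, mean(abs(y3 - x3)), tolerance = 1e-6)
  expect_equal(cst$median_ae, median(abs(y3 - x3)), tolerance = 1e-6)

  expect_true(is.na(agreement_stats(rep(1, 4), c(1, 2, 3, 4))$pearson))
  expect_error(agreement_stats(1:2, 1:2), "length")
})

test_that("ICC(2,1) matches an independent two-way ANOVA oracle", {
  # reference values computed with a standard two-way random-effects
  # absolute-agreement single-rater ICC implementation
  expect_equal(agreement_stats(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))$icc,
               0.992084432718, tolerance = 1e-9)
  x2 <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
          10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584)
  y2 <- c(11.162259, 9.321825, 12.374909, 11.693695, 6.892931, 7.128535,
          11.458441, 9.827574, 10.318508, 8.249168, 13.236829, 11.93196)
  expect_equal(agreement_stats(x2, y2)$icc, 0.920165614019, tolerance = 1e-9)
})

test_that("agreement statistics are invariant under paired shuffles", {
  set.seed(9)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.3)
  a <- agreement_stats(x, y)
  perm <- sample(20)
  b <- agreement_stats(x[perm], y[perm])
  expect_equal(a$pearson, b$pearson)
  expect_equal(a$icc, b$icc)
  expect_equal(a$mae, b$mae)
})
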