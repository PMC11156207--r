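test_that("fovea target has the documented structure", {
  tg <- build_fovea_target(c(256, 256), 120, 100)
  expect_equal(tg[100, 120], 1.0)
  expect_equal(tg[90, 120], 0.95)          # same column inside the window
  expect_equal(tg[100, 123], 0.65)         # column distance 3: 0.95 - 0.3
  expect_equal(tg[100, 129], 0.05)         # distance 9: 0.95 - 0.9
  expect_equal(tg[10, 10], 0.01)           # background
  expect_equal(tg[100 + 26, 120], 0.01)    # just below the 51-px window
  expect_error(build_fovea_target(c(64, 64), 0, 10), "out of range")
})

test_that("target is translation-equivariant away from borders", {
  t1 <- build_fovea_target(c(128, 128), 50, 64)
  t2 <- build_fovea_target(c(128, 128), 57, 64)
  expect_equal(t1[, 20:110], t2[, 27:117])
})

test_that("extraction round-trips the target exhaustively", {
  for (cc in 11:54) {   # interior columns on a 64-wide grid
    tg <- build_fovea_target(c(64, 64), cc, 32)
    expect_identical(extract_fovea_column(tg), cc)
  }
  # near the border the zero-padded filter can pull the argmax at most one
  # column inward; the clipped target window itself is asymmetric there
  tg5 <- build_fovea_target(c(64, 256), 5, 32)
  expect_lte(abs(extract_fovea_column(tg5) - 5L), 1L)
  expect_identical(extract_fovea_row(build_fovea_target(c(256, 64), 32, 77)),
                   77L)
  expect_error(extract_fovea_column(matrix(0, 8, 8)), "all-zero")
})

test_that("extraction is horizontal-flip equivariant", {
  s <- make_phantom(13, vessel_count = 15)
  deg <- degrade_to_probability_maps(s, 1, 0.03, seed = 2)
  W <- ncol(deg$fovea_prob)
  c1 <- extract_fovea_column(deg$fovea_prob)
  c2 <- extract_fovea_column(deg$fovea_prob[, W:1])
  expect_equal(c2, W + 1 - c1)
})

test_that("extraction tolerates blur and noise", {
  errs <- vapply(1:6, function(seed) {
    tg <- build_fovea_target(c(256, 256), 200, 128)
    deg <- tg + with_seed_for_tests(seed, matrix(rnorm(256 * 256, 0, 0.05),
                                                 256, 256))
    deg <- EBImage::gblur(pmin(pmax(deg, 0), 1), 2)
    abs(extract_fovea_column(deg) - 200)
  }, numeric(1))
  expect_true(mean(errs <= 3) >= 0.9)
})
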