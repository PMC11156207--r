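test_that("boundary extraction uses the half-pixel convention", {
  region <- matrix(FALSE, 300, 64)
  region[100:199, ] <- TRUE
  b <- extract_boundaries(region)
  expect_true(all(b$upper[b$valid_columns] == 99.5))
  expect_true(all(b$lower[b$valid_columns] == 199.5))
  expect_equal(b$valid_columns, 1:64)

  # isolated speck above the band is discarded (largest component)
  region2 <- region
  region2[10, 30] <- TRUE
  b2 <- extract_boundaries(region2)
  expect_equal(b2$upper[30], 99.5)

  # empty columns are excluded
  region3 <- region
  region3[, 10] <- FALSE
  b3 <- extract_boundaries(region3)
  expect_false(10 %in% b3$valid_columns)

  expect_error(extract_boundaries(matrix(FALSE, 4, 4)), "empty")
})

test_that("ROI definition converts microns to columns", {
  roi <- define_roi(385, 9000 / 768, 768, "hline")
  expect_equal(roi$col_lo, 385 - 256)   # round(3000 / 11.72) = 256
  expect_equal(roi$col_hi, 385 + 256)

  roi2 <- define_roi(50, 10, 768, "hline")
  expect_equal(roi2$col_lo, 1)          # clipped at the image edge
  expect_equal(roi2$col_hi, 350)

  roi3 <- define_roi(NA, 10, 768, "volume")
  expect_equal(roi3$center_col, 385)    # middle column
})

test_that("thickness is exact on flat bands and within 2% on sheared bands", {
  region <- matrix(FALSE, 300, 256)
  region[101:200, ] <- TRUE
  b <- extract_boundaries(region)
  roi <- define_roi(128, 10, 256, "hline")
  expect_equal(compute_thickness(b, roi, 10, 10), rep(1000, 3))

  for (deg in c(10, 25)) {
    m <- tan(deg * pi / 180)
    reg2 <- matrix(FALSE, 512, 256)
    tpx <- round(1000 / cos(deg * pi / 180) / 10)
    for (j in 1:256) {
      u <- round(100 + m * j)
      reg2[u:(u + tpx - 1), j] <- TRUE
    }
    th <- compute_thickness(extract_boundaries(reg2),
                            define_roi(128, 10, 256, "hline"), 10, 10)
    expect_true(all(abs(th - 1000) / 1000 < 0.02))
  }
})

test_that("area counts pixels with physical scaling", {
  region <- matrix(FALSE, 300, 768)
  region[1:100, 1:600] <- TRUE
  roi <- structure(list(center_col = 300, col_lo = 1, col_hi = 600),
                   class = "roi_window")
  expect_equal(compute_area(region, roi, 10, 10), 6.0)
  expect_equal(compute_area(matrix(FALSE, 10, 10),
                            structure(list(col_lo = 1, col_hi = 10),
                                      class = "roi_window"), 10, 10), 0)
  expect_equal(compute_area(region, roi, 10, 20), 12.0)  # linear in scale
})

test_that("vascularity index counts and reduces correctly", {
  region <- matrix(TRUE, 100, 100)
  roi <- structure(list(col_lo = 1, col_hi = 100), class = "roi_window")
  vessel <- matrix(FALSE, 100, 100)
  vessel[1:50, ] <- TRUE
  expect_equal(compute_vascular_index(region * 1, vessel * 1, roi, "hard"), 0.5)
  expect_equal(compute_vascular_index(region * 1, vessel * 1, roi, "soft"), 0.5)

  set.seed(8)
  v2 <- matrix(runif(1e4) < 0.37, 100, 100)
  f <- sum(v2) / 1e4
  expect_equal(compute_vascular_index(region * 1, v2 * 1, roi, "hard"), f)
  expect_equal(compute_vascular_index(region * 1, v2 * 1, roi, "soft"), f,
               tolerance = 1e-12)

  # literal vessel:nonvessel ratio
  expect_equal(compute_vascular_index(region * 1, vessel * 1, roi, "hard",
                                      literal = TRUE), 1.0)
  expect_error(compute_vascular_index(matrix(0, 4, 4), matrix(0, 4, 4),
                                      structure(list(col_lo = 1, col_hi = 4),
                                                class = "roi_window"), "hard"),
               "undefined")
})

test_that("soft CVI converges monotonically to hard CVI under sharpening", {
  s <- make_phantom(17, vessel_count = 30)
  deg <- degrade_to_probability_maps(s, 1.5, 0.03, seed = 5)
  roi <- define_roi(s$fovea_col, s$scale_x, ncol(s$image), "hline")
  hard <- compute_vascular_index(s$region_mask * 1, s$vessel_mask * 1, roi,
                                 "hard")
  errs <- vapply(c(1, 2, 4, 8, 16, 64), function(p) {
    sharp_v <- deg$vessel_prob^p / (deg$vessel_prob^p + (1 - deg$vessel_prob)^p)
    sharp_r <- deg$region_prob^p / (deg$region_prob^p + (1 - deg$region_prob)^p)
    abs(compute_vascular_index(sharp_r, sharp_v, roi, "soft") - hard)
  }, numeric(1))
  expect_lt(errs[length(errs)], 0.02)
  expect_true(all(diff(errs) < 0.005))    # essentially monotone decrease
})

test_that("metrics are invariant to resolution/scale rescaling", {
  s <- make_phantom(19, vessel_count = 30)
  seg <- degrade_to_probability_maps(s, 0, 0)
  scan <- bscan(s$image, s$scale_x, s$scale_y)
  met <- analyze_scan(scan, seg)

  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  s_up <- s
  s_up$image <- up(s$image)
  s_up$region_mask <- up(s$region_mask)
  s_up$vessel_mask <- up(s$vessel_mask)
  s_up$fovea_col <- 2L * s$fovea_col - 1L
  s_up$fovea_row <- 2L * s$fovea_row - 1L
  seg_up <- degrade_to_probability_maps(s_up, 0, 0)
  met_up <- analyze_scan(bscan(s_up$image, s$scale_x / 2, s$scale_y / 2),
                         seg_up)
  expect_lt(abs(met_up$area_mm2 - met$area_mm2) / met$area_mm2, 0.01)
  expect_lt(abs(met_up$thickness_mean_um - met$thickness_mean_um) /
              met$thickness_mean_um, 0.01)
  expect_lt(abs(met_up$cvi - met$cvi), 0.01)
})

test_that("analyze_scan recovers the generator's analytic truth", {
  s <- make_phantom(23, vessel_count = 40)
  seg <- degrade_to_probability_maps(s, 0, 0)
  scan <- bscan(s$image, s$scale_x, s$scale_y)
  met <- analyze_scan(scan, seg)

  expect_equal(met$fovea_col, s$fovea_col)
  cols <- met$roi$col_lo:met$roi$col_hi
  locs <- c(met$roi$col_lo, met$roi$center_col, met$roi$col_hi)
  true_thick <- mean(s$thickness_px[locs]) * s$scale_y
  true_area <- sum(s$region_mask[, cols]) * s$scale_x * s$scale_y * 1e-6
  true_cvi <- sum(s$vessel_mask[, cols]) / sum(s$region_mask[, cols])
  expect_lt(abs(met$thickness_mean_um - true_thick) / true_thick, 0.02)
  expect_lt(abs(met$area_mm2 - true_area) / true_area, 0.02)
  expect_lt(abs(met$cvi - true_cvi), 0.02)
  expect_equal(met$soft_cvi, met$cvi, tolerance = 1e-12)
})

test_that("peripapillary scans return masks only; empty regions error", {
  s <- make_phantom(29, vessel_count = 10, height = 128, width = 256)
  seg <- degrade_to_probability_maps(s, 0, 0)
  scan <- bscan(s$image, s$scale_x, s$scale_y, scan_type = "peripapillary")
  out <- analyze_scan(scan, seg)
  expect_null(out$metrics)
  expect_true(is.matrix(out$region_mask))
  expect_false(any(out$vessel_mask & !out$region_mask))

  seg_low <- seg
  seg_low$region_prob <- matrix(0.49, 256, 256)
  scan2 <- bscan(make_phantom(29, height = 256, width = 256)$image,
                 11.72, 3.87)
  expect_error(analyze_scan(scan2, seg_low), "empty region")
})
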