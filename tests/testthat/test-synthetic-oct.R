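test_that("generator is deterministic and geometrically truthful", {
  cfg <- generator_config(height = 192, width = 192, vessel_count = 25,
                          seed = 11)
  s1 <- generate_bscan(cfg)
  s2 <- generate_bscan(cfg)
  expect_identical(s1, s2)

  # per-column thickness read back from the mask equals the internal profile
  col_thickness <- colSums(s1$region_mask)
  expect_identical(as.integer(col_thickness), as.integer(s1$thickness_px))

  # region is one contiguous vertical run per column
  runs <- apply(s1$region_mask, 2, function(col) {
    r <- rle(col)
    sum(r$values)
  })
  expect_true(all(runs == 1))

  # containment
  expect_false(any(s1$vessel_mask & !s1$region_mask))
  expect_true(s1$fovea_col >= 1 && s1$fovea_col <= 192)
})

test_that("noise-free vessel-free band renders stroma exactly", {
  s <- generate_bscan(generator_config(height = 192, width = 192,
                                       vessel_count = 0, speckle_sigma = 0,
                                       seed = 2))
  expect_true(all(s$image[s$region_mask] == 0.8))
})

test_that("planted vessel fraction is close to the rasterised area tally", {
  s <- generate_bscan(generator_config(height = 768, width = 768,
                                       vessel_count = 30, seed = 5))
  union_frac <- sum(s$vessel_mask) / sum(s$region_mask)
  tally_frac <- s$vessel_area_px / sum(s$region_mask)
  expect_lt(abs(union_frac - tally_frac), 0.1)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(height = 100), "multiples of 64")
  expect_error(generator_config(stroma_intensity = 1.2), "intensities")
  expect_error(generator_config(vessel_radius_range = c(-1, 5)), "positive")
})

test_that("dataset generation is deterministic and spans fovea positions", {
  cfg <- generator_config(height = 128, width = 128,
                          choroid_mean_thickness = 180, vessel_count = 10,
                          seed = 1)
  expect_error(generate_dataset(cfg, 0), "n must be")
  expect_length(generate_dataset(cfg, 1), 1)
  d1 <- generate_dataset(cfg, 5, seed = 7)
  d2 <- generate_dataset(cfg, 5, seed = 7)
  expect_identical(d1, d2)

  fcols <- vapply(generate_dataset(cfg, 100, seed = 3),
                  function(s) s$fovea_col, integer(1))
  expect_gte(diff(range(fcols)), 0.2 * 128)
})

test_that("degradation to probability maps honours its contracts", {
  s <- make_phantom(21, vessel_count = 20)
  clean <- degrade_to_probability_maps(s, 0, 0)
  expect_equal(clean$region_prob, s$region_mask * 1, ignore_attr = TRUE)
  expect_equal(clean$fovea_prob,
               build_fovea_target(dim(s$image), s$fovea_col, s$fovea_row))

  deg <- degrade_to_probability_maps(s, 2, 0.05, seed = 4)
  for (ch in deg) {
    expect_gte(min(ch), 0)
    expect_lte(max(ch), 1)
  }
  expect_gte(dice_score(deg$region_prob, s$region_mask), 0.95)
})
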