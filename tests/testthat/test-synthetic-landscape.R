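test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- landscape_config(shape = c(40, 40), seed = 7)
  b1 <- generate_landscape(cfg)
  set.seed(123); before <- runif(1)
  b2 <- generate_landscape(cfg)
  expect_identical(b1$lulc$values, b2$lulc$values)
  expect_identical(b1$dem$values, b2$dem$values)
  expect_identical(b1$roads_1, b2$roads_1)
  expect_identical(b1$pollution_points, b2$pollution_points)
  set.seed(123)
  expect_identical(runif(1), before)
  # different seeds differ
  b3 <- generate_landscape(landscape_config(shape = c(40, 40), seed = 8))
  expect_false(identical(b1$lulc$values, b3$lulc$values))
})

test_that("realized class proportions track the configuration", {
  cfg <- landscape_config(shape = c(200, 200), seed = 2,
                          class_proportions = c("1" = 0.6, "3" = 0.25, "5" = 0.15))
  b <- generate_landscape(cfg)
  share <- table(b$lulc$values) / length(b$lulc$values)
  expect_equal(unname(share[["1"]]), 0.6, tolerance = 0.05 / 0.6)
  expect_equal(unname(share[["3"]]), 0.25, tolerance = 0.05 / 0.25)
  expect_error(landscape_config(class_proportions = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
})

test_that("bundle invariants hold across random configurations", {
  set.seed(31)
  for (trial in 1:4) {
    p <- runif(4); p <- p / sum(p)
    cfg <- landscape_config(
      shape = c(30 + trial * 5, 35), cell_size = sample(c(30, 100), 1),
      class_proportions = stats::setNames(p, c("1", "3", "6", "7")),
      autocorr_length = runif(1, 2, 10),
      n_roads1 = sample(0:3, 1), n_pollution = sample(0:6, 1),
      n_reserves = sample(0:3, 1), seed = trial)
    b <- generate_landscape(cfg)
    expect_true(congruent(b$lulc, b$dem, b$precipitation, b$aet, b$ndvi))
    expect_true(all(b$aet$values >= 0 & b$aet$values <= b$precipitation$values))
    expect_true(all(b$ndvi$values >= 0 & b$ndvi$values <= 1))
    expect_true(all(b$lulc$values %in% c(1, 3, 6, 7)))
    expect_true(all(vapply(b$csle, function(g) all(g$values >= 0), logical(1))))
  }
})

test_that("a pollution-free landscape scores the most permissive classes", {
  cfg <- landscape_config(shape = c(30, 30), n_pollution = 0, seed = 5)
  b <- generate_landscape(cfg)
  expect_equal(nrow(b$pollution_points), 0)
  f <- bundle_resistance_factors(b)
  expect_true(all(is.infinite(f$pollution_dist$values)))
  cls <- classify_factor(f$pollution_dist, default_resistance_table()$pollution_dist)
  expect_true(all(cls$values == 1))
})

test_that("fixture presets have their designed structure", {
  u <- landscape_fixture("uniform", shape = c(20, 20))
  ru <- integrated_resistance(bundle_resistance_factors(u))
  expect_equal(length(unique(as.vector(ru$values))), 1)

  hg <- landscape_fixture("hourglass", shape = c(40, 40))
  res <- hg$resistance$values
  # exactly one low-resistance cell per bridge column between the blocks
  for (cc in hg$meta$bridge_cols) {
    expect_equal(sum(res[, cc] == hg$meta$low), 1)
  }

  w <- landscape_fixture("wall", shape = c(40, 40))
  # the high-resistance strip spans every row: no gap
  expect_true(all(w$resistance$values[, w$meta$wall_cols] == w$meta$wall_resistance))

  tp <- landscape_fixture("two_patch", shape = c(40, 40))
  expect_equal(length(tp$reserves), 2)
})
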