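test_that("score layers reproduce the published break tables", {
  hb <- default_habitat_breaks()
  # distance to major road: 500 m is in the most sensitive class
  expect_equal(score_layer(rg(matrix(500, 1, 1)), hb$road)$values[1, 1], 7)
  # distance to reserves: 7000 m falls in [6000, 9000)
  expect_equal(score_layer(rg(matrix(7000, 1, 1)), hb$reserve)$values[1, 1], 3)
  # NDVI 0.6 falls in [0.5, 0.7)
  expect_equal(score_layer(rg(matrix(0.6, 1, 1)), hb$ndvi)$values[1, 1], 5)
  wb <- default_water_breaks()
  d <- function(x, br) score_layer(rg(matrix(x, 1, 1)), br)$values[1, 1]
  expect_equal(c(d(200, wb$water), d(1000, wb$wastewater), d(2000, wb$air)),
               c(7, 7, 7))
  expect_equal(c(d(2000, wb$water), d(12000, wb$wastewater), d(1e6, wb$air)),
               c(1, 1, 1))
})

test_that("distance score rows are monotone non-increasing step functions", {
  brs <- c(default_habitat_breaks()[c("road", "reserve")],
           default_water_breaks())
  for (br in brs) {
    dists <- rg(matrix(seq(0, 20000, by = 50), 1))
    sc <- as.vector(score_layer(dists, br)$values)
    expect_true(all(diff(sc) <= 0))
    expect_equal(sc[1], 7)
    expect_equal(sc[length(sc)], 1)
  }
})

test_that("habitat and water sensitivity combine sub-scores by mean", {
  n <- function(x) rg(matrix(x, 1, 1))
  leg <- default_lulc_legend()
  # all four sub-scores 7: road 0 m, reserve 0 m, forestland, NDVI 0.9
  hs <- habitat_sensitivity(n(0), n(0), n(3), n(0.9))
  expect_equal(hs$values[1, 1], 7)
  # sub-scores (7, 5, 3, 1): road 500 (7), reserve 4000 (5), bare (3), urban?
  hs2 <- habitat_sensitivity(n(500), n(4000), n(10), n(0.2))
  expect_equal(hs2$values[1, 1], mean(c(7, 5, 3, 1)))
  # all minimal
  hs3 <- habitat_sensitivity(n(5000), n(20000), n(7), n(0.1))
  expect_equal(hs3$values[1, 1], 1)
  # water: (7, 5, 3) -> 5; sum mode keeps the total
  ws <- water_sensitivity(n(200), n(4000), n(9000))
  expect_equal(ws$values[1, 1], 5)
  ws2 <- water_sensitivity(n(200), n(4000), n(9000), combine = "sum")
  expect_equal(ws2$values[1, 1], 15)
})

test_that("soil loss is the cellwise product of the six factors", {
  const <- function(x) rg(matrix(x, 2, 2))
  f <- list(R = const(100), K = const(0.5), LS = const(1), C = const(1),
            P = const(1), T = const(1))
  expect_equal(csle(f)$values, matrix(50, 2, 2))
  f$C <- const(0)
  expect_true(all(csle(f)$values == 0))
  f$C <- const(-0.1)
  expect_error(csle(f), "negative")
  f$C <- const(2)
  expect_error(csle(f), "ceiling")
  # random factors against a direct product; doubling K doubles A
  set.seed(29)
  fr <- lapply(stats::setNames(nm = c("R", "K", "LS", "C", "P", "T")),
               function(nm) rg(matrix(runif(16, 0.01, if (nm %in% c("C", "P", "T")) 1 else 50), 4)))
  A <- csle(fr)
  expect_equal(A$values, Reduce(`*`, lapply(fr, function(g) g$values)))
  fr2 <- fr; fr2$K$values <- 2 * fr$K$values
  expect_equal(csle(fr2)$values, 2 * A$values)
})

test_that("integrated sensitivity is scale-free and classifies by quantiles", {
  set.seed(37)
  h <- rg(matrix(runif(100, 1, 7), 10))
  w <- rg(matrix(runif(100, 1, 7), 10))
  a <- rg(matrix(rexp(100), 10))
  s1 <- integrated_sensitivity(h, w, a)
  # affine rescaling of an input is absorbed by the min-max normalization
  a2 <- rg(3 * a$values + 10)
  s2 <- integrated_sensitivity(h, w, a2)
  expect_equal(s1$index$values, s2$index$values)
  expect_equal(as.vector(table(s1$classes$values)), rep(25, 4))
  expect_true(all(s1$index$values >= 0 & s1$index$values <= 1))
})
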