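make_spec <- function(weight = 1, d_max = 1000, decay = "linear",
                      source = mask_at(3, 3, cbind(1, 1))) {
  threat_spec("t", weight, d_max, decay, source)
}

test_that("threat impact decays as specified with a hard cutoff", {
  lin <- make_spec(decay = "linear", d_max = 1000)
  expect_equal(threat_impact(0, lin), 1)
  expect_equal(threat_impact(1000, lin), 0)
  expect_equal(threat_impact(500, lin), 0.5)
  ex <- make_spec(decay = "exponential", d_max = 1000)
  expect_equal(threat_impact(0, ex), 1)
  expect_equal(threat_impact(1000, ex), exp(-2.99))
  expect_equal(threat_impact(1001, ex), 0)      # hard cutoff past d_max
  expect_error(threat_spec("t", 1, -5, "linear", mask_at(2, 2, cbind(1, 1))),
               "d_max")
})

simple_params <- function(S = 1, H = 1, k = 0.5, ids = "t") {
  habitat_params(
    suitability = c("1" = H),
    sensitivity = matrix(S, 1, length(ids), dimnames = list("1", ids)),
    k = k)
}

test_that("degradation is the weighted average of threat levels", {
  lu <- rg(matrix(1, 3, 3), cell_size = 100)
  # one threat, source everywhere relevant, S = 1 -> D = 1 on the source cell
  th <- list(make_spec(weight = 1, d_max = 1000))
  D <- degradation(lu, th, simple_params())
  expect_equal(D$values[1, 1], 1)
  # two threats with equal weight, impacts 1 and 0 -> D = 0.5
  far <- threat_spec("u", 1, 50, "linear", mask_at(3, 3, cbind(3, 3)))
  p2 <- habitat_params(c("1" = 1),
                       matrix(1, 1, 2, dimnames = list("1", c("t", "u"))))
  D2 <- degradation(lu, list(make_spec(weight = 1, d_max = 1000), far), p2)
  expect_equal(D2$values[1, 1], 0.5)
  # zero sensitivity gates everything off
  D3 <- degradation(lu, th, simple_params(S = 0))
  expect_true(all(D3$values == 0))
  # missing sensitivity entries are named errors
  expect_error(degradation(lu, list(make_spec()), simple_params(ids = "other")),
               "threat 't'")
})

test_that("degradation is linear in the threat weights (superposition)", {
  lu <- rg(matrix(1, 4, 4), cell_size = 100)
  a <- threat_spec("a", 1, 600, "linear", mask_at(4, 4, cbind(1, 1)))
  b <- threat_spec("b", 1, 600, "linear", mask_at(4, 4, cbind(4, 4)))
  prm <- habitat_params(c("1" = 1),
                        matrix(1, 1, 2, dimnames = list("1", c("a", "b"))))
  d_of <- function(w) {
    a$weight <- w; b$weight <- 1 - w
    degradation(lu, list(a, b), prm)$values
  }
  d0 <- d_of(0); d1 <- d_of(1)
  for (w in c(0.25, 0.5, 0.8)) {
    expect_equal(d_of(w), w * d1 + (1 - w) * d0)
  }
})

test_that("habitat quality follows the half-saturation law", {
  lu <- rg(matrix(1, 1, 3))
  prm <- simple_params(H = 0.8, k = 0.4)
  Dk <- rg(matrix(c(0, 0.4, 10), 1))
  Q <- habitat_quality(Dk, lu, prm)
  expect_equal(Q$values[1, 1], 0.8)          # D = 0 -> Q = H
  expect_equal(Q$values[1, 2], 0.4)          # D = k -> Q = H/2
  expect_lt(Q$values[1, 3], 0.01)
  # non-habitat stays zero
  prm0 <- simple_params(H = 0)
  expect_true(all(habitat_quality(Dk, lu, prm0)$values == 0))
  # monotone decreasing in D
  dgrid <- rg(matrix(seq(0, 2, length.out = 10), 1))
  qv <- habitat_quality(dgrid, rg(matrix(1, 1, 10)), prm)$values
  expect_true(all(diff(as.vector(qv)) < 0))
  expect_true(all(qv >= 0 & qv <= 0.8))
})

test_that("water yield is the exact water balance", {
  P <- rg(matrix(c(1000, 800, 0, 500), 2))
  A <- rg(matrix(c(400, 800, 0, 0), 2))
  Y <- water_yield(P, A)
  expect_equal(Y$values, matrix(c(600, 0, 0, 500), 2))
  expect_true(all(Y$values >= 0 & Y$values <= P$values))
  expect_error(water_yield(rg(matrix(-1, 1, 1)), rg(matrix(0, 1, 1))),
               "negative")
})

test_that("carbon storage sums the four pools per class", {
  pools <- data.frame(code = c(1, 2), c_above = c(10, 0), c_below = c(5, 0),
                      c_soil = c(20, 0), c_dead = c(2, 0))
  lu <- rg(matrix(c(1, 2, 1, 1), 2))
  C <- carbon_storage(lu, pools)
  expect_equal(C$values, matrix(c(37, 0, 37, 37), 2))
  expect_error(carbon_storage(rg(matrix(9, 1, 1)), pools), "absent")
  # random lookup oracle; unused extra rows change nothing
  set.seed(23)
  pools2 <- data.frame(code = 1:6, c_above = runif(6, 0, 50),
                       c_below = runif(6, 0, 20), c_soil = runif(6, 0, 100),
                       c_dead = runif(6, 0, 5))
  lu2 <- rg(matrix(sample(1:4, 30, replace = TRUE), 5))
  C2 <- carbon_storage(lu2, pools2)
  tot <- rowSums(pools2[, -1])
  for (k in seq_along(lu2$values)) {
    expect_equal(C2$values[k], tot[lu2$values[k]])
  }
  expect_equal(C2$values, carbon_storage(lu2, pools2[c(6:5, 1:4), ])$values)
})

test_that("integrated services average the normalized layers equally", {
  Q <- rg(matrix(c(0, 1, 0.5, 1), 2))
  Y <- rg(matrix(c(0, 200, 100, 0), 2))
  C <- rg(matrix(c(5, 10, 5, 10), 2))
  S <- integrated_services(Q, Y, C)
  expect_equal(S$values[2, 2], (1 + 0 + 1) / 3)
  expect_equal(S$values[1, 2], (0.5 + 0.5 + 0) / 3)
  expect_true(all(S$values >= 0 & S$values <= 1))
})
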