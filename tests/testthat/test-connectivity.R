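test_that("cost-weighted distance matches the uniform metric and the oracle", {
  r <- rg(matrix(1, 5, 5), cell_size = 100)
  cw <- cost_weighted_distance(r, mask_at(5, 5, cbind(3, 1)))
  expect_equal(cw$values[3, 1], 0)
  expect_equal(cw$values[3, 4], 300)          # straight line, 3 cells
  expect_equal(cw$values[4, 2], 100 * sqrt(2))
  # igraph Dijkstra oracle on random 6x6 grids
  skip_if_not_installed("igraph")
  set.seed(43)
  for (trial in 1:10) {
    res <- matrix(runif(36, 0.5, 10), 6)
    src <- sample(36, 2)
    cw2 <- cost_weighted_distance(rg(res, cell_size = 50), mask_at(6, 6, src, 50))
    expect_equal(cw2$values, oracle_cwd(res, src, 50), tolerance = 1e-10)
  }
  # exhaustive simple-path enumeration on a 3x3 grid
  set.seed(44)
  res3 <- matrix(runif(9, 0.5, 5), 3)
  cw3 <- cost_weighted_distance(rg(res3, cell_size = 10), mask_at(3, 3, 1, 10))
  expect_equal(cw3$values[3, 3], oracle_enumerate_lcp(res3, 1, 9, 10))
})

test_that("least-cost corridors are symmetric and recover planted structure", {
  # uniform landscape: straight-line corridor, swath contains the lcp at 0
  r <- rg(matrix(1, 21, 41), cell_size = 100)
  a <- as_source_patch(mask_at(21, 41, cbind(11, 2)), 1)
  b <- as_source_patch(mask_at(21, 41, cbind(11, 40)), 2)
  cor <- least_cost_corridors(r, list(a, b))
  expect_equal(length(cor), 1)
  expect_equal(cor[[1]]$lcp_cost, 3800)       # 38 unit-resistance steps
  # the swath minimum CWD_A + CWD_B - lcp_cost is 0 on the optimal path
  cwa <- cost_weighted_distance(r, a)
  cwb <- cost_weighted_distance(r, b)
  expect_equal(min(cwa$values + cwb$values - cor[[1]]$lcp_cost), 0)
  # symmetry of the optimal cost
  cor_ba <- least_cost_corridors(r, list(b, a))
  expect_equal(cor_ba[[1]]$lcp_cost, cor[[1]]$lcp_cost)
  # hourglass: the lcp must run through the designed bridge
  hg <- landscape_fixture("hourglass", shape = c(40, 40))
  srcs <- lapply(1:2, function(i) as_source_patch(hg$sources[[i]], i))
  ch <- least_cost_corridors(hg$resistance, srcs)
  rc <- xy_path_to_rowcol(ch[[1]]$lcp, hg$resistance)
  on_bridge <- rc[, 1] == hg$meta$bridge_row & rc[, 2] %in% hg$meta$bridge_cols
  expect_equal(sum(on_bridge), length(hg$meta$bridge_cols))
})

test_that("three collinear patches yield two adjacent corridors", {
  r <- rg(matrix(1, 11, 61), cell_size = 100)
  srcs <- list(as_source_patch(mask_at(11, 61, cbind(6, 2)), 1),
               as_source_patch(mask_at(11, 61, cbind(6, 31)), 2),
               as_source_patch(mask_at(11, 61, cbind(6, 60)), 3))
  cor <- least_cost_corridors(r, srcs, pairing = "adjacent")
  expect_true(has_pair(cor, c(1, 2)))
  expect_true(has_pair(cor, c(2, 3)))
  # the end-to-end pair runs through the middle patch and is pruned
  expect_false(has_pair(cor, c(1, 3)))
  # all-pairs keeps it
  cor_all <- least_cost_corridors(r, srcs, pairing = "all")
  expect_equal(length(cor_all), 3)
})

test_that("circuit solutions reproduce series and parallel closed forms", {
  # series chain of unit resistances: R_eff = sum, middle carries everything
  chain <- rg(matrix(1, 1, 4), cell_size = 1)
  sol <- circuit_solve(chain, mask_at(1, 4, 1, 1), mask_at(1, 4, 4, 1))
  expect_equal(sol$effective_resistance, 3)
  expect_equal(sol$current$values[1, 2], 1)
  expect_equal(sol$current$values[1, 3], 1)
  # two equal 2-hop diagonal paths in parallel: each carries 0.5 A and
  # R_eff is half the single-path value
  m <- matrix(1, 3, 3)
  m[1, 1] <- NA; m[3, 1] <- NA; m[1, 3] <- NA; m[3, 3] <- NA; m[2, 2] <- NA
  two <- rg(m, cell_size = 1)
  sol2 <- circuit_solve(two, mask_at(3, 3, cbind(2, 1), 1),
                        mask_at(3, 3, cbind(2, 3), 1))
  expect_equal(sol2$effective_resistance, sqrt(2))
  expect_equal(sol2$current$values[1, 2], 0.5)
  expect_equal(sol2$current$values[3, 2], 0.5)
  m[3, 2] <- NA                                 # cut one path
  sol1 <- circuit_solve(rg(m, cell_size = 1), mask_at(3, 3, cbind(2, 1), 1),
                        mask_at(3, 3, cbind(2, 3), 1))
  expect_equal(sol1$effective_resistance, 2 * sqrt(2))
  # disconnected terminals are an error
  m2 <- matrix(c(1, NA, 1), 1, 3)
  expect_error(circuit_solve(rg(m2, 1), mask_at(1, 3, 1, 1), mask_at(1, 3, 3, 1)),
               "singular|connected")
})

test_that("circuit solves satisfy Kirchhoff and match a dense oracle", {
  set.seed(47)
  for (trial in 1:10) {
    res <- matrix(runif(25, 0.2, 5), 5)
    cells <- sample(25, 2)
    sol <- circuit_solve(rg(res, cell_size = 1),
                         mask_at(5, 5, cells[1], 1), mask_at(5, 5, cells[2], 1))
    expect_lt(sol$kcl_residual, 1e-8)
    expect_equal(sol$effective_resistance,
                 oracle_effective_resistance(res, cells[1], cells[2]),
                 tolerance = 1e-8)
  }
})

test_that("effective resistance never exceeds the least-cost path resistance", {
  set.seed(53)
  for (trial in 1:5) {
    res <- matrix(runif(36, 0.5, 8), 6)
    cells <- sample(36, 2)
    cw <- cost_weighted_distance(rg(res, cell_size = 1), mask_at(6, 6, cells[1], 1))
    lcp_res <- cw$values[cells[2]]
    sol <- circuit_solve(rg(res, cell_size = 1),
                         mask_at(6, 6, cells[1], 1), mask_at(6, 6, cells[2], 1))
    expect_lte(sol$effective_resistance, lcp_res + 1e-10)
  }
})

test_that("network centrality ranks hub nodes above leaves", {
  # line network A - B - C with equal link resistances
  mk_cor <- function(a, b, cost) {
    structure(list(pair = c(a, b), lcp = cbind(0, 0), lcp_cost = cost,
                   length_km = 1, swath_mask = NULL, buffer_mask = NULL,
                   centrality = NA_real_, improvement = NA_real_,
                   improvement_level = NA_character_, priority = NA_real_,
                   priority_level = NA_character_), class = "corridor_record")
  }
  cent <- current_centrality(list(mk_cor(1, 2, 10), mk_cor(2, 3, 10)), 3)
  expect_gt(cent$node_centrality[2], cent$node_centrality[1])
  expect_equal(cent$node_centrality[1], cent$node_centrality[3])
  # symmetric 4-cycle: all links share the same centrality
  cyc <- list(mk_cor(1, 2, 5), mk_cor(2, 3, 5), mk_cor(3, 4, 5), mk_cor(4, 1, 5))
  cent2 <- current_centrality(cyc, 4)
  links <- vapply(cent2$corridors, `[[`, numeric(1), "centrality")
  expect_equal(max(links) - min(links), 0, tolerance = 1e-10)
  # two disconnected pairs are handled per component
  cent3 <- current_centrality(list(mk_cor(1, 2, 5), mk_cor(3, 4, 7)), 4)
  expect_equal(cent3$node_centrality, c(1, 1, 1, 1))
  expect_error(current_centrality(list(mk_cor(1, 2, 5)), 1), "at least 2")
})

test_that("the hourglass bridge is the rank-1 pinch point", {
  hg <- landscape_fixture("hourglass", shape = c(40, 40))
  srcs <- lapply(1:2, function(i) as_source_patch(hg$sources[[i]], i))
  cor <- least_cost_corridors(hg$resistance, srcs)
  pp <- pinch_points(hg$resistance, cor, srcs, top_n = 3)
  expect_lt(pp$kcl_residual, 1e-8)
  top <- pp$points[1, ]
  expect_equal(top$row, hg$meta$bridge_row)
  expect_true(top$col %in% hg$meta$bridge_cols)
  expect_gt(top$score, 0.9)                    # carries ~ all injected current
  expect_equal(nrow(pinch_points(hg$resistance, cor, srcs, top_n = 1)$points), 1)
})

test_that("barrier improvement scores are zero on already-permeable land", {
  r <- rg(matrix(1, 20, 20), cell_size = 100)
  srcs <- list(as_source_patch(mask_at(20, 20, cbind(10, 2)), 1),
               as_source_patch(mask_at(20, 20, cbind(10, 19)), 2))
  cor <- least_cost_corridors(r, srcs)
  bs <- barrier_scan(r, cor, srcs, r_min = 200, r_max = 400)
  expect_true(all(bs$is$values[!is.na(bs$is$values)] == 0))
  expect_equal(nrow(bs$barriers), 0)
  expect_error(barrier_scan(r, cor, srcs, r_min = 50), "smaller than one cell")
})

test_that("the wall is found and scored as the hand computation predicts", {
  w <- landscape_fixture("wall", shape = c(60, 60))
  srcs <- lapply(1:2, function(i) as_source_patch(w$sources[[i]], i))
  cor <- least_cost_corridors(w$resistance, srcs)
  bs <- barrier_scan(w$resistance, cor, srcs, r_min = 200, r_max = 600,
                     top_n = 5)
  top <- bs$barriers[1, ]
  expect_true(top$col %in% w$meta$wall_cols)
  # 1-D transect: crossing excess = cell * (2*(mean(lo, W) - lo) + (t-1)*(W - lo))
  cs <- w$resistance$cell_size
  lo <- w$meta$background; W <- w$meta$wall_resistance; t <- w$meta$thickness
  excess <- cs * (2 * ((lo + W) / 2 - lo) + (t - 1) * (W - lo))
  expect_equal(top$is, excess / (2 * 200))
  expect_equal(top$radius, 200)
})

test_that("lowering resistance never worsens cost or effective resistance", {
  set.seed(59)
  res <- matrix(runif(144, 1, 20), 12)
  a <- mask_at(12, 12, cbind(2, 2), 1); b <- mask_at(12, 12, cbind(11, 11), 1)
  base_lcp <- cost_weighted_distance(rg(res, 1), a)$values[11, 11]
  base_reff <- circuit_solve(rg(res, 1), a, b)$effective_resistance
  for (trial in 1:20) {
    res2 <- res
    cell <- sample(144, 1)
    res2[cell] <- res2[cell] * runif(1, 0.05, 0.95)
    lcp2 <- cost_weighted_distance(rg(res2, 1), a)$values[11, 11]
    reff2 <- circuit_solve(rg(res2, 1), a, b)$effective_resistance
    expect_lte(lcp2, base_lcp + 1e-10)
    expect_lte(reff2, base_reff + 1e-10)
  }
})

test_that("composite priority cross-tabulates quantile levels", {
  mk <- function(i, imp, pri) {
    structure(list(pair = c(1, 2), lcp = cbind(0, 0), lcp_cost = 1,
                   length_km = 1, centrality = NA_real_,
                   improvement = imp, improvement_level = NA_character_,
                   priority = pri, priority_level = NA_character_),
              class = "corridor_record")
  }
  imps <- 1:8; pris <- 8:1
  cors <- lapply(1:8, function(i) mk(i, imps[i], pris[i]))
  icls <- ecoscape:::quantile_class_vector(imps)
  pcls <- ecoscape:::quantile_class_vector(pris)
  expect_equal(as.vector(table(icls)), rep(2, 4))
  for (i in 1:8) {
    cors[[i]]$improvement_level <- ecoscape:::level_label(icls[i])
    cors[[i]]$priority_level <- ecoscape:::level_label(pcls[i])
  }
  lab <- composite_priority(cors)
  expect_equal(lab[8], "V&L")
  expect_equal(lab[1], "L&V")
  # a single corridor degenerates to the lowest class on both axes
  single <- mk(1, 3, 3)
  single$improvement_level <- ecoscape:::level_label(
    ecoscape:::quantile_class_vector(3))
  single$priority_level <- single$improvement_level
  expect_equal(composite_priority(list(single)), "L&L")
})
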