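test_that("min-max normalization rescales linearly and flags constant rasters", {
  expect_equal(minmax_normalize(rg(matrix(c(2, 4, 6), 1)))$values,
               matrix(c(0, 0.5, 1), 1))
  expect_warning(out <- minmax_normalize(rg(matrix(5, 1, 2))),
                 "constant")
  expect_equal(out$values, matrix(0, 1, 2))
  # brute-force recomputation on a random grid
  set.seed(11)
  m <- matrix(rnorm(25), 5)
  expect_equal(minmax_normalize(rg(m))$values,
               (m - min(m)) / (max(m) - min(m)))
})

test_that("quantile classification gives equal-rank classes with ties low", {
  expect_equal(as.vector(quantile_classify(rg(matrix(1:8, 1)), 4)$values),
               c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_warning(cst <- quantile_classify(rg(matrix(5, 2, 2)), 4), "distinct")
  expect_equal(unique(as.vector(cst$values)), 1)
  # rank counts on uniform draws
  set.seed(3)
  v <- rg(matrix(runif(100), 10))
  cls <- quantile_classify(v, 4)
  expect_equal(as.vector(table(cls$values)), rep(25, 4))
  # monotone in the values
  ord <- order(as.vector(v$values))
  expect_true(all(diff(as.vector(cls$values)[ord]) >= 0))
})

test_that("euclidean distance matches brute force and handles vector targets", {
  g <- mask_at(2, 2, cbind(1, 1), cell_size = 30)
  d <- euclidean_distance(g)
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[1, 2], 30)
  expect_equal(d$values[2, 2], 30 * sqrt(2))
  expect_error(euclidean_distance(rg(matrix(0, 3, 3))), "empty")
  # brute force over a random 8x8 mask
  set.seed(21)
  m <- matrix(runif(64) < 0.2, 8, 8)
  m[2, 7] <- TRUE
  tg <- which(m, arr.ind = TRUE)
  bf <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    bf[i, j] <- 30 * sqrt(min((i - tg[, 1])^2 + (j - tg[, 2])^2))
  }
  expect_equal(euclidean_distance(rg(m * 1, cell_size = 30))$values, bf)
  # point targets measured to exact coordinates
  like <- rg(matrix(0, 4, 4), cell_size = 100)
  dp <- euclidean_distance(cbind(150, 350), like = like)
  expect_equal(dp$values[1, 2], 0)           # cell center (150, 350)
  expect_equal(dp$values[1, 1], 100)
})

test_that("slope and relief recover analytic terrain", {
  flat <- rg(matrix(7, 5, 5), cell_size = 100)
  expect_true(all(slope(flat)$values == 0))
  expect_true(all(relief(flat)$values == 0))
  # plane rising 1 m per metre -> 45 degrees
  plane <- rg(matrix(rep(1:6, each = 6) * 100, 6, byrow = TRUE), cell_size = 100)
  expect_equal(slope(plane)$values[3, 3], 45)
  # relief equals brute-force focal range
  set.seed(5)
  dem <- rg(matrix(rnorm(49, 100, 20), 7))
  rl <- relief(dem, window = 3)$values
  for (i in 1:7) for (j in 1:7) {
    win <- dem$values[max(1, i - 1):min(7, i + 1), max(1, j - 1):min(7, j + 1)]
    expect_equal(rl[i, j], max(win) - min(win))
  }
})

test_that("connected components respect connectivity and match flood fill", {
  # diagonal-touching cells: one patch under 8, two under 4
  m <- mask_at(3, 3, rbind(c(1, 1), c(2, 2)))
  expect_equal(connected_patches(m, 8)$n, 1)
  expect_equal(connected_patches(m, 4)$n, 2)
  # areas: cells x cell_size^2 / 1e6
  p <- connected_patches(mask_at(4, 4, rbind(c(1, 1), c(1, 2), c(4, 4))), 4)
  expect_equal(p$n, 2)
  expect_equal(sort(unname(p$areas_km2)), c(0.01, 0.02))
  # flood-fill oracle on random masks
  flood_count <- function(mask, conn) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    nbrs <- if (conn == 8) expand.grid(di = -1:1, dj = -1:1) else
      data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
    nbrs <- nbrs[!(nbrs$di == 0 & nbrs$dj == 0), ]
    cnt <- 0L
    for (s in which(mask)) {
      if (lab[s] != 0) next
      cnt <- cnt + 1L
      q <- s
      lab[s] <- cnt
      while (length(q)) {
        u <- q[1]; q <- q[-1]
        i <- (u - 1) %% nrow(mask) + 1; j <- (u - 1) %/% nrow(mask) + 1
        for (k in seq_len(nrow(nbrs))) {
          ii <- i + nbrs$di[k]; jj <- j + nbrs$dj[k]
          if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask)) next
          v <- (jj - 1) * nrow(mask) + ii
          if (mask[v] && lab[v] == 0) { lab[v] <- cnt; q <- c(q, v) }
        }
      }
    }
    cnt
  }
  set.seed(9)
  for (trial in 1:5) {
    m <- matrix(runif(100) < 0.4, 10, 10)
    for (conn in c(4, 8)) {
      expect_equal(connected_patches(rg(m * 1), conn)$n, flood_count(m, conn))
    }
  }
})

test_that("zonal statistics aggregate per zone and report all-nodata zones", {
  vals <- rg(matrix(c(1, 3, 10, NA), 2))
  zones <- rg(matrix(c(1, 1, 2, 3), 2))
  zm <- zonal_mean(vals, zones)
  expect_equal(unname(zm), c(2, 10, NA))
  # random zones against a direct mean
  set.seed(13)
  v <- matrix(rnorm(36), 6)
  z <- matrix(sample(0:3, 36, replace = TRUE), 6)
  zm2 <- zonal_mean(rg(v), rg(z))
  for (id in 1:3) expect_equal(unname(zm2[as.character(id)]), mean(v[z == id]))
})

test_that("cellwise operations preserve the nodata mask", {
  set.seed(17)
  m <- matrix(runif(36), 6)
  m[c(3, 14, 30)] <- NA
  g <- rg(m)
  nas <- is.na(m)
  expect_equal(is.na(minmax_normalize(g)$values), nas)
  expect_equal(is.na(quantile_classify(g, 4)$values), nas)
  expect_equal(is.na(slope(g)$values), nas)
  expect_equal(is.na(relief(g)$values), nas)
})

test_that("ascii grid round-trips values, geometry and nodata", {
  set.seed(19)
  m <- matrix(round(runif(20), 4), 4, 5)
  m[2, 3] <- NA
  g <- raster_grid(m, cell_size = 30, origin = c(500, 1200))
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, g$values)
  expect_equal(back$cell_size, g$cell_size)
  expect_equal(back$origin, g$origin)
})
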