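#' Land-use / land-cover legend
#'
#' The default legend mirrors the land classes used by the resistance table
#' and the service/sensitivity models: code, name, base resistance, habitat
#' suitability, habitat-sensitivity land score, an NDVI baseline for the
#' synthetic generator, and flags for water and cropland classes.
#'
#' @return data.frame with one row per LULC code.
#' @export
default_lulc_legend <- function() {
  data.frame(
    code = 1:10,
    name = c("paddy_field", "irrigated_land", "forestland", "grassland",
             "river", "lake", "urban", "rural", "mine", "bare"),
    resistance = c(100, 90, 1, 50, 10, 10, 800, 700, 1000, 50),
    habitat_suitability = c(0.4, 0.35, 1, 0.7, 0.9, 0.9, 0, 0.05, 0, 0.1),
    habitat_score = c(5, 5, 7, 5, 7, 7, 1, 1, 1, 3),
    ndvi_base = c(0.55, 0.5, 0.8, 0.6, 0.1, 0.1, 0.15, 0.2, 0.1, 0.25),
    is_water = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_cropland = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic landscape configuration
#'
#' Controls the seeded generator that stands in for real GIS inputs. Class
#' proportions default to the composition of a cropland-dominated alluvial
#' plain (≈62% cropland, 16% forest, 13% water, 8% built-up); spatial
#' structure comes from Gaussian-smoothed white noise with the configured
#' correlation length.
#'
#' @param shape c(nrows, ncols) of all rasters.
#' @param cell_size cell size in m.
#' @param class_proportions named numeric over legend codes (as names),
#'   summing to 1.
#' @param autocorr_length correlation length of the random fields, in cells.
#' @param n_roads1,n_roads2 number of class-I / class-II road polylines.
#' @param n_pollution number of pollution point sources (split between
#'   wastewater and air types).
#' @param n_reserves number of circular reserve ("red line") polygons.
#' @param reserve_radius_km reserve radius.
#' @param dem_relief total elevation range in m.
#' @param precip_mean,precip_sd mean and spatial sd of annual precipitation
#'   (mm/yr).
#' @param aet_fraction_range range of the smooth AET/P fraction field.
#' @param ndvi_noise sd of NDVI noise around the per-class baseline.
#' @param seed integer RNG seed.
#' @param legend LULC legend data.frame.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(shape = c(120, 120), cell_size = 100,
                             class_proportions = NULL,
                             autocorr_length = 8,
                             n_roads1 = 2, n_roads2 = 3,
                             n_pollution = 8, n_reserves = 3,
                             reserve_radius_km = 1.2,
                             dem_relief = 250,
                             precip_mean = 1150, precip_sd = 120,
                             aet_fraction_range = c(0.2, 0.9),
                             ndvi_noise = 0.1,
                             seed = 1,
                             legend = default_lulc_legend()) {
  if (is.null(class_proportions)) {
    class_proportions <- c(
      "1" = 0.40, "2" = 0.2175, "3" = 0.1626, "4" = 0.0036,
      "5" = 0.06, "6" = 0.0727, "7" = 0.05, "8" = 0.0295,
      "9" = 0.0, "10" = 0.0041
    )
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  stopifnot(length(shape) == 2, all(shape >= 2), cell_size > 0,
            autocorr_length > 0, n_roads1 >= 0, n_roads2 >= 0,
            n_pollution >= 0, n_reserves >= 0)
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 class_proportions = class_proportions,
                 autocorr_length = autocorr_length,
                 n_roads1 = n_roads1, n_roads2 = n_roads2,
                 n_pollution = n_pollution, n_reserves = n_reserves,
                 reserve_radius_km = reserve_radius_km,
                 dem_relief = dem_relief,
                 precip_mean = precip_mean, precip_sd = precip_sd,
                 aet_fraction_range = aet_fraction_range,
                 ndvi_noise = ndvi_noise, seed = seed, legend = legend),
            class = "landscape_config")
}

# evaluate `code` with a local RNG seed, restoring the caller's RNG state
local_seed_eval <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# standardized Gaussian random field: white noise smoothed with a separable
# Gaussian kernel of sd `range_cells`, then rescaled to mean 0 / sd 1
gaussian_field <- function(nr, nc, range_cells) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  k1 <- function(n) {
    idx <- seq_len(n)
    K <- stats::dnorm(outer(idx, idx, "-"), sd = range_cells)
    K / rowSums(K)
  }
  f <- k1(nr) %*% w %*% t(k1(nc))
  (f - mean(f)) / stats::sd(f)
}

# random edge-to-edge polyline with jittered interior vertices
random_road <- function(extent_x, extent_y, jitter) {
  sides <- sample(1:4, 2)
  pt_on <- function(s) {
    switch(s,
      cbind(stats::runif(1, 0, extent_x), extent_y),       # top
      cbind(extent_x, stats::runif(1, 0, extent_y)),       # right
      cbind(stats::runif(1, 0, extent_x), 0),              # bottom
      cbind(0, stats::runif(1, 0, extent_y)))              # left
  }
  a <- pt_on(sides[1]); b <- pt_on(sides[2])
  t <- c(0.25, 0.5, 0.75)
  mid <- cbind(a[1] + t * (b[1] - a[1]) + stats::rnorm(3, 0, jitter),
               a[2] + t * (b[2] - a[2]) + stats::rnorm(3, 0, jitter))
  mid[, 1] <- pmin(pmax(mid[, 1], 0), extent_x)
  mid[, 2] <- pmin(pmax(mid[, 2], 0), extent_y)
  unname(rbind(a, mid, b))
}

circle_polygon <- function(cx, cy, radius, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + radius * cos(th), cy + radius * sin(th))
}

#' Generate a synthetic landscape bundle
#'
#' Builds congruent raster layers (LULC, DEM, precipitation, AET, NDVI and the
#' six CSLE factor rasters) plus vector layers (two road classes, pollution
#' points typed wastewater/air, reserve polygons), fully reproducible from the
#' config seed. LULC is carved from a smoothed random field thresholded at
#' the cumulative class proportions, which yields spatially clustered classes
#' whose realized shares match the requested proportions up to ties.
#'
#' @param config a `landscape_config`.
#' @return list of class `landscape_bundle`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  local_seed_eval(config$seed, {
    nr <- config$shape[1]; nc <- config$shape[2]
    cs <- config$cell_size
    origin <- c(0, nr * cs)
    extent_x <- nc * cs; extent_y <- nr * cs
    rg <- function(v) raster_grid(v, cell_size = cs, origin = origin)

    # LULC: threshold a smooth field at cumulative proportion quantiles
    p <- config$class_proportions
    codes <- as.integer(names(p))
    keep <- p > 0
    f <- gaussian_field(nr, nc, config$autocorr_length)
    qs <- stats::quantile(f, probs = cumsum(p[keep]), names = FALSE)
    qs[length(qs)] <- Inf
    cls <- codes[keep][findInterval(f, c(-Inf, qs[-length(qs)]))]
    lulc <- rg(matrix(cls, nr, nc))

    # DEM scaled to the requested relief
    fd <- gaussian_field(nr, nc, config$autocorr_length * 1.5)
    dem <- rg((fd - min(fd)) / (max(fd) - min(fd)) * config$dem_relief + 30)

    # climate fields
    fp <- gaussian_field(nr, nc, config$autocorr_length * 2)
    precip <- rg(pmax(config$precip_mean + config$precip_sd * fp, 1))
    fa <- gaussian_field(nr, nc, config$autocorr_length * 2)
    ar <- config$aet_fraction_range
    frac <- ar[1] + (ar[2] - ar[1]) * stats::pnorm(fa)
    aet <- rg(precip$values * frac)

    # NDVI: class baseline + smooth noise, clipped to [0, 1]
    leg <- config$legend
    base <- leg$ndvi_base[match(lulc$values, leg$code)]
    fn <- gaussian_field(nr, nc, config$autocorr_length)
    ndvi <- rg(matrix(pmin(pmax(base + config$ndvi_noise * fn, 0), 1), nr, nc))

    # vector layers
    roads_1 <- lapply(seq_len(config$n_roads1), function(i)
      random_road(extent_x, extent_y, jitter = 4 * cs))
    roads_2 <- lapply(seq_len(config$n_roads2), function(i)
      random_road(extent_x, extent_y, jitter = 6 * cs))
    pollution_points <- if (config$n_pollution > 0) {
      data.frame(x = stats::runif(config$n_pollution, 0, extent_x),
                 y = stats::runif(config$n_pollution, 0, extent_y),
                 type = rep(c("wastewater", "air"),
                            length.out = config$n_pollution),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(x = numeric(0), y = numeric(0), type = character(0),
                 stringsAsFactors = FALSE)
    }
    # reserve radius capped so polygons always fit the extent
    rad <- min(config$reserve_radius_km * 1000,
               0.4 * min(extent_x, extent_y))
    rad <- max(rad, cs)
    reserves <- lapply(seq_len(config$n_reserves), function(i)
      circle_polygon(stats::runif(1, rad, extent_x - rad),
                     stats::runif(1, rad, extent_y - rad), rad))

    # CSLE factor rasters (simple documented couplings)
    sl <- slope(dem)
    csle_factors <- list(
      R = rg(0.18 * precip$values),
      K = rg(0.01 + 0.04 * stats::pnorm(gaussian_field(nr, nc, config$autocorr_length))),
      LS = rg(pmax((sin(sl$values * pi / 180) / 0.0896)^1.3, 0.01)),
      C = rg(pmin(pmax(1 - ndvi$values, 0), 1)),
      P = rg(matrix(ifelse(leg$is_cropland[match(lulc$values, leg$code)], 0.5, 1), nr, nc)),
      T = rg(matrix(ifelse(leg$is_cropland[match(lulc$values, leg$code)], 0.7, 1), nr, nc))
    )

    structure(list(lulc = lulc, dem = dem, precipitation = precip, aet = aet,
                   ndvi = ndvi, roads_1 = roads_1, roads_2 = roads_2,
                   pollution_points = pollution_points, reserves = reserves,
                   csle = csle_factors, legend = leg, config = config,
                   seed = config$seed),
              class = "landscape_bundle")
  })
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %d x %d cells @ %g m, seed %d\n",
              nrow(x$lulc$values), ncol(x$lulc$values),
              x$lulc$cell_size, x$seed))
  cat(sprintf("  roads: %d class-I, %d class-II; pollution points: %d; reserves: %d\n",
              length(x$roads_1), length(x$roads_2),
              nrow(x$pollution_points), length(x$reserves)))
  invisible(x)
}

#' Named test-fixture landscapes
#'
#' Small designed landscapes with known structure:
#' * `"uniform"`: a one-class (forestland), flat, road-free bundle whose
#'   resistance surface is constant.
#' * `"two_patch"`: the uniform bundle plus two reserve polygons at opposite
#'   corners.
#' * `"hourglass"`: a resistance raster with two low-resistance blocks joined
#'   by a single 1-cell-wide low-resistance bridge across a high-resistance
#'   matrix (contrast 1:10000 so that circuit leakage through the matrix is
#'   ~2%), plus the two block masks as sources and the bridge cell indices.
#' * `"wall"`: a uniform low-resistance raster crossed by a 3-cell-thick
#'   high-resistance vertical strip with no gap, plus left/right source
#'   strips; `meta` carries the wall geometry for hand computations.
#'
#' @param name preset id.
#' @param shape c(nrows, ncols).
#' @param cell_size cell size in m.
#' @return `"uniform"`/`"two_patch"`: a `landscape_bundle`;
#'   `"hourglass"`/`"wall"`: a list with `resistance` (raster_grid),
#'   `sources` (list of boolean raster_grids) and `meta`.
#' @export
landscape_fixture <- function(name = c("uniform", "hourglass", "wall", "two_patch"),
                              shape = c(60, 60), cell_size = 100) {
  name <- match.arg(name)
  nr <- shape[1]; nc <- shape[2]
  origin <- c(0, nr * cell_size)
  rg <- function(v) raster_grid(v, cell_size = cell_size, origin = origin)

  if (name %in% c("uniform", "two_patch")) {
    const <- function(v) rg(matrix(v, nr, nc))
    reserves <- list()
    if (name == "two_patch") {
      rad <- max(3 * cell_size, 0.1 * nr * cell_size)
      reserves <- list(
        circle_polygon(rad + cell_size, rad + cell_size, rad),
        circle_polygon(nc * cell_size - rad - cell_size,
                       nr * cell_size - rad - cell_size, rad)
      )
    }
    leg <- default_lulc_legend()
    bundle <- structure(list(
      lulc = const(3),                      # forestland
      dem = const(100),
      precipitation = const(1000),
      aet = const(500),
      ndvi = const(0.8),
      roads_1 = list(), roads_2 = list(),
      pollution_points = data.frame(x = numeric(0), y = numeric(0),
                                    type = character(0), stringsAsFactors = FALSE),
      reserves = reserves,
      csle = list(R = const(180), K = const(0.03), LS = const(0.5),
                  C = const(0.2), P = const(1), T = const(1)),
      legend = leg,
      config = NULL, seed = 0L
    ), class = "landscape_bundle")
    return(bundle)
  }

  if (name == "hourglass") {
    lo <- 1; hi <- 1e4
    res <- matrix(hi, nr, nc)
    r0 <- max(2, round(0.40 * nr)); r1 <- min(nr - 1, round(0.60 * nr))
    a0 <- max(2, round(0.05 * nc)); a1 <- round(0.20 * nc)
    b0 <- round(0.80 * nc); b1 <- min(nc - 1, round(0.95 * nc))
    res[r0:r1, a0:a1] <- lo
    res[r0:r1, b0:b1] <- lo
    brow <- round(0.5 * (r0 + r1))
    bridge_cols <- (a1 + 1):(b0 - 1)
    res[brow, bridge_cols] <- lo
    src_a <- matrix(FALSE, nr, nc); src_a[r0:r1, a0:a1] <- TRUE
    src_b <- matrix(FALSE, nr, nc); src_b[r0:r1, b0:b1] <- TRUE
    return(list(name = name, resistance = rg(res),
                sources = list(rg(src_a * 1L), rg(src_b * 1L)),
                meta = list(bridge_row = brow, bridge_cols = bridge_cols,
                            low = lo, high = hi)))
  }

  # wall: compact source blocks at mid-height so corridor swaths stay narrow
  lo <- 1; wall_res <- 50; thick <- 3
  res <- matrix(lo, nr, nc)
  w0 <- round(nc / 2) - 1
  wall_cols <- w0:(w0 + thick - 1)
  res[, wall_cols] <- wall_res
  rmid <- round(nr / 2)
  rows <- max(1, rmid - 5):min(nr, rmid + 5)
  src_a <- matrix(FALSE, nr, nc); src_a[rows, 1:4] <- TRUE
  src_b <- matrix(FALSE, nr, nc); src_b[rows, (nc - 3):nc] <- TRUE
  list(name = name, resistance = rg(res),
       sources = list(rg(src_a * 1L), rg(src_b * 1L)),
       meta = list(wall_cols = wall_cols, wall_resistance = wall_res,
                   background = lo, thickness = thick))
}
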