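#' Score breaks for sensitivity overlays
#'
#' An ordered set of left-closed intervals `[lower_i, lower_{i+1})` that
#' partition the value axis, each mapped to a score in {7, 5, 3, 1} (7 = most
#' sensitive). The last interval is open-ended.
#'
#' @param lower increasing vector of interval lower bounds (first must be 0).
#' @param score score per interval, drawn from {7, 5, 3, 1}.
#' @param axis label of the value axis (documentation only).
#' @return data.frame of class `score_breaks` with columns lower, upper,
#'   score.
#' @export
score_breaks <- function(lower, score, axis = "") {
  stopifnot(length(lower) == length(score), lower[1] == 0,
            !is.unsorted(lower, strictly = TRUE),
            all(score %in% c(7, 5, 3, 1)))
  out <- data.frame(lower = lower,
                    upper = c(lower[-1], Inf),
                    score = score)
  attr(out, "axis") <- axis
  class(out) <- c("score_breaks", "data.frame")
  out
}

#' Default sensitivity score tables
#'
#' Habitat sensitivity scores distance to major roads, distance to natural
#' reserves, land-cover class and NDVI; water sensitivity scores distance to
#' water bodies, to wastewater sources / sewage plants, and to air-pollution
#' sources. Higher scores mark more sensitive land.
#'
#' @return named list of `score_breaks` (land-cover scores live in the
#'   legend's `habitat_score` column).
#' @export
default_habitat_breaks <- function() {
  list(
    road = score_breaks(c(0, 1000, 2000, 3000), c(7, 5, 3, 1),
                        axis = "distance to major road (m)"),
    reserve = score_breaks(c(0, 3000, 6000, 9000), c(7, 5, 3, 1),
                           axis = "distance to natural reserves (m)"),
    ndvi = score_breaks(c(0, 0.3, 0.5, 0.7), c(1, 3, 5, 7), axis = "NDVI")
  )
}

#' @rdname default_habitat_breaks
#' @export
default_water_breaks <- function() {
  list(
    water = score_breaks(c(0, 500, 1000, 1500), c(7, 5, 3, 1),
                         axis = "distance to rivers, lakes (m)"),
    wastewater = score_breaks(c(0, 3000, 6000, 9000), c(7, 5, 3, 1),
                              axis = "distance to wastewater sources (m)"),
    air = score_breaks(c(0, 4000, 8000, 12000), c(7, 5, 3, 1),
                       axis = "distance to polluting air sources (m)")
  )
}

#' Score a raster through interval breaks
#'
#' Per-cell lookup of the score of the interval containing the value.
#'
#' @param values raster_grid (distances, NDVI, ...); `Inf` falls in the last
#'   interval.
#' @param breaks a `score_breaks`.
#' @return raster_grid of scores.
#' @export
score_layer <- function(values, breaks) {
  stopifnot(inherits(breaks, "score_breaks"))
  v <- values$values
  ok <- !is.na(v)
  if (any(v[ok] < 0)) stop("score_layer: values below the first interval")
  idx <- findInterval(v[ok], breaks$lower)
  out <- v
  out[ok] <- breaks$score[idx]
  grid_like(values, out)
}

# distance raster to features; empty feature sets mean "infinitely far",
# which lands in the most permissive score / resistance class
distance_or_inf <- function(features, like, type = "points") {
  empty <- if (is.data.frame(features) || is.matrix(features)) {
    nrow(features) == 0
  } else {
    length(features) == 0
  }
  if (empty) {
    out <- grid_like(like, matrix(Inf, nrow(like$values), ncol(like$values)))
    out$values[is.na(like$values)] <- NA_real_
    return(out)
  }
  if (type == "points") {
    euclidean_distance(as.matrix(features), like = like)
  } else {
    mask <- rasterize_features(features, like, type = type)
    euclidean_distance(mask)
  }
}

# combine sub-score layers per decision: unweighted mean keeps the 1-7 scale
combine_scores <- function(layers, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  acc <- Reduce(`+`, lapply(layers, function(g) g$values))
  if (combine == "mean") acc <- acc / length(layers)
  grid_like(layers[[1]], acc)
}

#' Habitat sensitivity overlay
#'
#' Overlays four sub-scores — distance to major roads, distance to natural
#' reserves, land-cover class score and NDVI score — and combines them by
#' unweighted arithmetic mean (keeping the 1-7 scale; `combine = "sum"`
#' available).
#'
#' @param road_dist,reserve_dist raster_grids of distances in m.
#' @param lulc categorical raster_grid of LULC codes.
#' @param ndvi raster_grid of NDVI in \[0, 1\].
#' @param breaks list as from [default_habitat_breaks()].
#' @param legend LULC legend carrying the `habitat_score` column.
#' @param combine "mean" or "sum".
#' @return raster_grid of habitat sensitivity.
#' @export
habitat_sensitivity <- function(road_dist, reserve_dist, lulc, ndvi,
                                breaks = default_habitat_breaks(),
                                legend = default_lulc_legend(),
                                combine = "mean") {
  stopifnot_congruent(road_dist, reserve_dist, lulc, ndvi)
  lu_score <- grid_like(lulc, matrix(
    legend$habitat_score[match(lulc$values, legend$code)],
    nrow(lulc$values), ncol(lulc$values)))
  combine_scores(list(
    score_layer(road_dist, breaks$road),
    score_layer(reserve_dist, breaks$reserve),
    lu_score,
    score_layer(ndvi, breaks$ndvi)
  ), combine)
}

#' Water sensitivity overlay
#'
#' Overlays three sub-scores — distance to water bodies, to wastewater
#' sources or sewage treatment plants, and to air-pollution sources —
#' combined by unweighted arithmetic mean by default.
#'
#' @param water_dist,wastewater_dist,air_dist raster_grids of distances in m.
#' @param breaks list as from [default_water_breaks()].
#' @param combine "mean" or "sum".
#' @return raster_grid of water sensitivity.
#' @export
water_sensitivity <- function(water_dist, wastewater_dist, air_dist,
                              breaks = default_water_breaks(),
                              combine = "mean") {
  stopifnot_congruent(water_dist, wastewater_dist, air_dist)
  combine_scores(list(
    score_layer(water_dist, breaks$water),
    score_layer(wastewater_dist, breaks$wastewater),
    score_layer(air_dist, breaks$air)
  ), combine)
}

#' Soil loss by the multiplicative soil-loss equation
#'
#' `A = R x K x LS x C x P x T`: rainfall erosivity, soil erodibility, the
#' topographic slope-length/steepness factor, and the cover, engineering-
#' practice and tillage factors. All factors must be >= 0; the dimensionless
#' C, P, T factors must not exceed `ceiling`.
#'
#' @param factors named list of congruent raster_grids R, K, LS, C, P, T.
#' @param ceiling upper bound for C, P and T (default 1).
#' @return raster_grid of soil loss A in t/ha/yr.
#' @export
csle <- function(factors, ceiling = 1) {
  need <- c("R", "K", "LS", "C", "P", "T")
  stopifnot(all(need %in% names(factors)))
  do.call(stopifnot_congruent, unname(factors[need]))
  for (nm in need) {
    if (any(factors[[nm]]$values < 0, na.rm = TRUE)) {
      stop(sprintf("csle: factor %s has negative cells", nm))
    }
  }
  for (nm in c("C", "P", "T")) {
    if (any(factors[[nm]]$values > ceiling, na.rm = TRUE)) {
      stop(sprintf("csle: factor %s exceeds the ceiling %g", nm, ceiling))
    }
  }
  A <- Reduce(`*`, lapply(factors[need], function(g) g$values))
  grid_like(factors$R, A)
}

#' Integrated ecological sensitivity
#'
#' Min-max normalizes the habitat-sensitivity, water-sensitivity and soil-
#' loss layers, averages them with equal weights, and classifies the result
#' into quantile levels (non-sensitive ... extremely sensitive).
#'
#' @param habitat_s,water_s,soil_a congruent raster_grids.
#' @param n_classes number of quantile levels (default 4).
#' @return list with `index` (raster_grid in \[0, 1\]) and `classes`
#'   (raster_grid of levels 1..n_classes).
#' @export
integrated_sensitivity <- function(habitat_s, water_s, soil_a, n_classes = 4) {
  stopifnot_congruent(habitat_s, water_s, soil_a)
  n <- lapply(list(habitat_s, water_s, soil_a), minmax_normalize)
  idx <- grid_like(habitat_s,
                   (n[[1]]$values + n[[2]]$values + n[[3]]$values) / 3)
  list(index = idx, classes = quantile_classify(idx, n_classes))
}
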