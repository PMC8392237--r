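#' Resistance table
#'
#' Six weighted factors build the integrated resistance surface: the LULC
#' base resistance (weight 0.30), relief and slope (0.15 each), distance to
#' class-I and class-II roads (0.15 each) and distance to pollution sources
#' (0.10). Each factor maps its value axis onto per-class resistance values;
#' interval factors clamp values above the last printed break into the last
#' class. The default pollution breaks close the printed gap between 4000
#' and 6000 m by extending the 60-resistance class down to 4000 m, the only
#' gap-free reading that preserves five classes.
#'
#' @param legend LULC legend (supplies the per-class base resistance).
#' @return list of class `resistance_table`: per factor, a `weight` plus
#'   either a `classes` lookup (LULC) or `breaks`/`values` interval map.
#' @export
default_resistance_table <- function(legend = default_lulc_legend()) {
  structure(list(
    lulc = list(weight = 0.30,
                classes = stats::setNames(legend$resistance,
                                          as.character(legend$code))),
    relief = list(weight = 0.15,
                  breaks = c(0, 25, 50, 75, 100),
                  values = c(100, 80, 60, 40, 1)),
    slope = list(weight = 0.15,
                 breaks = c(0, 8, 15, 25, 35),
                 values = c(100, 80, 60, 40, 1)),
    road1_dist = list(weight = 0.15,
                      breaks = c(0, 200, 400, 800, 1600, 3200),
                      values = c(100, 80, 60, 40, 20, 1)),
    road2_dist = list(weight = 0.15,
                      breaks = c(0, 150, 250, 450, 800, 1000),
                      values = c(100, 80, 60, 40, 20, 1)),
    pollution_dist = list(weight = 0.10,
                          breaks = c(0, 2000, 4000, 8000, 10000),
                          values = c(100, 80, 60, 40, 1))
  ), class = "resistance_table")
}

#' Classify one resistance factor
#'
#' Looks up per-cell class resistance values: LULC codes through the class
#' table (a code without a row is an error), interval factors through
#' left-open breaks (values above the last break fall in the last class;
#' `Inf` distances land in the most permeable class).
#'
#' @param values raster_grid of factor values (LULC codes, relief m, slope
#'   degrees, or distances m).
#' @param spec one factor entry of a `resistance_table`.
#' @return raster_grid of class resistance values.
#' @export
classify_factor <- function(values, spec) {
  v <- values$values
  ok <- !is.na(v)
  out <- v
  if (!is.null(spec$classes)) {
    miss <- setdiff(unique(as.character(v[ok])), names(spec$classes))
    if (length(miss) > 0) {
      stop(sprintf("classify_factor: LULC code(s) %s have no resistance row",
                   paste(miss, collapse = ", ")))
    }
    out[ok] <- unname(spec$classes[as.character(v[ok])])
  } else {
    idx <- findInterval(v[ok], spec$breaks, left.open = TRUE)
    idx[v[ok] <= spec$breaks[1]] <- 1   # first interval is closed at 0
    idx <- pmin(pmax(idx, 1), length(spec$values))
    out[ok] <- spec$values[idx]
  }
  grid_like(values, out)
}

#' Integrated resistance surface
#'
#' Weighted overlay of the six classified factors. With the default table the
#' achievable range is \[1, 370\]: 1 when every factor sits in its most
#' permeable class, 370 when LULC is at its maximum (1000) and every other
#' factor at 100.
#'
#' @param factor_rasters named list of raster_grids matching the table's
#'   factor names (lulc, relief, slope, road1_dist, road2_dist,
#'   pollution_dist).
#' @param table a `resistance_table`.
#' @return raster_grid of integrated resistance.
#' @export
integrated_resistance <- function(factor_rasters,
                                  table = default_resistance_table()) {
  stopifnot(all(names(table) %in% names(factor_rasters)))
  w <- vapply(table, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("integrated_resistance: factor weights must sum to 1")
  }
  do.call(stopifnot_congruent, unname(factor_rasters[names(table)]))
  acc <- NULL
  for (f in names(table)) {
    cls <- classify_factor(factor_rasters[[f]], table[[f]])
    contrib <- table[[f]]$weight * cls$values
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  grid_like(factor_rasters[[names(table)[1]]], acc)
}

#' Factor rasters for the resistance surface from a landscape bundle
#'
#' Derives the six factor rasters: the LULC map, relief (focal range of the
#' DEM), slope, distances to the two rasterized road classes and distance to
#' pollution points. Empty road/pollution sets yield infinite distances,
#' i.e. the most permeable class.
#'
#' @param bundle a `landscape_bundle`.
#' @param relief_window relief focal window (cells).
#' @return named list of raster_grids.
#' @export
bundle_resistance_factors <- function(bundle, relief_window = 3) {
  lu <- bundle$lulc
  list(
    lulc = lu,
    relief = relief(bundle$dem, window = relief_window),
    slope = slope(bundle$dem),
    road1_dist = distance_or_inf(bundle$roads_1, lu, type = "lines"),
    road2_dist = distance_or_inf(bundle$roads_2, lu, type = "lines"),
    pollution_dist = distance_or_inf(
      bundle$pollution_points[, c("x", "y"), drop = FALSE], lu, type = "points")
  )
}
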