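#' Ecological importance surface
#'
#' Equal-weight combination of the min-max-normalized integrated-services and
#' integrated-sensitivity layers, with quantile levels (non-important ...
#' extremely important).
#'
#' @param services raster_grid (integrated ecosystem services).
#' @param sensitivity raster_grid (integrated ecological sensitivity index).
#' @param n_classes number of quantile levels (default 4).
#' @return list with `index` (raster_grid in \[0, 1\]) and `classes`.
#' @export
ecological_importance <- function(services, sensitivity, n_classes = 4) {
  stopifnot_congruent(services, sensitivity)
  ns <- minmax_normalize(services)
  nx <- minmax_normalize(sensitivity)
  idx <- grid_like(services, 0.5 * ns$values + 0.5 * nx$values)
  list(index = idx, classes = quantile_classify(idx, n_classes))
}

#' Select ecological-source patches
#'
#' Candidate cells are the top importance class ("extremely important";
#' `top_classes = 2` widens to the top two classes) unioned with the
#' rasterized ecological red line. Candidates are split into 8-connected
#' patches; patches smaller than `min_area_km2` are dropped unless they
#' intersect the red line (statutory reserves are kept wholesale).
#'
#' @param importance_classes raster_grid of importance class labels (from
#'   [ecological_importance()]).
#' @param redline list of red-line polygons (possibly empty).
#' @param min_area_km2 minimum patch area (> 0), default 10.
#' @param top_classes how many of the highest classes form candidates.
#' @return list of `source_patch` objects, sorted by area descending; each
#'   has id, mask (boolean raster_grid), area_km2, centroid (x, y),
#'   from_redline.
#' @export
select_sources <- function(importance_classes, redline = list(),
                           min_area_km2 = 10, top_classes = 1) {
  stopifnot(min_area_km2 > 0)
  cls <- importance_classes$values
  kmax <- max(cls, na.rm = TRUE)
  cand <- !is.na(cls) & cls > kmax - top_classes
  red_mask <- matrix(FALSE, nrow(cls), ncol(cls))
  if (length(redline) > 0) {
    red <- rasterize_features(redline, importance_classes, type = "polygons")
    red_mask <- !is.na(red$values) & red$values > 0
  }
  cand <- cand | red_mask
  cand_grid <- grid_like(importance_classes, cand * 1L)
  patches <- connected_patches(cand_grid, connectivity = 8)
  if (patches$n == 0) {
    stop("select_sources: no candidate patches; relax min_area_km2 or top_classes")
  }
  lab <- patches$labels$values
  keep <- list()
  for (id in seq_len(patches$n)) {
    m <- lab == id
    on_red <- any(m & red_mask)
    area <- patches$areas_km2[[as.character(id)]]
    if (area < min_area_km2 && !on_red) next
    rc <- which(m, arr.ind = TRUE)
    xy <- rowcol_to_xy(importance_classes, rc[, 1], rc[, 2])
    keep[[length(keep) + 1]] <- structure(
      list(id = NA_integer_,
           mask = grid_like(importance_classes, m * 1L),
           area_km2 = area,
           centroid = c(mean(xy[, 1]), mean(xy[, 2])),
           from_redline = on_red),
      class = "source_patch")
  }
  if (length(keep) == 0) {
    stop("select_sources: every patch fell below min_area_km2; relax the threshold")
  }
  ord <- order(vapply(keep, `[[`, numeric(1), "area_km2"), decreasing = TRUE)
  keep <- keep[ord]
  for (i in seq_along(keep)) keep[[i]]$id <- i
  keep
}

#' Wrap a boolean mask as a source patch
#'
#' Convenience constructor used by the fixtures and tests: computes area and
#' centroid from the mask.
#'
#' @param mask boolean raster_grid.
#' @param id patch id.
#' @param from_redline red-line flag.
#' @return a `source_patch`.
#' @export
as_source_patch <- function(mask, id = 1L, from_redline = FALSE) {
  m <- !is.na(mask$values) & mask$values > 0
  if (!any(m)) stop("as_source_patch: empty mask")
  rc <- which(m, arr.ind = TRUE)
  xy <- rowcol_to_xy(mask, rc[, 1], rc[, 2])
  structure(list(id = as.integer(id),
                 mask = grid_like(mask, m * 1L),
                 area_km2 = sum(m) * mask$cell_size^2 / 1e6,
                 centroid = c(mean(xy[, 1]), mean(xy[, 2])),
                 from_redline = from_redline),
            class = "source_patch")
}

#' @export
print.source_patch <- function(x, ...) {
  cat(sprintf("<source_patch> id %d, area %.3f km2, centroid (%.0f, %.0f)%s\n",
              x$id, x$area_km2, x$centroid[1], x$centroid[2],
              if (x$from_redline) ", red-line" else ""))
  invisible(x)
}

#' Summarize source patches
#'
#' @param sources list of `source_patch`.
#' @return data.frame with id, area_km2, centroid coordinates, from_redline.
#' @export
sources_table <- function(sources) {
  data.frame(
    id = vapply(sources, `[[`, integer(1), "id"),
    area_km2 = vapply(sources, `[[`, numeric(1), "area_km2"),
    x = vapply(sources, function(s) s$centroid[1], numeric(1)),
    y = vapply(sources, function(s) s$centroid[2], numeric(1)),
    from_redline = vapply(sources, `[[`, logical(1), "from_redline")
  )
}
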