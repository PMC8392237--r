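#' Min-max normalization to the unit interval
#'
#' Rescales valid cells by (v - min) / (max - min). A constant raster has no
#' range to stretch; it normalizes to all zeros (keeping downstream sums
#' defined) and a warning is issued.
#'
#' @param r a raster_grid with at least one valid cell.
#' @return raster_grid in \[0, 1\]; nodata preserved.
#' @export
minmax_normalize <- function(r) {
  v <- r$values
  ok <- !is.na(v)
  if (!any(ok)) stop("minmax_normalize: raster has no valid cells")
  lo <- min(v[ok]); hi <- max(v[ok])
  out <- v
  if (hi == lo) {
    warning("minmax_normalize: constant raster; returning all zeros")
    out[ok] <- 0
  } else {
    out[ok] <- (v[ok] - lo) / (hi - lo)
  }
  grid_like(r, out)
}

#' Quantile classification into equal-rank classes
#'
#' Class c collects cells whose rank fraction falls in ((c-1)/n, c/n]. Tied
#' values are kept together and assigned to the lower class, so the map of
#' classes is a deterministic monotone step function of the values. If fewer
#' distinct values than classes exist, classes collapse (with a warning).
#'
#' @param r a raster_grid.
#' @param n_classes number of classes (>= 2).
#' @return raster_grid of integer class labels 1..n_classes.
#' @export
quantile_classify <- function(r, n_classes = 4) {
  stopifnot(n_classes >= 2)
  v <- r$values
  ok <- !is.na(v)
  x <- v[ok]
  n <- length(x)
  if (n == 0) stop("quantile_classify: raster has no valid cells")
  # rank fraction of the smallest member of each tie group
  below <- (rank(x, ties.method = "min") - 1) / n
  cls <- floor(below * n_classes) + 1
  cls <- pmin(cls, n_classes)
  if (length(unique(x)) < n_classes) {
    warning("quantile_classify: fewer distinct values than classes; classes collapse")
  }
  out <- v
  out[ok] <- cls
  grid_like(r, out)
}

#' Euclidean distance to the nearest target
#'
#' Distance (m) from every cell center to the nearest target. Targets may be
#' a boolean raster_grid (exact distance transform between cell centers), a
#' two-column matrix of point coordinates, or a list of polyline coordinate
#' matrices (densified to half-cell spacing and measured exactly to the
#' sampled vertices).
#'
#' @param targets boolean raster_grid, point matrix, or list of polylines.
#' @param like reference raster_grid (required for vector targets).
#' @return raster_grid of distances in metres; 0 on targets.
#' @export
euclidean_distance <- function(targets, like = NULL) {
  if (is_raster_grid(targets)) {
    m <- targets$values
    tm <- !is.na(m) & (m != 0)
    if (!any(tm)) stop("euclidean_distance: empty target set")
    d <- cpp_edt(tm) * targets$cell_size
    d[is.infinite(d)] <- NA_real_
    out <- grid_like(targets, d)
    out$values[is.na(targets$values)] <- NA_real_
    return(out)
  }
  if (is.null(like)) stop("euclidean_distance: `like` grid required for vector targets")
  if (is.list(targets) && !is.matrix(targets)) {
    pts <- do.call(rbind, lapply(targets, densify_line, spacing = like$cell_size / 2))
  } else {
    pts <- as.matrix(targets)
  }
  if (is.null(pts) || nrow(pts) == 0) stop("euclidean_distance: empty target set")
  cc <- cell_centers(like)
  nr <- nrow(like$values); nc <- ncol(like$values)
  dmin <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(pts))) {
    d2 <- (cc$x - pts[k, 1])^2 + (cc$y - pts[k, 2])^2
    dmin <- pmin(dmin, d2)
  }
  out <- sqrt(dmin)
  out[is.na(like$values)] <- NA_real_
  grid_like(like, out)
}

# sample points along a polyline at a fixed spacing (keeping vertices)
densify_line <- function(coords, spacing) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 1) return(coords)
  out <- list(coords[1, , drop = FALSE])
  for (k in seq_len(nrow(coords) - 1)) {
    a <- coords[k, ]; b <- coords[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    nstep <- max(1L, ceiling(len / spacing))
    t <- seq_len(nstep) / nstep
    out[[length(out) + 1]] <- cbind(a[1] + t * (b[1] - a[1]),
                                    a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Terrain derivatives: slope and relief
#'
#' Slope is computed from central finite differences of the elevation (one-
#' sided at edges) as `atan(sqrt((dz/dx)^2 + (dz/dy)^2))` in degrees. Relief
#' is the focal elevation range (max - min) over a square window; the window
#' defaults to 3x3 cells.
#'
#' @param dem raster_grid of elevations in m.
#' @param window odd window edge length in cells (relief only).
#' @return raster_grid of slope in degrees / relief in m.
#' @export
slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- dem$cell_size
  # finite-difference gradient, central where both neighbors exist, one-sided
  # at edges and next to nodata; isolated cells get slope 0
  grad <- function(lower, upper) {
    nl <- !is.na(lower); nu <- !is.na(upper)
    lo <- ifelse(nl, lower, z)
    up <- ifelse(nu, upper, z)
    den <- (nl + nu) * cs
    out <- (up - lo) / den
    out[den == 0] <- 0
    out
  }
  left <- if (nc >= 2) cbind(NA_real_, z[, -nc, drop = FALSE]) else matrix(NA_real_, nr, nc)
  right <- if (nc >= 2) cbind(z[, -1, drop = FALSE], NA_real_) else matrix(NA_real_, nr, nc)
  up <- if (nr >= 2) rbind(NA_real_, z[-nr, , drop = FALSE]) else matrix(NA_real_, nr, nc)
  down <- if (nr >= 2) rbind(z[-1, , drop = FALSE], NA_real_) else matrix(NA_real_, nr, nc)
  dzdx <- grad(left, right)
  dzdy <- grad(up, down)
  s <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  s[is.na(z)] <- NA_real_
  grid_like(dem, s)
}

#' @rdname slope
#' @export
relief <- function(dem, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  out <- cpp_focal_range(dem$values, as.integer((window - 1) / 2))
  out[is.na(dem$values)] <- NA_real_
  grid_like(dem, out)
}

#' Connected-component labeling of a boolean raster
#'
#' @param mask boolean raster_grid (non-zero, non-NA cells are foreground).
#' @param connectivity 4 or 8.
#' @return list of class `patch_labeling`: `labels` (raster_grid of integer
#'   labels, 0 = background), `areas_km2` (named per-label areas), `n`,
#'   `connectivity`.
#' @export
connected_patches <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask$values
  fg <- !is.na(m) & (m != 0)
  lab <- cpp_label(fg, as.integer(connectivity))
  n <- max(lab)
  areas <- if (n > 0) {
    tab <- tabulate(lab[lab > 0], nbins = n)
    stats::setNames(tab * mask$cell_size^2 / 1e6, seq_len(n))
  } else stats::setNames(numeric(0), character(0))
  structure(list(labels = grid_like(mask, lab), areas_km2 = areas,
                 n = n, connectivity = connectivity),
            class = "patch_labeling")
}

#' Zonal mean of a value raster over labeled zones
#'
#' @param values raster_grid of values.
#' @param zones a `patch_labeling` or raster_grid of integer zone labels
#'   (0 = background).
#' @param fun summary function (default mean).
#' @return named numeric vector, one entry per zone label; zones whose cells
#'   are all nodata report `NA`.
#' @export
zonal_stat <- function(values, zones, fun = mean) {
  lab <- if (inherits(zones, "patch_labeling")) zones$labels$values else zones$values
  stopifnot(identical(dim(lab), dim(values$values)))
  v <- values$values
  ids <- sort(unique(lab[lab > 0 & !is.na(lab)]))
  out <- vapply(ids, function(id) {
    x <- v[lab == id]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else fun(x)
  }, numeric(1))
  stats::setNames(out, ids)
}

#' @rdname zonal_stat
#' @export
zonal_mean <- function(values, zones) zonal_stat(values, zones, mean)

#' Rasterize vector features onto a reference grid
#'
#' Points mark their containing cell; polylines mark every cell within half a
#' cell of the densified line; polygons mark cells whose centers fall inside.
#'
#' @param features point matrix, list of polyline matrices, or list of polygon
#'   matrices.
#' @param like reference raster_grid.
#' @param type "points", "lines", or "polygons".
#' @return boolean raster_grid mask.
#' @export
rasterize_features <- function(features, like,
                               type = c("points", "lines", "polygons")) {
  type <- match.arg(type)
  nr <- nrow(like$values); nc <- ncol(like$values)
  m <- matrix(FALSE, nr, nc)
  if (type == "points") {
    pts <- as.matrix(features)
    if (nrow(pts) > 0) {
      rc <- xy_to_rowcol(like, pts[, 1], pts[, 2])
      m[rc] <- TRUE
    }
  } else if (type == "lines") {
    for (ln in features) {
      pts <- densify_line(ln, spacing = like$cell_size / 2)
      rc <- xy_to_rowcol(like, pts[, 1], pts[, 2])
      m[rc] <- TRUE
    }
  } else {
    cc <- cell_centers(like)
    for (pg in features) {
      pg <- as.matrix(pg)
      inside <- point_in_polygon(cc$x, cc$y, pg)
      m <- m | inside
    }
  }
  grid_like(like, m * 1L)
}

# even-odd ray casting; x, y matrices of query coordinates
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- matrix(FALSE, nrow(x), ncol(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
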