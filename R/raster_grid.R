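#' Raster grid objects
#'
#' A `raster_grid` is the common currency of the pipeline: a 2-D matrix of
#' cell values together with the cell size (m) and the map coordinate of the
#' top-left corner. Nodata cells are stored as `NA` and propagate through
#' every cellwise operation. Grids are row-major with the first row at the
#' top; the center of cell (i, j) sits at
#' `x = x0 + (j - 0.5) * cell_size`, `y = y0 - (i - 0.5) * cell_size`.
#'
#' @param values numeric (or integer) matrix of cell values; `NA` = nodata.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, map (x, y) of the top-left corner.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 100, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0,
            length(origin) == 2)
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: min %g, mean %g, max %g; %d nodata cells\n",
                min(v[ok]), mean(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Test or assert that grids share shape, cell size and origin
#'
#' @param ... raster_grid objects.
#' @return `congruent()` returns TRUE/FALSE; `stopifnot_congruent()` errors
#'   with the offending property.
#' @export
congruent <- function(...) {
  gs <- list(...)
  if (length(gs) < 2) return(TRUE)
  ref <- gs[[1]]
  all(vapply(gs[-1], function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      isTRUE(all.equal(g$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(g$origin, ref$origin))
  }, logical(1)))
}

#' @rdname congruent
#' @export
stopifnot_congruent <- function(...) {
  if (!congruent(...)) {
    stop("raster layers must share shape, cell_size and origin", call. = FALSE)
  }
  invisible(TRUE)
}

# Rebuild a grid with new values, inheriting geometry (and the nodata mask of
# `like` unless the new values carry their own NAs).
grid_like <- function(like, values) {
  raster_grid(values, cell_size = like$cell_size, origin = like$origin)
}

# Apply a vectorized function cellwise, preserving nodata.
grid_map <- function(g, f, ...) {
  v <- g$values
  ok <- !is.na(v)
  out <- v
  out[ok] <- f(v[ok], ...)
  grid_like(g, out)
}

#' Cell-center coordinates
#'
#' @param g a raster_grid.
#' @return list with matrices `x` and `y` of cell-center map coordinates.
#' @export
cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  x <- g$origin[1] + (matrix(rep(seq_len(nc), each = nr), nr) - 0.5) * g$cell_size
  y <- g$origin[2] - (matrix(rep(seq_len(nr), nc), nr) - 0.5) * g$cell_size
  list(x = x, y = y)
}

# map coords -> (row, col), clamped to the grid
xy_to_rowcol <- function(g, x, y) {
  col <- pmin(pmax(ceiling((x - g$origin[1]) / g$cell_size), 1), ncol(g$values))
  row <- pmin(pmax(ceiling((g$origin[2] - y) / g$cell_size), 1), nrow(g$values))
  cbind(row = row, col = col)
}

rowcol_to_xy <- function(g, row, col) {
  cbind(x = g$origin[1] + (col - 0.5) * g$cell_size,
        y = g$origin[2] - (row - 0.5) * g$cell_size)
}

#' Read and write Esri ASCII grids
#'
#' Plain-text single-band raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values, top row first.
#'
#' @param g a raster_grid.
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `read_ascii_grid()` returns a raster_grid; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nr * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]
  nodata <- vals[["nodata_value"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, cell_size = cs,
              origin = c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * cs))
}

#' Write point / line / polygon layers as GeoJSON
#'
#' Minimal GeoJSON writer for the pipeline's vector outputs. `features` is a
#' list of features, each a list with `geometry` (for points: length-2 xy; for
#' lines/polygons: a two-column coordinate matrix) and an optional named list
#' `properties`.
#'
#' @param features list of features (see details).
#' @param type one of "Point", "LineString", "Polygon" (applied to all
#'   features).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(features, type = c("Point", "LineString", "Polygon"),
                          path) {
  type <- match.arg(type)
  feat_list <- lapply(features, function(f) {
    coords <- f$geometry
    g <- switch(type,
      Point = list(type = "Point", coordinates = as.numeric(coords)),
      LineString = list(type = "LineString",
                        coordinates = apply(unname(coords), 1, as.numeric,
                                            simplify = FALSE)),
      Polygon = {
        m <- unname(coords)
        if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
        list(type = "Polygon",
             coordinates = list(apply(m, 1, as.numeric, simplify = FALSE)))
      })
    list(type = "Feature", geometry = g,
         properties = if (is.null(f$properties)) stats::setNames(list(), character(0)) else f$properties)
  })
  obj <- list(type = "FeatureCollection", features = feat_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
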