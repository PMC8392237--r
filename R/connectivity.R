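#' Cost-weighted distance from a source patch
#'
#' Multi-source Dijkstra over the 8-neighbor raster graph. The cost of moving
#' between adjacent cells is the mean of the two cell resistances times the
#' center-to-center distance (cell_size, x sqrt(2) for diagonal moves). Patch
#' cells sit at distance 0; nodata cells block movement.
#'
#' @param resistance raster_grid of positive resistance values.
#' @param patch boolean raster_grid (or `source_patch`) of source cells.
#' @return raster_grid of cost-weighted distances (NA where unreachable).
#' @export
cost_weighted_distance <- function(resistance, patch) {
  res <- cwd_fields(resistance, patch)
  res$cwd
}

# internal: CWD raster plus the predecessor matrix for path backtracking
cwd_fields <- function(resistance, patch) {
  mask <- patch_mask(patch)
  stopifnot_congruent(resistance, mask)
  src <- !is.na(mask$values) & mask$values > 0
  if (!any(src)) stop("cost_weighted_distance: patch has no cells on the grid")
  out <- cpp_dijkstra(resistance$values, src, resistance$cell_size)
  list(cwd = grid_like(resistance, out$dist), parent = out$parent)
}

patch_mask <- function(patch) {
  if (inherits(patch, "source_patch")) patch$mask else patch
}

# backtrack the least-cost path from a cell to the source of a CWD field;
# returns a (row, col) matrix ordered source -> cell
backtrack_path <- function(parent, start_idx, nr) {
  path <- integer(0)
  idx <- start_idx
  repeat {
    path <- c(path, idx)
    p <- parent[idx]
    if (p == 0) break
    idx <- p
  }
  path <- rev(path)
  cbind(row = (path - 1) %% nr + 1, col = (path - 1) %/% nr + 1)
}

polyline_length_km <- function(coords) {
  if (nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2))) / 1000
}

#' Least-cost corridors between source patches
#'
#' For every retained source pair, backtracks the least-cost path (LCP)
#' through the cost-weighted distance fields, and maps the corridor swath as
#' the cells where `CWD_A + CWD_B - lcp_cost <= swath_threshold` plus a fixed
#' 1-km-wide buffer of the LCP polyline.
#'
#' Pair retention (`pairing = "adjacent"`): mutually-nearest pairs by LCP
#' cost, plus every pair whose LCP does not cross a third source — the pruned
#' adjacency used by corridor-mapping practice. `pairing = "all"` keeps all
#' reachable pairs. Disconnected pairs are dropped with a warning.
#'
#' @param resistance raster_grid of positive resistances.
#' @param sources list of `source_patch` (>= 2).
#' @param pairing "adjacent" or "all".
#' @param swath_threshold cost-units threshold for the swath; defaults to
#'   half the corridor width times the landscape's minimum resistance, which
#'   makes the swath about 1 km wide on a uniform landscape.
#' @param corridor_width_m buffered corridor width (default 1000 m).
#' @return list of `corridor_record`: pair ids, lcp (map-coordinate
#'   polyline), lcp_cost, length_km, swath_mask, buffer_mask.
#' @export
least_cost_corridors <- function(resistance, sources,
                                 pairing = c("adjacent", "all"),
                                 swath_threshold = NULL,
                                 corridor_width_m = 1000) {
  pairing <- match.arg(pairing)
  n <- length(sources)
  if (n < 2) stop("least_cost_corridors: need at least 2 sources")
  if (is.null(swath_threshold)) {
    swath_threshold <- 0.5 * corridor_width_m *
      min(resistance$values, na.rm = TRUE)
  }
  nr <- nrow(resistance$values)
  fields <- lapply(sources, function(s) cwd_fields(resistance, s))
  masks <- lapply(sources, function(s) {
    m <- patch_mask(s)$values
    !is.na(m) & m > 0
  })

  # pairwise LCP costs (min of CWD_i over patch j)
  cost <- matrix(NA_real_, n, n)
  entry <- matrix(NA_integer_, n, n)  # best entry cell (linear idx) into j
  for (i in seq_len(n)) {
    di <- fields[[i]]$cwd$values
    for (j in seq_len(n)) {
      if (i == j) next
      vals <- di[masks[[j]]]
      if (all(is.na(vals))) next
      cost[i, j] <- min(vals, na.rm = TRUE)
      which_j <- which(masks[[j]])
      entry[i, j] <- which_j[which.min(ifelse(is.na(vals), Inf, vals))]
    }
  }

  nearest <- apply(cost, 1, function(x) if (all(is.na(x))) NA_integer_ else which.min(x))
  records <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.na(cost[i, j])) {
        warning(sprintf("corridor (%d, %d): patches are disconnected; skipped", i, j))
        next
      }
      path_rc <- backtrack_path(fields[[i]]$parent, entry[i, j], nr)
      if (pairing == "adjacent") {
        mutual <- !is.na(nearest[i]) && !is.na(nearest[j]) &&
          nearest[i] == j && nearest[j] == i
        through_third <- FALSE
        for (k in seq_len(n)) {
          if (k == i || k == j) next
          if (any(masks[[k]][path_rc])) { through_third <- TRUE; break }
        }
        if (through_third && !mutual) next
      }
      lcp_cost <- cost[i, j]
      swath <- fields[[i]]$cwd$values + fields[[j]]$cwd$values - lcp_cost
      swath_mask <- !is.na(swath) & swath <= swath_threshold
      coords <- rowcol_to_xy(resistance, path_rc[, 1], path_rc[, 2])
      path_grid <- grid_like(resistance,
                             matrix(0, nr, ncol(resistance$values)))
      path_grid$values[path_rc] <- 1
      buf <- euclidean_distance(path_grid)
      buffer_mask <- !is.na(buf$values) & buf$values <= corridor_width_m / 2
      records[[length(records) + 1]] <- structure(list(
        pair = c(i, j),
        lcp = coords,
        lcp_cost = lcp_cost,
        length_km = polyline_length_km(coords),
        swath_mask = grid_like(resistance, swath_mask * 1L),
        buffer_mask = grid_like(resistance, buffer_mask * 1L),
        centrality = NA_real_,
        improvement = NA_real_, improvement_level = NA_character_,
        priority = NA_real_, priority_level = NA_character_
      ), class = "corridor_record")
    }
  }
  if (length(records) == 0) stop("least_cost_corridors: no reachable pairs")
  records
}

#' @export
print.corridor_record <- function(x, ...) {
  cat(sprintf("<corridor_record> pair (%d, %d): cost %.1f, length %.2f km\n",
              x$pair[1], x$pair[2], x$lcp_cost, x$length_km))
  invisible(x)
}

#' Summarize corridors
#'
#' @param corridors list of `corridor_record`.
#' @return data.frame of per-corridor attributes.
#' @export
corridors_table <- function(corridors) {
  data.frame(
    from = vapply(corridors, function(r) r$pair[1], numeric(1)),
    to = vapply(corridors, function(r) r$pair[2], numeric(1)),
    lcp_cost = vapply(corridors, `[[`, numeric(1), "lcp_cost"),
    length_km = vapply(corridors, `[[`, numeric(1), "length_km"),
    centrality = vapply(corridors, `[[`, numeric(1), "centrality"),
    improvement = vapply(corridors, `[[`, numeric(1), "improvement"),
    improvement_level = vapply(corridors, `[[`, character(1), "improvement_level"),
    priority = vapply(corridors, `[[`, numeric(1), "priority"),
    priority_level = vapply(corridors, `[[`, character(1), "priority_level")
  )
}

# vectorized 8-neighbor edge list over valid (non-NA) cells, column-major
# linear indices; step is 1 for rook moves, sqrt(2) for diagonals
grid_edge_list <- function(res) {
  nr <- nrow(res); nc <- ncol(res)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pairs <- list(
    list(a = idx[, -nc, drop = FALSE], b = idx[, -1, drop = FALSE], s = 1),
    list(a = idx[-nr, , drop = FALSE], b = idx[-1, , drop = FALSE], s = 1),
    list(a = idx[-nr, -nc, drop = FALSE], b = idx[-1, -1, drop = FALSE], s = sqrt(2)),
    list(a = idx[-1, -nc, drop = FALSE], b = idx[-nr, -1, drop = FALSE], s = sqrt(2))
  )
  a <- unlist(lapply(pairs, function(p) as.vector(p$a)))
  b <- unlist(lapply(pairs, function(p) as.vector(p$b)))
  s <- unlist(lapply(pairs, function(p) rep(p$s, length(p$a))))
  ra <- res[a]; rb <- res[b]
  ok <- !is.na(ra) & !is.na(rb)
  list(a = a[ok], b = b[ok],
       resistance = 0.5 * (ra[ok] + rb[ok]) * s[ok])
}

#' Circuit-theory current map between two patches
#'
#' Treats the resistance raster as a resistor network (cell conductance =
#' 1/resistance; edge resistance = mean cell resistance x step length in cell
#' units), collapses the two patches to supernodes, injects `current` amperes
#' at patch A and withdraws it at patch B, and solves the Kirchhoff/Laplacian
#' system with sparse linear algebra. Per-cell current is half the sum of
#' absolute edge currents incident to the cell; patch cells are reported NA.
#'
#' @param resistance raster_grid of positive resistances.
#' @param patch_a,patch_b boolean raster_grids or `source_patch`es in the
#'   same connected component.
#' @param current injected current (default 1 A).
#' @return list: `current` (raster_grid), `effective_resistance`,
#'   `kcl_residual` (max absolute net current at non-terminal nodes).
#' @export
circuit_solve <- function(resistance, patch_a, patch_b, current = 1) {
  ma <- patch_mask(patch_a); mb <- patch_mask(patch_b)
  stopifnot_congruent(resistance, ma, mb)
  res <- resistance$values
  nr <- nrow(res); nc <- ncol(res)
  a_cells <- !is.na(ma$values) & ma$values > 0 & !is.na(res)
  b_cells <- !is.na(mb$values) & mb$values > 0 & !is.na(res)
  if (!any(a_cells) || !any(b_cells)) stop("circuit_solve: empty patch")
  if (any(a_cells & b_cells)) stop("circuit_solve: patches overlap")

  valid <- !is.na(res)
  node_of <- integer(nr * nc)
  plain <- valid & !a_cells & !b_cells
  m <- sum(plain)
  node_of[plain] <- seq_len(m)
  na_node <- m + 1L; nb_node <- m + 2L
  node_of[a_cells] <- na_node
  node_of[b_cells] <- nb_node
  nn <- m + 2L

  el <- grid_edge_list(res)
  i <- node_of[el$a]; j <- node_of[el$b]
  g <- 1 / el$resistance
  keep <- i != j
  i <- i[keep]; j <- j[keep]; g <- g[keep]

  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(g, g),
                            dims = c(nn, nn))
  dg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = dg) - W
  # ground patch B, inject at patch A
  keep_idx <- seq_len(nn)[-nb_node]
  rhs <- numeric(nn - 1)
  rhs[match(na_node, keep_idx)] <- current
  Lg <- L[keep_idx, keep_idx, drop = FALSE]
  v_part <- tryCatch(
    as.numeric(Matrix::solve(Lg, rhs)),
    error = function(e) stop("circuit_solve: singular system (are the patches connected?)")
  )
  v <- numeric(nn)
  v[keep_idx] <- v_part

  edge_cur <- g * (v[i] - v[j])
  flow <- numeric(nn)
  net <- numeric(nn)
  abs_cur <- abs(edge_cur)
  for (side in 1:2) {
    nd <- if (side == 1) i else j
    sgn <- if (side == 1) 1 else -1
    flow <- flow + unname(tapply_sum(abs_cur, nd, nn))
    net <- net + sgn * unname(tapply_sum(edge_cur, nd, nn))
  }
  kcl <- max(abs(net[seq_len(m)]), 0)

  cur <- matrix(NA_real_, nr, nc)
  cur[plain] <- 0.5 * flow[node_of[plain]]
  out <- grid_like(resistance, cur)
  list(current = out,
       effective_resistance = v[na_node] / current,
       kcl_residual = kcl)
}

# sum `x` by integer group `g` into a length-n vector (fast path of tapply)
tapply_sum <- function(x, g, n) {
  out <- numeric(n)
  acc <- rowsum(x, g)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Current-flow centrality of sources and corridors
#'
#' Builds the coarse network (one node per source, one link per corridor with
#' resistance equal to its LCP cost), injects 1 A between every node pair in
#' the same component, and accumulates absolute currents. Link centrality is
#' the accumulated |current| through the corridor; node centrality is the
#' accumulated throughflow (terminals count their injected current).
#'
#' @param corridors list of `corridor_record`.
#' @param n_sources number of source nodes.
#' @return list: `node_centrality` (numeric), `corridors` (records with
#'   `centrality` filled in).
#' @export
current_centrality <- function(corridors, n_sources) {
  if (n_sources < 2) stop("current_centrality: need at least 2 nodes")
  links <- do.call(rbind, lapply(corridors, function(r)
    data.frame(a = r$pair[1], b = r$pair[2], res = r$lcp_cost)))
  n <- n_sources
  G <- matrix(0, n, n)
  for (k in seq_len(nrow(links))) {
    g <- 1 / links$res[k]
    a <- links$a[k]; b <- links$b[k]
    G[a, b] <- G[a, b] + g
    G[b, a] <- G[b, a] + g
  }
  # components by repeated BFS on the link graph
  comp <- integer(n); cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    q <- s
    comp[s] <- cid
    while (length(q) > 0) {
      u <- q[1]; q <- q[-1]
      nbr <- which(G[u, ] > 0 & comp == 0)
      comp[nbr] <- cid
      q <- c(q, nbr)
    }
  }
  L <- diag(rowSums(G), n) - G
  node_cent <- numeric(n)
  link_cent <- numeric(nrow(links))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (comp[a] != comp[b]) next
      members <- which(comp == comp[a])
      Ls <- L[members, members, drop = FALSE]
      gi <- match(b, members)
      keep <- setdiff(seq_along(members), gi)
      rhs <- numeric(length(keep))
      rhs[match(match(a, members), keep)] <- 1
      v <- numeric(length(members))
      v[keep] <- solve(Ls[keep, keep, drop = FALSE], rhs)
      # link currents
      Ilink <- abs((v[match(links$a, members)] - v[match(links$b, members)]) /
                     links$res)
      in_comp <- links$a %in% members & links$b %in% members
      Ilink[!in_comp | is.na(Ilink)] <- 0
      link_cent <- link_cent + Ilink
      # node throughflow
      for (u in seq_along(members)) {
        node <- members[u]
        inc <- which((links$a == node | links$b == node) & in_comp)
        thr <- 0.5 * sum(Ilink[inc])
        if (node == a || node == b) thr <- thr + 0.5  # injected current
        node_cent[node] <- node_cent[node] + thr
      }
    }
  }
  for (k in seq_along(corridors)) corridors[[k]]$centrality <- link_cent[k]
  list(node_centrality = node_cent, corridors = corridors)
}

# quantile classes (1..n) of a score vector, ties to the lower class
quantile_class_vector <- function(x, n_classes = 4) {
  n <- length(x)
  below <- (rank(x, ties.method = "min") - 1) / n
  pmin(floor(below * n_classes) + 1, n_classes)
}

level_label <- function(cls) c("L", "M", "H", "V")[cls]

# greedy non-maximum suppression: pick highest-score cells at least
# `radius_cells` apart; ties broken by cell index
nms_top <- function(score, top_n, radius_cells) {
  cand <- which(!is.na(score) & score > 0)
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(-score[cand], cand)]
  nr <- nrow(score)
  picked <- integer(0)
  pr <- numeric(0); pc <- numeric(0)
  for (idx in ord) {
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    if (length(picked) > 0 &&
        any((pr - r)^2 + (pc - c)^2 < radius_cells^2)) next
    picked <- c(picked, idx)
    pr <- c(pr, r); pc <- c(pc, c)
    if (length(picked) >= top_n) break
  }
  picked
}

#' Pinch points from pairwise current maps
#'
#' Solves the circuit for every corridor's source pair, scores each swath
#' cell by the maximum pairwise current it carries, and returns the top-n
#' cells after non-maximum suppression (so the reported points are distinct
#' locations at least one suppression radius apart). Corridor priority levels
#' are quantile classes of the zonal maximum current over each swath.
#'
#' @param resistance raster_grid.
#' @param corridors list of `corridor_record`.
#' @param sources list of `source_patch`.
#' @param top_n number of pinch points to report (default 40).
#' @param suppression_radius_m non-maximum suppression radius (default
#'   1000 m).
#' @return list: `points` (data.frame row, col, x, y, score, rank), `score`
#'   (raster_grid of pairwise-max current), `corridors` (records with
#'   `priority`/`priority_level` filled), `kcl_residual` (worst over pairs).
#' @export
pinch_points <- function(resistance, corridors, sources, top_n = 40,
                         suppression_radius_m = 1000) {
  nr <- nrow(resistance$values); nc <- ncol(resistance$values)
  score <- matrix(NA_real_, nr, nc)
  worst_kcl <- 0
  pri <- numeric(length(corridors))
  for (k in seq_along(corridors)) {
    r <- corridors[[k]]
    sol <- circuit_solve(resistance, sources[[r$pair[1]]], sources[[r$pair[2]]])
    worst_kcl <- max(worst_kcl, sol$kcl_residual)
    inswath <- r$swath_mask$values > 0 & !is.na(sol$current$values)
    vals <- ifelse(inswath, sol$current$values, NA_real_)
    score <- pmax(score, vals, na.rm = TRUE)
    pri[k] <- if (any(inswath)) max(sol$current$values[inswath]) else 0
  }
  cls <- quantile_class_vector(pri)
  for (k in seq_along(corridors)) {
    corridors[[k]]$priority <- pri[k]
    corridors[[k]]$priority_level <- level_label(cls[k])
  }
  picked <- nms_top(score, top_n, suppression_radius_m / resistance$cell_size)
  rows <- (picked - 1) %% nr + 1; cols <- (picked - 1) %/% nr + 1
  xy <- rowcol_to_xy(resistance, rows, cols)
  pts <- data.frame(row = rows, col = cols, x = xy[, 1], y = xy[, 2],
                    score = score[picked], rank = seq_along(picked))
  list(points = pts, score = grid_like(resistance, score),
       corridors = corridors, kcl_residual = worst_kcl)
}

#' Moving-window barrier detection
#'
#' Scans candidate window centers (the corridor swaths) over radii from
#' `r_min` to `r_max` in steps of one cell. Each window's resistance is
#' restored to the landscape minimum, the pair's least-cost cost is
#' recomputed, and the improvement score is `IS = (cost_before -
#' cost_after) / (2 * radius)`. Per-cell IS keeps the best radius; the top-n
#' barriers are reported after non-maximum suppression, and corridor
#' improvement levels are quantile classes of the zonal mean IS.
#'
#' @param resistance raster_grid.
#' @param corridors list of `corridor_record`.
#' @param sources list of `source_patch`.
#' @param r_min,r_max search radii in m (r_min must be >= one cell).
#' @param top_n barriers to report (default 40).
#' @param restore_value resistance the window is restored to (default: the
#'   landscape minimum).
#' @param stride evaluate every stride-th swath cell (default 1 = all).
#' @param suppression_radius_m non-maximum suppression radius.
#' @return list: `barriers` (data.frame), `is` (raster_grid of improvement
#'   scores), `corridors` (records with `improvement`/`improvement_level`).
#' @export
barrier_scan <- function(resistance, corridors, sources,
                         r_min = 200, r_max = 1000, top_n = 40,
                         restore_value = NULL, stride = 1,
                         suppression_radius_m = 1000) {
  cs <- resistance$cell_size
  if (r_min < cs) stop("barrier_scan: r_min is smaller than one cell")
  radii <- seq(r_min, r_max, by = cs)
  if (is.null(restore_value)) {
    restore_value <- min(resistance$values, na.rm = TRUE)
  }
  nr <- nrow(resistance$values); nc <- ncol(resistance$values)
  is_map <- matrix(NA_real_, nr, nc)
  rad_map <- matrix(NA_real_, nr, nc)
  imp <- numeric(length(corridors))
  for (k in seq_along(corridors)) {
    r <- corridors[[k]]
    ma <- patch_mask(sources[[r$pair[1]]])
    mb <- patch_mask(sources[[r$pair[2]]])
    src <- !is.na(ma$values) & ma$values > 0
    tgt <- !is.na(mb$values) & mb$values > 0
    centers <- which(r$swath_mask$values > 0 & !src & !tgt)
    if (stride > 1) centers <- centers[seq(1, length(centers), by = stride)]
    if (length(centers) == 0) { imp[k] <- 0; next }
    out <- cpp_barrier_scan(resistance$values, src, tgt, cs,
                            centers, radii, restore_value, r$lcp_cost)
    better <- is.na(is_map[centers]) | out$is > is_map[centers]
    is_map[centers[better]] <- out$is[better]
    rad_map[centers[better]] <- out$radius[better]
    imp[k] <- mean(out$is)
  }
  cls <- quantile_class_vector(imp)
  for (k in seq_along(corridors)) {
    corridors[[k]]$improvement <- imp[k]
    corridors[[k]]$improvement_level <- level_label(cls[k])
  }
  picked <- nms_top(is_map, top_n, suppression_radius_m / cs)
  rows <- (picked - 1) %% nr + 1; cols <- (picked - 1) %/% nr + 1
  xy <- rowcol_to_xy(resistance, rows, cols)
  barriers <- data.frame(row = rows, col = cols, x = xy[, 1], y = xy[, 2],
                         radius = rad_map[picked], is = is_map[picked],
                         rank = seq_along(picked))
  list(barriers = barriers, is = grid_like(resistance, is_map),
       corridors = corridors)
}

#' Composite corridor priority
#'
#' Cross-tabulates the improvement level (connectivity-enhancement potential)
#' and the priority level (conservation value) of every corridor into labels
#' like "V&V"; the "V&V" corridors are the priority corridors.
#'
#' @param corridors list of `corridor_record` with both levels filled in.
#' @return character vector of labels, one per corridor.
#' @export
composite_priority <- function(corridors) {
  vapply(corridors, function(r) {
    if (is.na(r$improvement_level) || is.na(r$priority_level)) {
      stop("composite_priority: corridor levels not yet computed")
    }
    paste0(r$improvement_level, "&", r$priority_level)
  }, character(1))
}
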