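# shared helpers: tiny grids and independent oracles

rg <- function(m, cell_size = 100) {
  m <- as.matrix(m)
  raster_grid(m, cell_size = cell_size, origin = c(0, nrow(m) * cell_size))
}

mask_at <- function(nr, nc, cells, cell_size = 100) {
  m <- matrix(0, nr, nc)
  m[cells] <- 1
  rg(m, cell_size)
}

xy_path_to_rowcol <- function(coords, g) {
  cbind(row = round((g$origin[2] - coords[, 2]) / g$cell_size + 0.5),
        col = round((coords[, 1] - g$origin[1]) / g$cell_size + 0.5))
}

has_pair <- function(corridors, p) {
  any(vapply(corridors, function(r) all(r$pair == p), logical(1)))
}

# independent raster-graph builder (double loop, no package internals):
# returns data.frame(from, to, weight) using the mean-resistance edge cost
oracle_edge_list <- function(res, cell_size) {
  nr <- nrow(res); nc <- ncol(res)
  id <- function(i, j) (j - 1) * nr + i
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(res[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(res[ii, jj])) next
      if (id(ii, jj) < id(i, j)) next   # undirected, once
      step <- if (di != 0 && dj != 0) sqrt(2) else 1
      out[[length(out) + 1]] <- c(id(i, j), id(ii, jj),
                                  0.5 * (res[i, j] + res[ii, jj]) * cell_size * step)
    }
  }
  el <- do.call(rbind, out)
  data.frame(from = el[, 1], to = el[, 2], weight = el[, 3])
}

# igraph Dijkstra oracle for multi-source cost-weighted distance
oracle_cwd <- function(res, src_cells, cell_size) {
  el <- oracle_edge_list(res, cell_size)
  n <- length(res)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(el$from), to = as.character(el$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  d <- igraph::distances(g, v = as.character(src_cells), weights = el$weight)
  out <- apply(d, 2, min)
  out <- out[as.character(seq_len(n))]
  matrix(ifelse(is.infinite(out), NA_real_, out), nrow(res), ncol(res))
}

# exhaustive simple-path enumeration (DFS) for tiny grids: minimum path cost
oracle_enumerate_lcp <- function(res, from, to, cell_size) {
  el <- oracle_edge_list(res, cell_size)
  n <- length(res)
  adj <- vector("list", n)
  for (k in seq_len(nrow(el))) {
    a <- el$from[k]; b <- el$to[k]; w <- el$weight[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- Inf
  visited <- logical(n)
  dfs <- function(u, cost) {
    if (cost >= best) return()
    if (u == to) { best <<- cost; return() }
    visited[u] <<- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (k in seq_len(nrow(nb))) {
        v <- nb[k, 1]
        if (!visited[v]) dfs(v, cost + nb[k, 2])
      }
    }
    visited[u] <<- FALSE
  }
  dfs(from, 0)
  best
}

# dense-matrix circuit oracle on a raster: effective resistance between two
# single-cell terminals, conductance = 1 / (mean resistance x step)
oracle_effective_resistance <- function(res, a_cell, b_cell) {
  el <- oracle_edge_list(res, cell_size = 1)
  n <- length(res)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(el))) {
    i <- el$from[k]; j <- el$to[k]; g <- 1 / el$weight[k]
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
  }
  keep <- setdiff(which(diag(L) > 0), b_cell)
  rhs <- numeric(length(keep))
  rhs[match(a_cell, keep)] <- 1
  v <- solve(L[keep, keep], rhs)
  v[match(a_cell, keep)]
}
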