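#' Threat specification for the habitat-quality model
#'
#' A threat is a raster of source intensities in \[0, 1\] together with a
#' weight, a maximum effective distance and a decay kind. Threat weights are
#' renormalized to sum to 1 before use, so degradation is a weighted average
#' of threat levels.
#'
#' @param id short threat name.
#' @param weight relative weight in \[0, 1\].
#' @param d_max maximum effective distance in m (> 0).
#' @param decay "linear" or "exponential".
#' @param source raster_grid of source intensity in \[0, 1\] (typically a
#'   0/1 mask).
#' @return list of class `threat_spec`.
#' @export
threat_spec <- function(id, weight, d_max, decay = c("linear", "exponential"),
                        source) {
  decay <- match.arg(decay)
  if (d_max <= 0) stop("threat_spec: d_max must be > 0")
  stopifnot(weight >= 0, weight <= 1, is_raster_grid(source))
  structure(list(id = id, weight = weight, d_max = d_max, decay = decay,
                 source = source), class = "threat_spec")
}

#' Distance-decayed threat impact
#'
#' Linear decay: `max(0, 1 - d/d_max)`. Exponential decay:
#' `exp(-(2.99/d_max) * d)`, which falls to ~0.05 at the maximum effective
#' distance. Both decays are hard-cut to 0 beyond `d_max`.
#'
#' @param d distance(s) in m, >= 0.
#' @param spec a `threat_spec` (its source raster is not used here).
#' @return impact value(s) in \[0, 1\].
#' @export
threat_impact <- function(d, spec) {
  if (spec$d_max <= 0) stop("threat_impact: d_max must be > 0")
  stopifnot(all(d >= 0, na.rm = TRUE))
  i <- if (spec$decay == "linear") {
    pmax(0, 1 - d / spec$d_max)
  } else {
    exp(-(2.99 / spec$d_max) * d)
  }
  i[d > spec$d_max] <- 0
  i
}

#' Habitat parameters
#'
#' @param suitability named numeric in \[0, 1\]: habitat suitability per LULC
#'   code (names are codes).
#' @param sensitivity numeric matrix in \[0, 1\]: rows = LULC codes (rownames),
#'   columns = threat ids (colnames).
#' @param k half-saturation constant (> 0): the degradation level at which
#'   quality falls to half the suitability.
#' @param z exponent of the half-saturation function.
#' @return list of class `habitat_params`.
#' @export
habitat_params <- function(suitability, sensitivity, k = 0.5, z = 2.5) {
  if (k <= 0) stop("habitat_params: k must be > 0")
  stopifnot(z > 0, all(suitability >= 0 & suitability <= 1),
            all(sensitivity >= 0 & sensitivity <= 1))
  structure(list(suitability = suitability, sensitivity = sensitivity,
                 k = k, z = z), class = "habitat_params")
}

#' Habitat degradation from distance-decayed threats
#'
#' Computes the total threat level per cell as the normalized-weight sum over
#' threats of (impact of the nearest source cell) x (sensitivity of the
#' cell's LULC class to that threat), with the policy-accessibility factor
#' fixed at 1. With weights normalized to 1 the result is a weighted average
#' of threat levels, bounded by \[0, 1\].
#'
#' `method = "sum"` instead accumulates the impact over *all* source cells of
#' each threat (clipped to 1 per threat); this is an O(cells x sources)
#' computation intended for small rasters.
#'
#' @param lulc categorical raster_grid of LULC codes.
#' @param threats list of `threat_spec`.
#' @param params `habitat_params`; every (code, threat id) pair present in
#'   the data must have a sensitivity entry.
#' @param method "nearest" (default) or "sum".
#' @return raster_grid of degradation D in \[0, 1\].
#' @export
degradation <- function(lulc, threats, params, method = c("nearest", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "habitat_params"), length(threats) >= 1)
  for (th in threats) stopifnot_congruent(lulc, th$source)
  codes <- sort(unique(as.vector(lulc$values[!is.na(lulc$values)])))
  wsum <- sum(vapply(threats, `[[`, numeric(1), "weight"))
  if (wsum <= 0) stop("degradation: threat weights sum to 0")
  D <- matrix(0, nrow(lulc$values), ncol(lulc$values))
  for (th in threats) {
    s_col <- as.character(th$id)
    if (!s_col %in% colnames(params$sensitivity)) {
      stop(sprintf("degradation: no sensitivity column for threat '%s'", th$id))
    }
    missing_codes <- setdiff(as.character(codes), rownames(params$sensitivity))
    if (length(missing_codes) > 0) {
      stop(sprintf("degradation: no sensitivity row for LULC code(s) %s (threat '%s')",
                   paste(missing_codes, collapse = ", "), th$id))
    }
    src <- th$source$values
    has_src <- any(!is.na(src) & src > 0)
    if (method == "nearest") {
      imp <- if (has_src) {
        dmask <- grid_like(th$source, (src > 0) * 1)
        d <- euclidean_distance(dmask)
        iv <- threat_impact(as.vector(d$values), th)
        # nearest-source intensity: with 0/1 masks this is 1; for graded
        # sources scale by the maximum source intensity
        iv * max(src, na.rm = TRUE)
      } else {
        rep(0, length(src))
      }
    } else {
      imp <- rep(0, length(src))
      if (has_src) {
        cc <- cell_centers(lulc)
        idx <- which(!is.na(src) & src > 0)
        for (y in idx) {
          d <- sqrt((cc$x - cc$x[y])^2 + (cc$y - cc$y[y])^2)
          imp <- imp + src[y] * threat_impact(as.vector(d), th)
        }
        imp <- pmin(imp, 1)
      }
    }
    code_chr <- as.character(lulc$values)
    code_chr[is.na(code_chr)] <- rownames(params$sensitivity)[1]
    S <- params$sensitivity[code_chr, s_col]
    D <- D + (th$weight / wsum) * matrix(imp * S, nrow(D), ncol(D))
  }
  D[is.na(lulc$values)] <- NA_real_
  grid_like(lulc, D)
}

#' Habitat quality from degradation
#'
#' `Q = H_j * (1 - D^z / (D^z + k^z))`: quality equals the LULC suitability
#' at zero degradation and falls to half of it at `D = k`.
#'
#' @param D raster_grid of degradation.
#' @param lulc categorical raster_grid of LULC codes.
#' @param params `habitat_params`.
#' @return raster_grid of habitat quality in \[0, 1\].
#' @export
habitat_quality <- function(D, lulc, params) {
  stopifnot(inherits(params, "habitat_params"))
  if (params$k <= 0) stop("habitat_quality: k must be > 0")
  stopifnot_congruent(D, lulc)
  H <- unname(params$suitability[as.character(lulc$values)])
  H[is.na(lulc$values)] <- NA_real_
  dz <- D$values^params$z
  Q <- matrix(H, nrow(D$values), ncol(D$values)) *
    (1 - dz / (dz + params$k^params$z))
  Q[is.na(D$values) | is.na(lulc$values)] <- NA_real_
  grid_like(D, Q)
}

#' Annual water yield
#'
#' Water balance per pixel: `Y = (1 - AET/P) * P = P - AET` in mm/yr. Cells
#' with zero precipitation yield zero.
#'
#' @param precipitation raster_grid, mm/yr (>= 0).
#' @param aet raster_grid of actual annual evapotranspiration, mm/yr (>= 0).
#' @return raster_grid of water yield Y in mm/yr.
#' @export
water_yield <- function(precipitation, aet) {
  stopifnot_congruent(precipitation, aet)
  P <- precipitation$values; A <- aet$values
  if (any(P < 0, na.rm = TRUE) || any(A < 0, na.rm = TRUE)) {
    stop("water_yield: negative precipitation or AET")
  }
  Y <- P - A
  Y[P == 0] <- 0
  grid_like(precipitation, Y)
}

#' Carbon storage from per-class pools
#'
#' Per-cell lookup of total carbon density, the sum of the four pools
#' (aboveground, belowground, soil, dead organic matter), in t/ha.
#'
#' @param lulc categorical raster_grid of LULC codes.
#' @param pools data.frame with columns code, c_above, c_below, c_soil,
#'   c_dead (all >= 0, t/ha).
#' @return raster_grid of carbon density in t/ha.
#' @export
carbon_storage <- function(lulc, pools) {
  stopifnot(all(c("code", "c_above", "c_below", "c_soil", "c_dead") %in%
                  names(pools)))
  if (any(pools[, c("c_above", "c_below", "c_soil", "c_dead")] < 0)) {
    stop("carbon_storage: carbon pools must be >= 0")
  }
  total <- pools$c_above + pools$c_below + pools$c_soil + pools$c_dead
  codes <- as.vector(lulc$values)
  miss <- setdiff(unique(codes[!is.na(codes)]), pools$code)
  if (length(miss) > 0) {
    stop(sprintf("carbon_storage: LULC code(s) %s absent from the pool table",
                 paste(miss, collapse = ", ")))
  }
  C <- total[match(codes, pools$code)]
  grid_like(lulc, matrix(C, nrow(lulc$values), ncol(lulc$values)))
}

#' Integrated ecosystem services
#'
#' Equal-weight mean of the three min-max-normalized service layers (habitat
#' quality, water yield, carbon storage).
#'
#' @param Q,Y,C congruent raster_grids.
#' @return raster_grid in \[0, 1\].
#' @export
integrated_services <- function(Q, Y, C) {
  stopifnot_congruent(Q, Y, C)
  n <- lapply(list(Q, Y, C), minmax_normalize)
  grid_like(Q, (n[[1]]$values + n[[2]]$values + n[[3]]$values) / 3)
}

#' Default threat table and habitat parameters
#'
#' Desk-scale defaults for the synthetic landscapes: built-up classes,
#' cropland and the two road classes act as threats; suitability follows the
#' legend; sensitivities are highest for forest and water classes. All are
#' plain tables the caller can edit (also shipped as CSVs under
#' `inst/extdata`).
#'
#' @param legend LULC legend data.frame.
#' @return `default_threat_table()`: data.frame (id, weight, d_max_m, decay);
#'   `default_habitat_params()`: a `habitat_params`;
#'   `default_carbon_pools()`: data.frame of carbon pools.
#' @export
default_threat_table <- function() {
  data.frame(
    id = c("urban", "rural", "cropland", "road1", "road2"),
    weight = c(1.0, 0.7, 0.5, 0.9, 0.6),
    d_max_m = c(8000, 5000, 2000, 3000, 2000),
    decay = c("exponential", "exponential", "linear", "linear", "linear"),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_threat_table
#' @export
default_habitat_params <- function(legend = default_lulc_legend()) {
  codes <- as.character(legend$code)
  suit <- stats::setNames(legend$habitat_suitability, codes)
  threats <- default_threat_table()$id
  S <- matrix(0, nrow = length(codes), ncol = length(threats),
              dimnames = list(codes, threats))
  base <- stats::setNames(
    c(0.55, 0.5, 0.9, 0.7, 0.85, 0.85, 0, 0.1, 0, 0.3), codes)
  mult <- stats::setNames(c(1, 0.9, 0.6, 0.95, 0.75), threats)
  for (th in threats) S[, th] <- pmin(base * mult[th], 1)
  habitat_params(suitability = suit, sensitivity = S, k = 0.5, z = 2.5)
}

#' @rdname default_threat_table
#' @export
default_carbon_pools <- function(legend = default_lulc_legend()) {
  data.frame(
    code = legend$code,
    name = legend$name,
    c_above = c(8, 7, 60, 10, 0, 0, 2, 3, 0, 1),
    c_below = c(2, 2, 15, 4, 0, 0, 1, 1, 0, 0),
    c_soil = c(65, 60, 90, 70, 0, 0, 20, 25, 5, 10),
    c_dead = c(1, 1, 5, 1, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Build threat specs from a landscape bundle
#'
#' Derives the default threat source rasters from a synthetic bundle: urban,
#' rural and cropland masks from the LULC map and the two rasterized road
#' classes.
#'
#' @param bundle a `landscape_bundle`.
#' @param table threat table (see [default_threat_table()]).
#' @return list of `threat_spec`.
#' @export
bundle_threats <- function(bundle, table = default_threat_table()) {
  leg <- bundle$legend
  lu <- bundle$lulc
  mask_of <- function(classes) {
    m <- lu$values
    m[] <- as.numeric(lu$values %in% leg$code[leg$name %in% classes])
    grid_like(lu, m)
  }
  sources <- list(
    urban = mask_of("urban"),
    rural = mask_of("rural"),
    cropland = mask_of(c("paddy_field", "irrigated_land")),
    road1 = rasterize_features(bundle$roads_1, lu, type = "lines"),
    road2 = rasterize_features(bundle$roads_2, lu, type = "lines")
  )
  specs <- list()
  for (k in seq_len(nrow(table))) {
    id <- table$id[k]
    if (!id %in% names(sources)) next
    specs[[id]] <- threat_spec(id, table$weight[k], table$d_max_m[k],
                               table$decay[k], sources[[id]])
  }
  specs
}
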