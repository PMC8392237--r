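#' Pipeline configuration
#'
#' One object drives the whole ecological-security-pattern run: the landscape
#' (a `landscape_config`, a ready `landscape_bundle`, or a fixture name), the
#' parameter tables, and the thresholds. All tables default to the package's
#' built-in values and can be replaced wholesale.
#'
#' @param landscape `landscape_config`, `landscape_bundle`, or fixture name
#'   ("uniform"/"two_patch").
#' @param threat_table data.frame (id, weight, d_max_m, decay).
#' @param habitat `habitat_params`.
#' @param carbon_pools carbon pool data.frame.
#' @param habitat_breaks,water_breaks sensitivity score break lists.
#' @param resistance_table a `resistance_table`.
#' @param min_area_km2 minimum source-patch area (default 10).
#' @param top_classes importance classes forming source candidates.
#' @param corridor_width_m corridor width (default 1000 m).
#' @param swath_threshold corridor swath threshold (NULL = auto).
#' @param barrier_r_min,barrier_r_max barrier search radii in m.
#' @param barrier_stride evaluate every stride-th swath cell in the barrier
#'   scan.
#' @param top_n number of barriers and pinch points reported.
#' @param pairing corridor pairing rule ("adjacent" or "all").
#' @param relief_window relief focal window in cells.
#' @param seed integer seed recorded in outputs (the landscape generator uses
#'   its own config seed; if `landscape` is a `landscape_config` with a
#'   different seed, this seed overrides it).
#' @return list of class `esp_config`.
#' @export
esp_config <- function(landscape = landscape_config(),
                       threat_table = default_threat_table(),
                       habitat = default_habitat_params(),
                       carbon_pools = default_carbon_pools(),
                       habitat_breaks = default_habitat_breaks(),
                       water_breaks = default_water_breaks(),
                       resistance_table = default_resistance_table(),
                       min_area_km2 = 10, top_classes = 1,
                       corridor_width_m = 1000, swath_threshold = NULL,
                       barrier_r_min = 200, barrier_r_max = 1000,
                       barrier_stride = 1,
                       top_n = 40, pairing = "adjacent",
                       relief_window = 3, seed = 1) {
  stopifnot(min_area_km2 > 0, top_n >= 1)
  w <- vapply(resistance_table, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("esp_config: resistance factor weights must sum to 1")
  }
  cfg <- list(landscape = landscape, threat_table = threat_table,
              habitat = habitat, carbon_pools = carbon_pools,
              habitat_breaks = habitat_breaks, water_breaks = water_breaks,
              resistance_table = resistance_table,
              min_area_km2 = min_area_km2, top_classes = top_classes,
              corridor_width_m = corridor_width_m,
              swath_threshold = swath_threshold,
              barrier_r_min = barrier_r_min, barrier_r_max = barrier_r_max,
              barrier_stride = barrier_stride,
              top_n = top_n, pairing = pairing,
              relief_window = relief_window, seed = seed)
  class(cfg) <- "esp_config"
  cfg
}

#' Demo configuration
#'
#' A 120 x 120-cell (12 x 12 km at 100 m) synthetic landscape with three
#' reserves, scaled thresholds (2 km2 minimum source area) and a thinned
#' barrier scan, sized so the full pipeline completes in well under a minute.
#'
#' @param seed integer seed.
#' @return an `esp_config`.
#' @export
demo_config <- function(seed = 1) {
  esp_config(
    landscape = landscape_config(shape = c(120, 120), cell_size = 100,
                                 seed = seed),
    min_area_km2 = 2,
    barrier_stride = 4,
    top_n = 40,
    seed = seed
  )
}

raster_summary <- function(g) {
  v <- g$values[!is.na(g$values)]
  list(min = min(v), mean = mean(v), max = max(v), nodata = sum(is.na(g$values)))
}

#' Run the full ecological-security-pattern pipeline
#'
#' Executes all stages in order: landscape -> ecosystem services ->
#' ecological sensitivity -> ecological importance and source selection ->
#' resistance surface -> least-cost corridors -> circuit analysis (pinch
#' points, priority) -> barrier scan -> centrality -> composite priority ->
#' report. When `outdir` is given, rasters (Esri ASCII), vector layers
#' (GeoJSON), tables (CSV) and a JSON run manifest (config hash, seed,
#' per-stage summaries) are written there.
#'
#' @param config an `esp_config`.
#' @param outdir output directory (NULL = no files written).
#' @param quiet suppress progress messages.
#' @return list of class `esp_run` with all intermediate and final artifacts.
#' @export
run_esp <- function(config = demo_config(), outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "esp_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  # --- landscape ---
  lands <- config$landscape
  if (inherits(lands, "landscape_config")) {
    lands$seed <- config$seed
    bundle <- generate_landscape(lands)
  } else if (inherits(lands, "landscape_bundle")) {
    bundle <- lands
  } else if (is.character(lands)) {
    bundle <- landscape_fixture(lands)
  } else {
    stop("run_esp: unrecognized landscape specification")
  }
  say("stage landscape: %d x %d cells", nrow(bundle$lulc$values),
      ncol(bundle$lulc$values))
  lu <- bundle$lulc

  # --- ecosystem services ---
  threats <- bundle_threats(bundle, config$threat_table)
  D <- degradation(lu, threats, config$habitat)
  Q <- habitat_quality(D, lu, config$habitat)
  Y <- water_yield(bundle$precipitation, bundle$aet)
  C <- carbon_storage(lu, config$carbon_pools)
  services <- integrated_services(Q, Y, C)
  say("stage services: Q mean %.3f, Y mean %.0f mm, C mean %.0f t/ha",
      mean(Q$values, na.rm = TRUE), mean(Y$values, na.rm = TRUE),
      mean(C$values, na.rm = TRUE))

  # --- ecological sensitivity ---
  leg <- bundle$legend
  water_mask <- lu$values
  water_mask[] <- as.numeric(lu$values %in% leg$code[leg$is_water])
  water_mask <- grid_like(lu, water_mask)
  road1_dist <- distance_or_inf(bundle$roads_1, lu, type = "lines")
  reserve_dist <- distance_or_inf(bundle$reserves, lu, type = "polygons")
  water_dist <- if (any(water_mask$values > 0, na.rm = TRUE)) {
    euclidean_distance(water_mask)
  } else {
    distance_or_inf(list(), lu)
  }
  pp <- bundle$pollution_points
  ww_dist <- distance_or_inf(pp[pp$type == "wastewater", c("x", "y"), drop = FALSE], lu)
  air_dist <- distance_or_inf(pp[pp$type == "air", c("x", "y"), drop = FALSE], lu)
  hab_s <- habitat_sensitivity(road1_dist, reserve_dist, lu, bundle$ndvi,
                               config$habitat_breaks, legend = leg)
  wat_s <- water_sensitivity(water_dist, ww_dist, air_dist, config$water_breaks)
  soil_a <- csle(bundle$csle)
  sens <- integrated_sensitivity(hab_s, wat_s, soil_a)
  say("stage sensitivity: habitat %.2f, water %.2f, soil loss mean %.1f t/ha",
      mean(hab_s$values, na.rm = TRUE), mean(wat_s$values, na.rm = TRUE),
      mean(soil_a$values, na.rm = TRUE))

  # --- importance and sources ---
  importance <- ecological_importance(services, sens$index)
  sources <- select_sources(importance$classes, bundle$reserves,
                            min_area_km2 = config$min_area_km2,
                            top_classes = config$top_classes)
  say("stage sources: %d patches, %.2f km2 total", length(sources),
      sum(vapply(sources, `[[`, numeric(1), "area_km2")))

  # --- resistance ---
  factors <- bundle_resistance_factors(bundle, config$relief_window)
  resistance <- integrated_resistance(factors, config$resistance_table)
  say("stage resistance: min %.2f, mean %.2f, max %.2f",
      min(resistance$values, na.rm = TRUE),
      mean(resistance$values, na.rm = TRUE),
      max(resistance$values, na.rm = TRUE))

  # --- corridors ---
  corridors <- least_cost_corridors(resistance, sources,
                                    pairing = config$pairing,
                                    swath_threshold = config$swath_threshold,
                                    corridor_width_m = config$corridor_width_m)
  say("stage corridors: %d corridors, total length %.2f km",
      length(corridors),
      sum(vapply(corridors, `[[`, numeric(1), "length_km")))

  # --- circuit: pinch points and corridor priority ---
  pinch <- pinch_points(resistance, corridors, sources, top_n = config$top_n)
  corridors <- pinch$corridors
  say("stage pinchpoints: %d points, worst KCL residual %.2e",
      nrow(pinch$points), pinch$kcl_residual)

  # --- barriers ---
  barriers <- barrier_scan(resistance, corridors, sources,
                           r_min = config$barrier_r_min,
                           r_max = config$barrier_r_max,
                           top_n = config$top_n,
                           stride = config$barrier_stride)
  corridors <- barriers$corridors
  say("stage barriers: %d barriers, best IS %.3f", nrow(barriers$barriers),
      if (nrow(barriers$barriers) > 0) max(barriers$barriers$is) else 0)

  # --- centrality and composite priority ---
  cent <- current_centrality(corridors, length(sources))
  corridors <- cent$corridors
  composite <- composite_priority(corridors)
  say("stage centrality: top node centrality %.3f", max(cent$node_centrality))

  run <- structure(list(
    config = config, bundle = bundle,
    degradation = D, habitat_quality = Q, water_yield = Y, carbon = C,
    services = services,
    habitat_sensitivity = hab_s, water_sensitivity = wat_s, soil_loss = soil_a,
    sensitivity = sens,
    importance = importance, sources = sources,
    resistance = resistance,
    corridors = corridors, pinch = pinch, barriers = barriers,
    node_centrality = cent$node_centrality,
    composite = composite,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "esp_run")

  if (!is.null(outdir)) write_esp_outputs(run, outdir)
  run
}

#' @export
print.esp_run <- function(x, ...) {
  cat(sprintf("<esp_run> %d sources, %d corridors, %d pinch points, %d barriers (%.1f s)\n",
              length(x$sources), length(x$corridors), nrow(x$pinch$points),
              nrow(x$barriers$barriers), x$elapsed_s))
  invisible(x)
}

# write all pipeline artifacts plus a reproducibility manifest
write_esp_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  rasters <- list(
    lulc = run$bundle$lulc, dem = run$bundle$dem,
    habitat_quality = run$habitat_quality, water_yield = run$water_yield,
    carbon = run$carbon, services = run$services,
    habitat_sensitivity = run$habitat_sensitivity,
    water_sensitivity = run$water_sensitivity, soil_loss = run$soil_loss,
    sensitivity_index = run$sensitivity$index,
    importance_index = run$importance$index,
    importance_classes = run$importance$classes,
    resistance = run$resistance,
    current_max = run$pinch$score, barrier_is = run$barriers$is
  )
  for (nm in names(rasters)) write_ascii_grid(rasters[[nm]], p(paste0(nm, ".asc")))

  utils::write.csv(sources_table(run$sources), p("sources.csv"), row.names = FALSE)
  ct <- corridors_table(run$corridors)
  ct$composite <- run$composite
  utils::write.csv(ct, p("corridors.csv"), row.names = FALSE)
  utils::write.csv(run$pinch$points, p("pinch_points.csv"), row.names = FALSE)
  utils::write.csv(run$barriers$barriers, p("barriers.csv"), row.names = FALSE)

  write_geojson(lapply(run$corridors, function(r)
    list(geometry = r$lcp,
         properties = list(from = r$pair[1], to = r$pair[2],
                           cost = r$lcp_cost, length_km = r$length_km,
                           centrality = r$centrality,
                           improvement_level = r$improvement_level,
                           priority_level = r$priority_level))),
    type = "LineString", path = p("corridors.geojson"))
  if (nrow(run$pinch$points) > 0) {
    write_geojson(lapply(seq_len(nrow(run$pinch$points)), function(i)
      list(geometry = c(run$pinch$points$x[i], run$pinch$points$y[i]),
           properties = list(rank = i, score = run$pinch$points$score[i]))),
      type = "Point", path = p("pinch_points.geojson"))
  }

  report <- report_esp(run)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(report$corridor_land_composition,
                   p("corridor_land_composition.csv"), row.names = FALSE)

  cfg <- run$config
  manifest <- list(
    package = "ecoscape",
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    r_version = as.character(getRversion()),
    stages = list(
      sources = list(n = length(run$sources),
                     area_km2 = sum(sources_table(run$sources)$area_km2)),
      corridors = list(n = length(run$corridors),
                       total_length_km = sum(ct$length_km)),
      pinch_points = list(n = nrow(run$pinch$points)),
      barriers = list(n = nrow(run$barriers$barriers)),
      priority_corridors = list(n = sum(run$composite == "V&V"))
    ),
    rasters = lapply(rasters, raster_summary)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Summary report of an ESP run
#'
#' Source count and area, corridor count and total length, the land-cover
#' composition of the 1-km corridor buffers (percent per class, summing to
#' 100), the top-n barrier and pinch-point tables, and the composite
#' improvement x priority cross-tabulation.
#'
#' @param run an `esp_run`.
#' @return list of report tables.
#' @export
report_esp <- function(run) {
  st <- sources_table(run$sources)
  ct <- corridors_table(run$corridors)
  buf <- Reduce(`|`, lapply(run$corridors, function(r) r$buffer_mask$values > 0))
  lu <- run$bundle$lulc$values
  leg <- run$bundle$legend
  codes <- lu[buf & !is.na(lu)]
  comp <- if (length(codes) > 0) {
    tab <- table(factor(codes, levels = leg$code))
    data.frame(code = leg$code, name = leg$name,
               percent = as.numeric(tab) / length(codes) * 100)
  } else {
    data.frame(code = leg$code, name = leg$name, percent = 0)
  }
  cross <- table(factor(vapply(run$corridors, `[[`, character(1), "improvement_level"),
                        levels = c("L", "M", "H", "V")),
                 factor(vapply(run$corridors, `[[`, character(1), "priority_level"),
                        levels = c("L", "M", "H", "V")))
  list(
    sources = list(n = nrow(st), total_area_km2 = sum(st$area_km2),
                   redline_share = if (sum(st$area_km2) > 0)
                     sum(st$area_km2[st$from_redline]) / sum(st$area_km2) else NA),
    corridors = list(n = nrow(ct), total_length_km = sum(ct$length_km)),
    corridor_land_composition = comp,
    composite_crosstab = as.data.frame.matrix(cross),
    priority_corridors = which(run$composite == "V&V"),
    barriers = run$barriers$barriers,
    pinch_points = run$pinch$points
  )
}
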