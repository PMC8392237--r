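# Stage 1 — synthesize the study landscape.
# A seeded synthetic plain stands in for real GIS inputs: clustered LULC,
# a smooth DEM, precipitation/AET/NDVI fields, two road classes, pollution
# point sources and reserve polygons.

source("analysis/00_common.R")

bundle <- demo_landscape()
print(bundle)

share <- sort(table(bundle$lulc$values), decreasing = TRUE)
leg <- bundle$legend
cat("\nRealized land-cover shares:\n")
for (code in names(share)) {
  cat(sprintf("  %-15s %5.1f%%\n", leg$name[leg$code == as.integer(code)],
              100 * share[[code]] / length(bundle$lulc$values)))
}

for (nm in c("lulc", "dem", "precipitation", "aet", "ndvi")) {
  save_grid(bundle[[nm]], nm)
}
write_geojson(lapply(bundle$roads_1, function(r) list(geometry = r)),
              "LineString", file.path(results_dir, "roads_1.geojson"))
write_geojson(lapply(bundle$roads_2, function(r) list(geometry = r)),
              "LineString", file.path(results_dir, "roads_2.geojson"))
write_geojson(lapply(seq_len(nrow(bundle$pollution_points)), function(i)
  list(geometry = c(bundle$pollution_points$x[i], bundle$pollution_points$y[i]),
       properties = list(type = bundle$pollution_points$type[i]))),
  "Point", file.path(results_dir, "pollution_points.geojson"))
write_geojson(lapply(bundle$reserves, function(p) list(geometry = p)),
              "Polygon", file.path(results_dir, "reserves.geojson"))

cat(sprintf("\nWrote landscape rasters and vector layers under %s/\n", results_dir))
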