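# Stage 4 — ecological importance and source selection.
# Equal-weight overlay of integrated services and sensitivity, quantile
# classification, union with the reserve ("red line") polygons, and the
# minimum-area filter with the red-line exemption.

source("analysis/00_common.R")

cfg <- demo_pipeline_config()
run <- run_esp(cfg, quiet = TRUE)   # reuse the pipeline up to this stage

st <- sources_table(run$sources)
cat(sprintf("Selected %d ecological sources totalling %.2f km2\n",
            nrow(st), sum(st$area_km2)))
cat(sprintf("Red-line share of source area: %.1f%%\n",
            100 * sum(st$area_km2[st$from_redline]) / sum(st$area_km2)))
print(st)

save_grid(run$importance$index, "importance_index")
save_grid(run$importance$classes, "importance_classes")
write.csv(st, file.path(results_dir, "sources.csv"), row.names = FALSE)
cat(sprintf("Wrote importance rasters and sources.csv under %s/\n", results_dir))
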