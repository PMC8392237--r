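# Stage 6 — corridors, circuit analysis, barriers, centrality.
# Least-cost corridors between source pairs, pairwise current maps for pinch
# points and corridor priority, the moving-window barrier scan, and
# current-flow centrality on the coarse source network.

source("analysis/00_common.R")

run <- run_esp(demo_pipeline_config(), quiet = TRUE)

ct <- corridors_table(run$corridors)
ct$composite <- run$composite
cat(sprintf("%d corridors, total length %.2f km\n", nrow(ct), sum(ct$length_km)))
print(ct)

cat(sprintf("\nTop pinch points (of %d):\n", nrow(run$pinch$points)))
print(utils::head(run$pinch$points, 5))
cat(sprintf("\nTop barriers (of %d):\n", nrow(run$barriers$barriers)))
print(utils::head(run$barriers$barriers, 5))
cat("\nSource current-flow centrality:\n")
print(round(run$node_centrality, 3))
cat(sprintf("\nPriority (V&V) corridors: %s\n",
            if (any(run$composite == "V&V")) paste(which(run$composite == "V&V"), collapse = ", ")
            else "none at this scale"))

write.csv(ct, file.path(results_dir, "corridors.csv"), row.names = FALSE)
write.csv(run$pinch$points, file.path(results_dir, "pinch_points.csv"), row.names = FALSE)
write.csv(run$barriers$barriers, file.path(results_dir, "barriers.csv"), row.names = FALSE)
save_grid(run$pinch$score, "current_max")
save_grid(run$barriers$is, "barrier_is")
cat(sprintf("Wrote connectivity tables and rasters under %s/\n", results_dir))
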