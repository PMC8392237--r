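# Stage 2 — ecosystem services.
# Habitat quality (distance-decayed threats + half-saturation), annual water
# yield (P - AET) and carbon storage (four pools per land class), then the
# equal-weight normalized integration.

source("analysis/00_common.R")

bundle <- demo_landscape()
threats <- bundle_threats(bundle)
params <- default_habitat_params()

D <- degradation(bundle$lulc, threats, params)
Q <- habitat_quality(D, bundle$lulc, params)
Y <- water_yield(bundle$precipitation, bundle$aet)
C <- carbon_storage(bundle$lulc, default_carbon_pools())
S <- integrated_services(Q, Y, C)

cat(sprintf("Habitat degradation: mean %.3f (max %.3f)\n",
            mean(D$values), max(D$values)))
cat(sprintf("Habitat quality:     mean %.3f\n", mean(Q$values)))
cat(sprintf("Water yield:         mean %.0f mm/yr\n", mean(Y$values)))
cat(sprintf("Carbon storage:      mean %.1f t/ha\n", mean(C$values)))
cat(sprintf("Integrated services: mean %.3f\n", mean(S$values)))

save_grid(D, "degradation"); save_grid(Q, "habitat_quality")
save_grid(Y, "water_yield"); save_grid(C, "carbon")
save_grid(S, "services")
cat(sprintf("Wrote service rasters under %s/\n", results_dir))
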