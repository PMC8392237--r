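# Stage 5 — integrated resistance surface.
# Weighted overlay of six classified factors: land class (0.30), relief and
# slope (0.15 each), distances to the two road classes (0.15 each) and
# distance to pollution sources (0.10).

source("analysis/00_common.R")

bundle <- demo_landscape()
factors <- bundle_resistance_factors(bundle)
resistance <- integrated_resistance(factors)

cat(sprintf("Integrated resistance: min %.2f, mean %.2f, max %.2f\n",
            min(resistance$values), mean(resistance$values),
            max(resistance$values)))
cat("The analytic range under the default table is [1, 370]; a surface\n")
cat("minimum above 1 simply means no pixel happens to sit in the most\n")
cat("permeable class of all six factors at once.\n")

for (nm in names(factors)) {
  cls <- classify_factor(factors[[nm]], default_resistance_table()[[nm]])
  save_grid(cls, paste0("resistance_", nm))
}
save_grid(resistance, "resistance")
cat(sprintf("Wrote factor and integrated resistance rasters under %s/\n",
            results_dir))
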