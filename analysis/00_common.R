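# Shared settings for the analysis scripts. Run every script from the
# repository root: Rscript analysis/01_landscape.R

library(ecoscape)

demo_seed <- 1
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

# the study landscape: a 120 x 120-cell (12 x 12 km at 100 m) synthetic
# cropland-dominated plain; all scripts regenerate it from this seed, so
# every stage sees bit-identical inputs
demo_landscape <- function() {
  generate_landscape(landscape_config(shape = c(120, 120), cell_size = 100,
                                      seed = demo_seed))
}

demo_pipeline_config <- function() demo_config(seed = demo_seed)

save_grid <- function(g, name) {
  write_ascii_grid(g, file.path(results_dir, paste0(name, ".asc")))
}
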