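# Stage 3 — ecological sensitivity.
# Habitat sensitivity (roads, reserves, land class, NDVI), water sensitivity
# (water bodies, wastewater and air-pollution sources) and soil loss by the
# multiplicative soil-loss equation, integrated into quantile levels.

source("analysis/00_common.R")

bundle <- demo_landscape()
lu <- bundle$lulc
leg <- bundle$legend

water_vals <- lu$values
water_vals[] <- as.numeric(lu$values %in% leg$code[leg$is_water])
water_mask <- raster_grid(water_vals, lu$cell_size, lu$origin)

road1_dist <- euclidean_distance(rasterize_features(bundle$roads_1, lu, "lines"))
reserve_dist <- euclidean_distance(rasterize_features(bundle$reserves, lu, "polygons"))
water_dist <- euclidean_distance(water_mask)
pp <- bundle$pollution_points
ww <- as.matrix(pp[pp$type == "wastewater", c("x", "y")])
air <- as.matrix(pp[pp$type == "air", c("x", "y")])
ww_dist <- euclidean_distance(ww, like = lu)
air_dist <- euclidean_distance(air, like = lu)

hab_s <- habitat_sensitivity(road1_dist, reserve_dist, lu, bundle$ndvi)
wat_s <- water_sensitivity(water_dist, ww_dist, air_dist)
soil_a <- csle(bundle$csle)
sens <- integrated_sensitivity(hab_s, wat_s, soil_a)

cat(sprintf("Habitat sensitivity: mean %.2f on the 1-7 scale\n", mean(hab_s$values)))
cat(sprintf("Water sensitivity:   mean %.2f\n", mean(wat_s$values)))
cat(sprintf("Soil loss:           mean %.2f t/ha/yr (max %.1f)\n",
            mean(soil_a$values), max(soil_a$values)))
lev <- table(sens$classes$values)
cat("Sensitivity levels (non / slight / moderate / extreme):",
    paste(lev, collapse = " / "), "cells\n")

save_grid(hab_s, "habitat_sensitivity"); save_grid(wat_s, "water_sensitivity")
save_grid(soil_a, "soil_loss"); save_grid(sens$index, "sensitivity_index")
save_grid(sens$classes, "sensitivity_classes")
cat(sprintf("Wrote sensitivity rasters under %s/\n", results_dir))
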