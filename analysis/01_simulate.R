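#!/usr/bin/env Rscript
# Build the synthetic study landscape and describe it: drivers, protected
# areas, the property mosaic by size class and Legal Reserve regime, and
# the four-period conversion history generated from the known model.

source("analysis/00_config.R")
cfg <- study_config()
out <- results_dir("landscape")

ds <- synth_dataset(cfg$synth)

message("Landscape: ", cfg$synth$grid_rows, " x ", cfg$synth$grid_cols,
        " cells of ", cfg$synth$cell_area, " ha (",
        cfg$synth$grid_rows * cfg$synth$grid_cols * cfg$synth$cell_area / 1e6,
        " Mha)")
message("Protected cells: ", sum(ds$properties$id == -1L), " (",
        round(100 * mean(ds$properties$id == -1L), 1), "% of the grid)")

tab <- ds$properties$table
message("Properties: ", nrow(tab))
print(table(class = tab$size_class))
print(stats::aggregate(area_ha ~ region + lr_fraction, tab, sum))

native <- vapply(c(list(ds$initial_state), ds$observed_states),
                 function(s) sum(s$native), integer(1))
history <- data.frame(
  year = seq(cfg$synth$start_year, by = 2L, length.out = length(native)),
  native_cells = native,
  native_ha = native * cfg$synth$cell_area,
  converted_in_period_ha = c(NA, -diff(native)) * cfg$synth$cell_area)
message("Observed conversion per two-year period (ha):")
print(history)

write.csv(history, file.path(out, "history.csv"), row.names = FALSE)
write_property_map(ds$properties,
                   file.path(out, "properties.csv"),
                   file.path(out, "property_id.asc"))
write_ascii_grid(1 - ds$observed_states[[4L]]$native,
                 file.path(out, "anthropogenic_2016.asc"))
yaml::write_yaml(list(seed = STUDY_SEED,
                      intercept = ds$truth$intercept,
                      coefficients = as.list(ds$truth$coefficients)),
                 file.path(out, "truth.yaml"))
message("wrote ", out)
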