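#!/usr/bin/env Rscript
# Simulate one plate well: 12 three-channel fields with planted,
# analytically known cells (40% marker-positive), written as 3-page TIFFs
# plus a pooled ground-truth table.

suppressMessages(library(stau2screen))

out_dir <- "results/images"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

const <- function(v) intensity_law("constant", value = v)
sims <- lapply(1:12, function(i) {
  sim <- generate_field_image(image_sim_config(
    n_cells = 25, positive_fraction = 0.4, seed = 5000L + i,
    radius_range_um = c(5, 10),
    intensity_law_red = const(200), intensity_law_green = const(200),
    intensity_law_blue = const(200), background_noise_sd = 0))
  write_field_tiff(sim$image, file.path(out_dir, sprintf("A1_f%02d.tif", i)))
  sim$truth$field <- i
  sim
})

truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
write.csv(truth, "results/well_A1_ground_truth.csv", row.names = FALSE)

cat(sprintf("Simulated well A1: 12 fields, %d cells, %d marker-positive (%.1f%%).\n",
            nrow(truth), sum(truth$is_marker_positive),
            100 * mean(truth$is_marker_positive)))
cat("TIFFs in", out_dir, "- ground truth in results/well_A1_ground_truth.csv\n")
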