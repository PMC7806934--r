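#!/usr/bin/env Rscript
# Quantify the simulated well from its TIFF files alone (no ground truth):
# detect blobs per channel, apply the capture filters (perimeter 25-200 um,
# mean grey 140-300), colocalize red/green, call positivity (25-150 um,
# 150-280), and summarise the well. Then audit against the ground truth.

suppressMessages(library(stau2screen))

paths <- sort(list.files("results/images", pattern = "^A1_f.*\\.tif$",
                         full.names = TRUE))
stopifnot(length(paths) == 12)
fields <- lapply(paths, read_field_tiff, um_per_px = 0.65, bit_depth = 8)

cfg <- quant_config()
res <- quantify_well(fields, cfg, sample_id = "A1")
write.csv(res, "results/well_A1_sample.csv", row.names = FALSE)

truth <- read.csv("results/well_A1_ground_truth.csv")
cat(sprintf("Well A1: %d cells detected (%d planted), %d positive (%d planted).\n",
            res$n_cells, nrow(truth), res$n_positive,
            sum(truth$is_marker_positive)))
cat(sprintf("Percent positive: %.2f%% measured vs %.2f%% planted.\n",
            res$pct_positive, 100 * mean(truth$is_marker_positive)))
cat(sprintf("Average intensity of positive cells: %.1f grey units (planted 200).\n",
            res$avg_intensity))
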