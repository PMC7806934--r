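qc <- quant_config()

test_that("blank channels yield no signals", {
  blank <- matrix(0, 80, 80)
  expect_equal(nrow(detect_signals(blank, qc)), 0)
})

test_that("a clean disk is measured to analytic geometry", {
  # one disk, radius 10 um, uniform grey 200, noiseless
  sim <- generate_field_image(clean_field_config(
    n_cells = 1, positive_fraction = 1, radius_range_um = c(10, 10),
    seed = 6))
  sig <- detect_signals(sim$image, qc, "green")
  expect_equal(nrow(sig), 1)
  expect_lt(abs(sig$perimeter_um / (2 * pi * 10) - 1), 0.1)
  expect_lt(abs(sig$mean_grey - 200), 1)
})

test_that("capture filter rejects oversized blobs", {
  # true perimeter 250 um -> radius ~39.8 um, above the 200 um capture bound
  r <- 250 / (2 * pi)
  sim <- generate_field_image(clean_field_config(
    n_cells = 1, positive_fraction = 1, radius_range_um = c(r, r),
    seed = 6, field_width_px = 300, field_height_px = 300))
  expect_equal(nrow(detect_signals(sim$image, qc, "green")), 0)
})

test_that("perimeter estimator is consistent for disks across radii", {
  for (r_um in c(4, 6, 9, 13, 19)) {  # 6.2 to 29 px at 0.65 um/px
    sim <- generate_field_image(clean_field_config(
      n_cells = 1, positive_fraction = 1, radius_range_um = c(r_um, r_um),
      seed = 17, field_width_px = 150, field_height_px = 150))
    cfg <- quant_config(capture_perimeter_range = c(0, Inf))
    sig <- detect_signals(sim$image, cfg, "red")
    expect_equal(nrow(sig), 1)
    ratio <- sig$perimeter_um / (2 * pi * r_um)
    expect_gt(ratio, 0.9)
    expect_lt(ratio, 1.1)
  }
})

test_that("raising the detection threshold never increases detections", {
  # uniform-interior blobs: a threshold increase can only drop whole blobs,
  # never split one into several
  sim <- generate_field_image(clean_field_config(
    n_cells = 30, seed = 13,
    intensity_law_red = intensity_law("uniform", min = 150, max = 260)))
  counts <- vapply(c(100, 140, 180, 220, 260), function(th) {
    cfg <- quant_config(detection_threshold = th,
                        capture_perimeter_range = c(0, Inf),
                        capture_intensity_range = c(0, Inf))
    nrow(detect_signals(sim$image, cfg, "red"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every captured signal satisfies the inclusive capture ranges", {
  sim <- generate_field_image(clean_field_config(
    n_cells = 30, seed = 14, field_width_px = 900, field_height_px = 900,
    intensity_law_red = intensity_law("uniform", min = 120, max = 290),
    radius_range_um = c(3, 25), background_noise_sd = 5))
  sig <- detect_signals(sim$image, qc, "red")
  expect_true(all(sig$perimeter_um >= qc$capture_perimeter_range[1]))
  expect_true(all(sig$perimeter_um <= qc$capture_perimeter_range[2]))
  expect_true(all(sig$mean_grey >= qc$capture_intensity_range[1]))
  expect_true(all(sig$mean_grey <= qc$capture_intensity_range[2]))
})

sig_row <- function(x, y, perim = 60, grey = 200) {
  data.frame(signal_id = 1L, x = x, y = y, area_px = 100L,
             perimeter_um = perim, mean_grey = grey)
}

test_that("colocalization handles empty, coincident and crossed instances", {
  g <- sig_row(10, 10)
  none <- colocalize(empty <- sig_row(1, 1)[0, ], g, qc)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "discarded_green"), 1L)

  coincide <- colocalize(sig_row(10, 10), sig_row(10, 10), qc)
  expect_true(coincide$has_green)

  # 2 red + 2 green crossed: greedy result must equal the exhaustive
  # minimum-total-distance matching of the 2x2 instance
  red <- rbind(sig_row(10, 10), sig_row(16, 10))
  green <- rbind(sig_row(11, 10), sig_row(15, 10))
  out <- colocalize(red, green, qc)
  # brute force over both complete matchings (r1-g1/r2-g2 vs r1-g2/r2-g1)
  d <- function(i, j) sqrt((red$x[i] - green$x[j])^2 + (red$y[i] - green$y[j])^2)
  m1 <- d(1, 1) + d(2, 2); m2 <- d(1, 2) + d(2, 1)
  best <- if (m1 <= m2) list(c(1, 1), c(2, 2)) else list(c(1, 2), c(2, 1))
  for (pair in best)
    expect_equal(out$green_x[pair[1]], green$x[pair[2]])
})

test_that("green signals beyond the colocalization radius are discarded", {
  # 5 um tolerance = ~7.7 px at 0.65 um/px; offset 20 px is too far
  out <- colocalize(sig_row(10, 10), sig_row(30, 10), qc)
  expect_false(out$has_green)
  expect_equal(attr(out, "discarded_green"), 1L)
})

test_that("positivity bounds are inclusive and require a green signal", {
  mk_cell <- function(perim, grey, has = TRUE) {
    data.frame(cell_id = 1L, red_x = 5, red_y = 5, red_perimeter_um = 60,
               red_mean_grey = 200,
               green_x = if (has) 5 else NA_real_, green_y = if (has) 5 else NA_real_,
               green_perimeter_um = if (has) perim else NA_real_,
               green_mean_grey = if (has) grey else NA_real_,
               has_green = has)
  }
  expect_true(classify_positive(mk_cell(100, 200), qc)$is_positive)
  expect_true(classify_positive(mk_cell(150, 280), qc)$is_positive)  # bounds
  expect_true(classify_positive(mk_cell(25, 150), qc)$is_positive)   # bounds
  expect_false(classify_positive(mk_cell(150.5, 200), qc)$is_positive)
  expect_false(classify_positive(mk_cell(100, 281), qc)$is_positive)
  expect_false(classify_positive(mk_cell(0, 0, has = FALSE), qc)$is_positive)
})

make_cells <- function(green_means, positive) {
  n <- length(green_means)
  data.frame(cell_id = seq_len(n), red_x = seq_len(n), red_y = rep(1, n),
             red_perimeter_um = rep(60, n), red_mean_grey = rep(200, n),
             green_x = rep(1, n), green_y = rep(1, n),
             green_perimeter_um = rep(60, n),
             green_mean_grey = green_means,
             has_green = green_means > 0, is_positive = positive)
}

test_that("sample summary reproduces hand arithmetic in both modes", {
  cells <- make_cells(c(200, 180, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  mean_mode <- summarize_sample(cells, qc)
  expect_equal(mean_mode$avg_intensity, 190)  # (200 + 180) / 2
  expect_equal(mean_mode$pct_positive, 50)

  ratio_cfg <- quant_config(intensity_stat_mode = "ratio_as_stated")
  ratio_mode <- summarize_sample(cells, ratio_cfg)
  expect_equal(ratio_mode$avg_intensity, 380 / 380)  # negatives add 0

  all_pos <- summarize_sample(make_cells(rep(200, 10), rep(TRUE, 10)), qc)
  expect_equal(all_pos$pct_positive, 100)

  none_pos <- summarize_sample(make_cells(rep(0, 10), rep(FALSE, 10)), qc)
  expect_equal(none_pos$pct_positive, 0)
  expect_true(is.na(none_pos$avg_intensity))

  zero <- summarize_sample(make_cells(numeric(0), logical(0)), qc)
  expect_true(zero$undefined)
  expect_true(is.na(zero$pct_positive))
})

test_that("well quantification recovers planted ground truth over 12 fields", {
  sims <- lapply(1:12, function(i)
    generate_field_image(clean_field_config(n_cells = 20,
                                            positive_fraction = 0.4,
                                            seed = 100 + i)))
  fields <- lapply(sims, `[[`, "image")
  planted_pos <- sum(vapply(sims, function(s) sum(s$truth$is_marker_positive),
                            numeric(1)))
  res <- quantify_well(fields, qc, sample_id = "A1")
  expect_equal(res$n_cells, 12 * 20)
  expect_equal(res$n_positive, planted_pos)
  expect_equal(res$pct_positive, 100 * planted_pos / (12 * 20))

  # order invariance and single-field reduction
  shuffled <- quantify_well(fields[sample(12)], qc, sample_id = "A1")
  expect_equal(shuffled[c("n_cells", "n_positive", "pct_positive",
                          "avg_intensity")],
               res[c("n_cells", "n_positive", "pct_positive",
                     "avg_intensity")])

  one <- quantify_well(fields[1], qc)
  red <- detect_signals(fields[[1]], qc, "red")
  green <- detect_signals(fields[[1]], qc, "green")
  direct <- summarize_sample(classify_positive(colocalize(red, green, qc), qc), qc)
  expect_equal(one$n_positive, direct$n_positive)
  expect_equal(one$avg_intensity, direct$avg_intensity)

  expect_error(quantify_well(list(), qc), "at least one")
})

test_that("interassay rescaling equalizes the control across batches", {
  ctrl <- c(b1 = 100, b2 = 125)
  vals <- c(50, 80, 50, 80)
  batch <- c("b1", "b1", "b2", "b2")
  adj <- adjust_interassay(vals, batch, ctrl, reference = 100)
  expect_equal(adj, c(50, 80, 40, 64))
  expect_error(adjust_interassay(1, "b3", ctrl), "control")
})
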