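#' Signal quantification configuration
#'
#' Filter and measurement settings for per-channel blob detection and
#' positivity calling. Two filter stages mirror the screening protocol:
#' a *capture* filter applied at detection (perimeter 25-200 um, mean grey
#' 140-300 by default) and a stricter *positivity* filter applied to the
#' marker (green) signal of each cell (perimeter 25-150 um, mean grey
#' 150-280). All range bounds are inclusive.
#'
#' @param um_per_px pixel calibration (um/pixel); required for perimeter
#'   measurement.
#' @param detection_threshold binarization threshold in grey-value units;
#'   defaults to the capture-intensity lower bound.
#' @param capture_perimeter_range,capture_intensity_range inclusive
#'   (min, max) ranges a detected signal must satisfy to be kept.
#' @param positive_perimeter_range,positive_intensity_range inclusive
#'   (min, max) ranges the green signal must satisfy for the cell to be
#'   called marker-positive.
#' @param coloc_max_centroid_dist_um maximum red/green centroid distance
#'   (um) for colocalization.
#' @param intensity_stat_mode how the per-sample average intensity is
#'   computed: `"mean_of_positives"` (arithmetic mean of green mean grey
#'   over positive cells; grey-value scale, the default) or
#'   `"ratio_as_stated"` (sum of green mean grey over positive cells
#'   divided by the sum over all cells; a dimensionless ratio <= 1).
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(um_per_px = 0.65, detection_threshold = 140,
                         capture_perimeter_range = c(25, 200),
                         capture_intensity_range = c(140, 300),
                         positive_perimeter_range = c(25, 150),
                         positive_intensity_range = c(150, 280),
                         coloc_max_centroid_dist_um = 5,
                         intensity_stat_mode = c("mean_of_positives",
                                                 "ratio_as_stated")) {
  intensity_stat_mode <- match.arg(intensity_stat_mode)
  ok_range <- function(r) length(r) == 2 && !anyNA(r) && r[1] <= r[2]
  if (is.null(um_per_px) || is.na(um_per_px) || um_per_px <= 0)
    stop("um_per_px calibration must be a positive number", call. = FALSE)
  for (r in list(capture_perimeter_range, capture_intensity_range,
                 positive_perimeter_range, positive_intensity_range))
    if (!ok_range(r)) stop("filter ranges must be ordered (min, max) pairs",
                           call. = FALSE)
  if (coloc_max_centroid_dist_um <= 0)
    stop("coloc_max_centroid_dist_um must be > 0", call. = FALSE)
  structure(list(um_per_px = um_per_px,
                 detection_threshold = detection_threshold,
                 capture_perimeter_range = capture_perimeter_range,
                 capture_intensity_range = capture_intensity_range,
                 positive_perimeter_range = positive_perimeter_range,
                 positive_intensity_range = positive_intensity_range,
                 coloc_max_centroid_dist_um = coloc_max_centroid_dist_um,
                 intensity_stat_mode = intensity_stat_mode),
            class = "quant_config")
}

# Perimeter of one labelled object: polygon length through the ordered
# 8-connected outer contour, x 0.95 chain-code bias correction (digital
# straight segments overestimate smooth boundaries by ~5%). Within 0.5% of
# 2*pi*r for digital disks of radius >= 5 px.
contour_perimeter_px <- function(contour_xy) {
  n <- nrow(contour_xy)
  if (n < 2) return(0)
  nxt <- contour_xy[c(2:n, 1), , drop = FALSE]
  0.95 * sum(sqrt(rowSums((contour_xy - nxt)^2)))
}

empty_signals <- function() {
  data.frame(signal_id = integer(0), x = numeric(0), y = numeric(0),
             area_px = integer(0), perimeter_um = numeric(0),
             mean_grey = numeric(0))
}

#' Detect and measure signals on one image channel
#'
#' Thresholds the channel at `detection_threshold`, labels connected
#' components (8-connectivity), and measures each blob: centroid (px),
#' area (px), boundary perimeter scaled to micrometres, and interior mean
#' grey value. Only blobs inside both capture ranges (inclusive) are
#' returned.
#'
#' @param channel numeric matrix (one channel, indexed \[x, y\]) or a
#'   `field_image`, in which case `which` selects the channel.
#' @param config a [quant_config()]. When `channel` is a `field_image` its
#'   own `um_per_px` overrides the config calibration.
#' @param which channel name when `channel` is a `field_image`.
#' @return `data.frame` with one row per captured signal: `signal_id`,
#'   `x`, `y`, `area_px`, `perimeter_um`, `mean_grey`.
#' @export
detect_signals <- function(channel, config, which = c("green", "red", "blue")) {
  stopifnot(inherits(config, "quant_config"))
  um_per_px <- config$um_per_px
  if (inherits(channel, "field_image")) {
    which <- match.arg(which)
    um_per_px <- channel$um_per_px
    channel <- channel$channels[[which]]
  }
  if (!is.matrix(channel)) stop("channel must be a numeric matrix", call. = FALSE)
  if (is.null(um_per_px) || is.na(um_per_px) || um_per_px <= 0)
    stop("missing um-per-pixel calibration", call. = FALSE)

  mask <- channel >= config$detection_threshold
  if (!any(mask)) return(empty_signals())
  lab <- EBImage::bwlabel(mask)
  n_obj <- max(lab)
  contours <- EBImage::ocontour(lab)

  idx <- which(lab > 0)
  labv <- lab[idx]
  greyv <- channel[idx]
  xs <- ((idx - 1) %% nrow(channel)) + 1
  ys <- ((idx - 1) %/% nrow(channel)) + 1
  area <- tabulate(labv, nbins = n_obj)
  mean_grey <- as.numeric(tapply(greyv, labv, mean))
  cx <- as.numeric(tapply(xs, labv, mean))
  cy <- as.numeric(tapply(ys, labv, mean))
  perim_um <- vapply(contours, contour_perimeter_px, numeric(1)) * um_per_px

  out <- data.frame(signal_id = seq_len(n_obj), x = cx, y = cy,
                    area_px = area, perimeter_um = perim_um,
                    mean_grey = mean_grey)
  keep <- out$perimeter_um >= config$capture_perimeter_range[1] &
    out$perimeter_um <= config$capture_perimeter_range[2] &
    out$mean_grey >= config$capture_intensity_range[1] &
    out$mean_grey <= config$capture_intensity_range[2]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$signal_id <- seq_len(nrow(out))
  out
}

#' Colocalize red (leukocyte) and green (marker) signals
#'
#' Greedy nearest-centroid matching: green signals, processed in (y, x)
#' order, are each assigned to the nearest still-unassigned red signal
#' within `coloc_max_centroid_dist_um`. Every red signal becomes one cell
#' record; unmatched green signals are discarded and counted in the
#' `discarded_green` attribute.
#'
#' @param red,green signal tables from [detect_signals()] on the same field.
#' @param config a [quant_config()].
#' @return `data.frame` of cell records (one per red signal) with the red
#'   measurements, the matched green measurements (`NA` when none), and a
#'   `has_green` flag; attribute `discarded_green` counts unmatched green
#'   signals.
#' @export
colocalize <- function(red, green, config) {
  stopifnot(inherits(config, "quant_config"))
  n_red <- nrow(red)
  cells <- data.frame(
    cell_id = seq_len(n_red),
    red_x = red$x, red_y = red$y,
    red_perimeter_um = red$perimeter_um, red_mean_grey = red$mean_grey,
    green_x = rep(NA_real_, n_red), green_y = rep(NA_real_, n_red),
    green_perimeter_um = rep(NA_real_, n_red),
    green_mean_grey = rep(NA_real_, n_red),
    has_green = rep(FALSE, n_red))
  discarded <- 0L
  if (n_red > 0 && nrow(green) > 0) {
    green <- green[order(green$y, green$x), , drop = FALSE]
    free <- rep(TRUE, n_red)
    max_d_px <- config$coloc_max_centroid_dist_um / config$um_per_px
    for (gi in seq_len(nrow(green))) {
      d2 <- (red$x - green$x[gi])^2 + (red$y - green$y[gi])^2
      d2[!free] <- Inf
      j <- which.min(d2)
      if (is.finite(d2[j]) && sqrt(d2[j]) <= max_d_px) {
        free[j] <- FALSE
        cells$green_x[j] <- green$x[gi]
        cells$green_y[j] <- green$y[gi]
        cells$green_perimeter_um[j] <- green$perimeter_um[gi]
        cells$green_mean_grey[j] <- green$mean_grey[gi]
        cells$has_green[j] <- TRUE
      } else {
        discarded <- discarded + 1L
      }
    }
  } else {
    discarded <- nrow(green)
  }
  attr(cells, "discarded_green") <- discarded
  cells
}

#' Call marker positivity per cell
#'
#' A cell is marker-positive iff it has a colocalized green signal whose
#' perimeter and mean grey value fall inside the positivity ranges
#' (inclusive bounds).
#'
#' @param cells cell records from [colocalize()].
#' @param config a [quant_config()].
#' @return `cells` with an `is_positive` logical column added.
#' @export
classify_positive <- function(cells, config) {
  stopifnot(inherits(config, "quant_config"))
  pr <- config$positive_perimeter_range
  ir <- config$positive_intensity_range
  cells$is_positive <- !is.na(cells$green_mean_grey) & cells$has_green &
    cells$green_perimeter_um >= pr[1] & cells$green_perimeter_um <= pr[2] &
    cells$green_mean_grey >= ir[1] & cells$green_mean_grey <= ir[2]
  cells
}

#' Summarise a sample from its pooled cell records
#'
#' Computes the two per-sample screening statistics:
#' `pct_positive = 100 * n_positive / n_cells`, and `avg_intensity` per the
#' configured `intensity_stat_mode` — either the arithmetic mean of green
#' mean grey over positive cells (`"mean_of_positives"`, grey-value scale)
#' or the ratio of summed positive-cell green intensity to the summed green
#' intensity of all cells (`"ratio_as_stated"`; cells without a green
#' signal contribute 0 to the denominator sum).
#'
#' @param cells classified cell records (pooled over the sample's fields).
#' @param config a [quant_config()].
#' @param sample_id,group_label optional annotations carried into the row.
#' @return one-row `data.frame`: `sample_id`, `group`, `n_cells`,
#'   `n_positive`, `avg_intensity`, `pct_positive`, `intensity_mode`,
#'   `undefined` (TRUE when `n_cells == 0`, in which case both statistics
#'   are `NA` rather than an error).
#' @export
summarize_sample <- function(cells, config, sample_id = NA_character_,
                             group_label = NA_character_) {
  stopifnot(inherits(config, "quant_config"))
  if (!"is_positive" %in% names(cells))
    cells <- classify_positive(cells, config)
  n_cells <- nrow(cells)
  n_pos <- sum(cells$is_positive)
  if (n_cells == 0L) {
    return(data.frame(sample_id = sample_id, group = group_label,
                      n_cells = 0L, n_positive = 0L,
                      avg_intensity = NA_real_, pct_positive = NA_real_,
                      intensity_mode = config$intensity_stat_mode,
                      undefined = TRUE))
  }
  green <- ifelse(is.na(cells$green_mean_grey), 0, cells$green_mean_grey)
  avg <- if (config$intensity_stat_mode == "mean_of_positives") {
    if (n_pos > 0) mean(cells$green_mean_grey[cells$is_positive]) else NA_real_
  } else {
    denom <- sum(green)
    if (denom > 0) sum(green[cells$is_positive]) / denom else NA_real_
  }
  data.frame(sample_id = sample_id, group = group_label,
             n_cells = n_cells, n_positive = n_pos,
             avg_intensity = avg,
             pct_positive = 100 * n_pos / n_cells,
             intensity_mode = config$intensity_stat_mode,
             undefined = FALSE)
}

#' Quantify one well from its field images
#'
#' Runs detect -> colocalize -> classify on every supplied field (the
#' protocol captures up to 12 fields per well), pools the cell records and
#' returns one [summarize_sample()] row for the well. The result is
#' invariant to field order.
#'
#' @param fields list of `field_image` objects (length 1-12).
#' @param config a [quant_config()].
#' @param sample_id,group_label annotations for the output row.
#' @return one-row sample `data.frame` (see [summarize_sample()]).
#' @export
quantify_well <- function(fields, config, sample_id = NA_character_,
                          group_label = NA_character_) {
  stopifnot(inherits(config, "quant_config"))
  if (length(fields) == 0L) stop("at least one field required", call. = FALSE)
  if (length(fields) > 12L) stop("at most 12 fields per well", call. = FALSE)
  per_field <- lapply(fields, function(f) {
    red <- detect_signals(f, config, which = "red")
    green <- detect_signals(f, config, which = "green")
    classify_positive(colocalize(red, green, config), config)
  })
  pooled <- do.call(rbind, per_field)
  summarize_sample(pooled, config, sample_id = sample_id,
                   group_label = group_label)
}

#' Interassay intensity rescaling
#'
#' Multiplicative per-batch adjustment against a shared positive control:
#' each batch's intensities are multiplied by
#' `reference / control_by_batch[batch]`, so the control reads the same
#' value in every batch.
#'
#' @param values numeric intensities to adjust.
#' @param batch batch identifier per value.
#' @param control_by_batch named numeric vector: the positive-control
#'   intensity measured in each batch.
#' @param reference target control level; defaults to the mean of the
#'   per-batch controls.
#' @return adjusted numeric vector.
#' @export
adjust_interassay <- function(values, batch,
                              control_by_batch,
                              reference = mean(control_by_batch)) {
  batch <- as.character(batch)
  if (!all(batch %in% names(control_by_batch)))
    stop("every batch needs a control intensity", call. = FALSE)
  if (any(control_by_batch <= 0))
    stop("control intensities must be > 0", call. = FALSE)
  values * reference / unname(control_by_batch[batch])
}
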