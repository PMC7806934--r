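#' Intensity law specification
#'
#' Small constructor for the per-cell intensity distributions used by the
#' field-image simulator. Supported laws: `"constant"` (args: `value`),
#' `"uniform"` (args: `min`, `max`) and `"normal"` (args: `mean`, `sd`).
#' All values are on the grey-value scale of the simulated image.
#'
#' @param dist one of `"constant"`, `"uniform"`, `"normal"`.
#' @param ... distribution parameters (see Details).
#' @return an object of class `intensity_law`.
#' @export
intensity_law <- function(dist = c("constant", "uniform", "normal"), ...) {
  dist <- match.arg(dist)
  pars <- list(...)
  need <- switch(dist,
    constant = "value",
    uniform  = c("min", "max"),
    normal   = c("mean", "sd"))
  if (!all(need %in% names(pars)))
    stop("intensity_law('", dist, "') needs parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (dist == "uniform" && pars$min > pars$max)
    stop("uniform intensity law needs min <= max", call. = FALSE)
  structure(list(dist = dist, pars = pars[need]), class = "intensity_law")
}

draw_intensity <- function(law, n) {
  p <- law$pars
  switch(law$dist,
    constant = rep(p$value, n),
    uniform  = stats::runif(n, p$min, p$max),
    normal   = stats::rnorm(n, p$mean, p$sd))
}

#' Field-image simulation configuration
#'
#' Parameters for one simulated 3-channel fluorescence field: a nuclear
#' (blue) stain, a pan-leukocyte (red) stain, and the marker (green) stain.
#' Cells are rendered as filled disks of uniform interior intensity so that
#' the true perimeter (2 * pi * r) and true mean grey value are analytically
#' known for every planted cell.
#'
#' @param field_width_px,field_height_px field size in pixels.
#' @param um_per_px pixel calibration in micrometres per pixel. The default
#'   0.65 is typical of a 20x widefield objective; it must be set to the
#'   acquisition calibration when analysing other data.
#' @param n_cells number of cells to plant (>= 0).
#' @param positive_fraction fraction of planted cells that also receive a
#'   green (marker) disk, in \[0, 1\]. Exactly
#'   `round(positive_fraction * n_cells)` cells are made positive.
#' @param radius_range_um cell radius range in micrometres; radii are drawn
#'   uniformly in this range.
#' @param intensity_law_red,intensity_law_green,intensity_law_blue
#'   [intensity_law()] objects for the per-cell disk intensities.
#' @param background_noise_sd standard deviation of additive Gaussian
#'   background noise (grey-value units, >= 0); 0 gives a noiseless image.
#' @param bit_depth 8 or 16; intensities are clipped to
#'   \[0, 2^bit_depth - 1\].
#' @param seed optional integer seed; with a fixed seed the generated image
#'   is reproducible byte-for-byte.
#' @return an object of class `image_sim_config`.
#' @export
image_sim_config <- function(field_width_px = 400, field_height_px = 400,
                             um_per_px = 0.65, n_cells = 50,
                             positive_fraction = 0.5,
                             radius_range_um = c(5, 10),
                             intensity_law_red = intensity_law("uniform", min = 180, max = 260),
                             intensity_law_green = intensity_law("uniform", min = 180, max = 260),
                             intensity_law_blue = intensity_law("uniform", min = 180, max = 260),
                             background_noise_sd = 0, bit_depth = 8,
                             seed = NULL) {
  if (field_width_px < 1 || field_height_px < 1)
    stop("field dimensions must be positive", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]", call. = FALSE)
  if (length(radius_range_um) != 2 || any(radius_range_um <= 0) ||
      radius_range_um[1] > radius_range_um[2])
    stop("radius_range_um must be a positive (min, max) pair", call. = FALSE)
  if (um_per_px <= 0) stop("um_per_px must be > 0", call. = FALSE)
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(list(
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px),
    um_per_px = um_per_px, n_cells = as.integer(n_cells),
    positive_fraction = positive_fraction,
    radius_range_um = radius_range_um,
    intensity_law_red = intensity_law_red,
    intensity_law_green = intensity_law_green,
    intensity_law_blue = intensity_law_blue,
    background_noise_sd = background_noise_sd,
    bit_depth = as.integer(bit_depth), seed = seed),
    class = "image_sim_config")
}

# Rejection sampler for non-overlapping disk centres: minimum centre
# distance is the sum of the two radii (in px), so one blob <-> one cell.
place_cells <- function(n, radii_px, width, height, max_tries = 200L) {
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii_px[i]
    if (2 * r + 2 > min(width, height))
      stop("cell radius too large for field", call. = FALSE)
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::runif(1, r + 1, width - r)
      y <- stats::runif(1, r + 1, height - r)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all((cx[j] - x)^2 + (cy[j] - y)^2 >=
                    (radii_px[j] + r + 1)^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells; ",
           "reduce n_cells or radius_range_um", call. = FALSE)
  }
  cbind(x = cx, y = cy)
}

# paint a uniform disk onto channel matrix m (indexed [x, y]); returns m
paint_disk <- function(m, cx, cy, r_px, value) {
  x0 <- max(1L, floor(cx - r_px)); x1 <- min(nrow(m), ceiling(cx + r_px))
  y0 <- max(1L, floor(cy - r_px)); y1 <- min(ncol(m), ceiling(cy + r_px))
  xs <- x0:x1; ys <- y0:y1
  sub <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= r_px^2
  block <- m[xs, ys, drop = FALSE]
  block[sub] <- value
  m[xs, ys] <- block
  m
}

#' Simulate one 3-channel immunofluorescence field
#'
#' Plants `n_cells` non-overlapping disk-shaped cells. Every cell carries a
#' blue (nuclear) and a red (leukocyte) disk at its centroid; a fraction
#' `positive_fraction` additionally carries a green (marker) disk, i.e. is
#' marker-positive by construction. Gaussian background noise is then added
#' per channel and all grey values are clipped to the bit-depth range.
#'
#' @param config an [image_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{image}{a `field_image`: named list of channel matrices
#'       (`blue`, `red`, `green`, indexed \[x, y\]) plus `um_per_px` and
#'       `bit_depth`.}
#'     \item{truth}{ground-truth `data.frame`: one row per planted cell with
#'       centroid (px), radius (um), true perimeter (um), per-channel mean
#'       grey value (green is `NA` for negative cells) and
#'       `is_marker_positive`.}
#'   }
#' @export
generate_field_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  run <- function() {
    w <- config$field_width_px; h <- config$field_height_px
    maxg <- 2^config$bit_depth - 1
    n <- config$n_cells
    blank <- function() matrix(0, nrow = w, ncol = h)
    ch <- list(blue = blank(), red = blank(), green = blank())

    if (n > 0L) {
      radii_um <- stats::runif(n, config$radius_range_um[1], config$radius_range_um[2])
      radii_px <- radii_um / config$um_per_px
      centres <- place_cells(n, radii_px, w, h)
      n_pos <- round(config$positive_fraction * n)
      pos_idx <- if (n_pos > 0) sample(n, n_pos) else integer(0)
      is_pos <- seq_len(n) %in% pos_idx
      clip <- function(v) pmin(pmax(v, 0), maxg)
      grey <- list(
        blue  = clip(draw_intensity(config$intensity_law_blue, n)),
        red   = clip(draw_intensity(config$intensity_law_red, n)),
        green = clip(draw_intensity(config$intensity_law_green, n)))
      for (i in seq_len(n)) {
        ch$blue <- paint_disk(ch$blue, centres[i, 1], centres[i, 2], radii_px[i], grey$blue[i])
        ch$red  <- paint_disk(ch$red,  centres[i, 1], centres[i, 2], radii_px[i], grey$red[i])
        if (is_pos[i])
          ch$green <- paint_disk(ch$green, centres[i, 1], centres[i, 2], radii_px[i], grey$green[i])
      }
      truth <- data.frame(
        cell_id = seq_len(n),
        x_px = centres[, 1], y_px = centres[, 2],
        radius_um = radii_um,
        perimeter_um = 2 * pi * radii_um,
        blue_grey = grey$blue, red_grey = grey$red,
        green_grey = ifelse(is_pos, grey$green, NA_real_),
        is_marker_positive = is_pos)
    } else {
      truth <- data.frame(
        cell_id = integer(0), x_px = numeric(0), y_px = numeric(0),
        radius_um = numeric(0), perimeter_um = numeric(0),
        blue_grey = numeric(0), red_grey = numeric(0),
        green_grey = numeric(0), is_marker_positive = logical(0))
    }

    if (config$background_noise_sd > 0) {
      w_ <- config$field_width_px; h_ <- config$field_height_px
      for (nm in names(ch)) {
        ch[[nm]] <- pmin(pmax(
          ch[[nm]] + matrix(stats::rnorm(w_ * h_, 0, config$background_noise_sd), w_, h_),
          0), maxg)
      }
    }
    image <- structure(list(channels = ch, um_per_px = config$um_per_px,
                            bit_depth = config$bit_depth),
                       class = "field_image")
    list(image = image, truth = truth)
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' Write / read a field image as a 3-page TIFF
#'
#' Channels are stored in the order blue, red, green, one page each, at the
#' image's bit depth. Calibration is not stored in the file and must be
#' supplied again on read.
#'
#' @param image a `field_image`.
#' @param path TIFF file path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns a `field_image`.
#' @export
write_field_tiff <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  maxg <- 2^image$bit_depth - 1
  pages <- lapply(image$channels[c("blue", "red", "green")],
                  function(m) t(m) / maxg)  # tiff expects [row=y, col=x]
  tiff::writeTIFF(pages, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param um_per_px calibration of the stored image (um/pixel).
#' @param bit_depth bit depth the image was written at.
#' @export
read_field_tiff <- function(path, um_per_px, bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3)
    stop("expected a 3-page TIFF (blue, red, green)", call. = FALSE)
  maxg <- 2^bit_depth - 1
  ch <- lapply(pages, function(m) t(m) * maxg)
  names(ch) <- c("blue", "red", "green")
  structure(list(channels = ch, um_per_px = um_per_px,
                 bit_depth = as.integer(bit_depth)),
            class = "field_image")
}
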