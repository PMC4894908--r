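#' @useDynLib mucilager, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @import tibble
NULL

# ---- RGB image container ----------------------------------------------------

#' Construct an RGB image with pixel-size calibration
#'
#' The common substrate of the three imaging assays (ruthenium-red capsules,
#' S4B fluorescence, polarized-light birefringence). Pixels are stored as a
#' `height x width x 3` integer array with intensities in \[0, 255\] and a
#' fixed red, green, blue channel order. Coordinates are row-major with the
#' origin at the top-left corner, 0-based.
#'
#' @param pixels Integer array `height x width x 3` (or a `height x width`
#'   matrix, replicated to three identical channels) with values in
#'   \[0, 255\].
#' @param pixel_size Micrometres per pixel; strictly positive scalar.
#' @param source Optional character tag recording where the pixels came from
#'   (a file path or generator name).
#' @return An object of class `rgb_image` with elements `pixels`,
#'   `pixel_size` and `source`.
#' @export
rgb_image <- function(pixels, pixel_size = 1, source = NA_character_) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array or a matrix.")
  }
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L) {
    abort("images must be at least 8 x 8 pixels.")
  }
  storage.mode(pixels) <- "integer"
  rng <- range(pixels)
  if (anyNA(pixels) || rng[1] < 0L || rng[2] > 255L) {
    abort("pixel intensities must lie in [0, 255] with no missing values.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      is.na(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (micrometres/pixel).")
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         source = source),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %.4g um/px", d[1], d[2], x$pixel_size))
  if (!is.na(x$source)) cat(sprintf(" [%s]", x$source))
  cat("\n")
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read a PNG or TIFF micrograph into an `rgb_image`
#'
#' Grayscale rasters are replicated to three identical channels; an alpha
#' channel, if present, is dropped. Images stored at more than 8 bits per
#' sample are min-max rescaled to \[0, 255\] with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_size Micrometres per pixel.
#' @return An [rgb_image()].
#' @export
read_image <- function(path, pixel_size = 1) {
  if (!file.exists(path)) abort(paste0("cannot read image: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext, " (", path, ")"))
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 4L) raw <- raw[, , 1:3]
  # readPNG/readTIFF return [0, 1] doubles regardless of on-disk depth;
  # values above 1 can only come from unnormalized high-depth TIFFs
  if (max(raw) > 1) {
    warn(paste0("rescaling >8-bit intensities to [0, 255]: ", path))
    raw <- (raw - min(raw)) / (max(raw) - min(raw))
  }
  px <- round(raw * 255)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  rgb_image(px, pixel_size = pixel_size, source = path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(ifelse(mask$pixels, 1, 0), path)
  invisible(path)
}

# ---- Threshold windows ------------------------------------------------------

#' Per-channel inclusive color-threshold window
#'
#' Reproduces ImageJ's Color Threshold semantics: a pixel is selected iff
#' every channel intensity lies inclusively between that channel's minimum
#' and maximum.
#'
#' @param red,green,blue Length-2 integer vectors `c(min, max)` in
#'   \[0, 255\], `min <= max`.
#' @return A `threshold_window` object.
#' @seealso [rr_capsule_window()], [rr_seed_window()],
#'   [birefringence_window()] for the windows used by the assays.
#' @export
threshold_window <- function(red = c(0L, 255L), green = c(0L, 255L),
                             blue = c(0L, 255L)) {
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < 0L || x[2] > 255L)
      abort(sprintf("`%s` must be c(min, max) with 0 <= min <= max <= 255.", nm))
    x
  }
  structure(
    list(red = chk(red, "red"), green = chk(green, "green"),
         blue = chk(blue, "blue")),
    class = "threshold_window"
  )
}

#' @export
print.threshold_window <- function(x, ...) {
  cat(sprintf("<threshold_window> red (%d, %d), green (%d, %d), blue (%d, %d)\n",
              x$red[1], x$red[2], x$green[1], x$green[2], x$blue[1], x$blue[2]))
  invisible(x)
}

#' Default threshold windows for the three imaging assays
#'
#' `rr_capsule_window()` selects mucilage-plus-seed regions in
#' ruthenium-red micrographs, `rr_seed_window()` selects the seed bodies
#' alone, and `birefringence_window()` selects bright crystalline regions in
#' polarized-light images. These are the calibrated windows of the published
#' Fiji macros, on 8-bit RGB channels.
#'
#' @return A [threshold_window()].
#' @export
rr_capsule_window <- function() {
  threshold_window(red = c(0, 255), green = c(0, 115), blue = c(0, 255))
}

#' @rdname rr_capsule_window
#' @export
rr_seed_window <- function() {
  threshold_window(red = c(0, 120), green = c(0, 255), blue = c(0, 255))
}

#' @rdname rr_capsule_window
#' @export
birefringence_window <- function() {
  threshold_window(red = c(55, 255), green = c(140, 255), blue = c(60, 255))
}

#' Segment an image by a color-threshold window
#'
#' @param image An [rgb_image()].
#' @param window A [threshold_window()].
#' @return A `binary_mask`: logical `height x width` matrix plus the
#'   inherited `pixel_size`.
#' @export
segment_by_window <- function(image, window) {
  stopifnot(inherits(image, "rgb_image"), inherits(window, "threshold_window"))
  p <- image$pixels
  m <- p[, , 1] >= window$red[1]   & p[, , 1] <= window$red[2] &
       p[, , 2] >= window$green[1] & p[, , 2] <= window$green[2] &
       p[, , 3] >= window$blue[1]  & p[, , 3] <= window$blue[2]
  binary_mask(m, pixel_size = image$pixel_size)
}

#' Construct a binary mask
#'
#' @param pixels Logical matrix.
#' @param pixel_size Micrometres per pixel, inherited from the source image.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size = 1) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) abort("mask contains missing values.")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    abort("`pixel_size` must be positive.")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' absorbed into the foreground, so a hole ends up belonging to the particle
#' that encloses it.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  bg <- cc_label_cpp(!mask$pixels, 4L)
  n <- attr(bg, "n_components")
  if (n == 0L) return(mask)
  nr <- nrow(bg); nc <- ncol(bg)
  border_labels <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  hole <- setdiff(seq_len(n), border_labels)
  m <- mask$pixels
  if (length(hole)) m[bg %in% hole] <- TRUE
  binary_mask(m, mask$pixel_size)
}

# ---- Crofton perimeter ------------------------------------------------------

# 4-direction Crofton perimeter of a binary matrix (integral-geometry
# intercept estimate). The 2x2 configuration code at each padded pixel is
# m[i,j] + 2 m[i+1,j] + 4 m[i,j-1] + 8 m[i+1,j-1]; each code contributes a
# fixed length increment. Unbiased for lines at 0/45/90/135 degrees and
# accurate for smooth outlines, which keeps circularity of rasterized disks
# near 1 where naive edge counting would not.
crofton_perimeter <- function(m) {
  storage.mode(m) <- "integer"
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  tr <- p[1:(nr + 1L), 2:(nc + 2L)]  # top-right of each 2x2 window
  br <- p[2:(nr + 2L), 2:(nc + 2L)]  # bottom-right
  tl <- p[1:(nr + 1L), 1:(nc + 1L)]  # top-left
  bl <- p[2:(nr + 2L), 1:(nc + 1L)]  # bottom-left
  code <- br + 2L * tr + 4L * bl + 8L * tl
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Circularity of a particle
#'
#' `4 * pi * area / perimeter^2`, clamped at 1.0 (small rasterized particles
#' can exceed 1 under any discrete perimeter estimate; ImageJ clamps the
#' same way). 1 for a disk, approaching 0 for elongated objects.
#'
#' @param area_px Particle area in pixels (>= 1).
#' @param perimeter_px Perimeter estimate in pixels (> 0).
#' @return Circularity in \[0, 1\].
#' @export
circularity <- function(area_px, perimeter_px) {
  if (any(area_px < 1)) abort("`area_px` must be >= 1.")
  if (any(perimeter_px <= 0)) abort("`perimeter_px` must be positive.")
  pmin(4 * pi * area_px / perimeter_px^2, 1.0)
}

# ---- Particle analysis ------------------------------------------------------

#' Label connected particles and measure them
#'
#' Connected-component analysis of a binary mask under 8-connectivity (the
#' foreground connectivity of ImageJ's Analyze Particles). Optionally fills
#' interior holes before measuring, mirroring the "include holes" option.
#'
#' @param mask A `binary_mask`.
#' @param fill_holes Absorb enclosed background regions into their particle
#'   before measuring?
#' @return A tibble with one row per particle: `label`, `area_px`,
#'   `area_um2`, `perimeter_px`, `circularity`, `centroid_row`,
#'   `centroid_col`, `touches_edge`, and the half-open 0-based bounding box
#'   `row0`, `col0`, `row1`, `col1`. An empty mask yields a zero-row tibble.
#' @export
label_particles <- function(mask, fill_holes = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (isTRUE(fill_holes)) mask <- fill_holes(mask)
  lab <- cc_label_cpp(mask$pixels, 8L)
  n <- attr(lab, "n_components")
  if (n == 0L) {
    out <- tibble(
      label = integer(), area_px = integer(), area_um2 = numeric(),
      perimeter_px = numeric(), circularity = numeric(),
      centroid_row = numeric(), centroid_col = numeric(),
      touches_edge = logical(), row0 = integer(), col0 = integer(),
      row1 = integer(), col1 = integer()
    )
    attr(out, "labels") <- lab
    attr(out, "pixel_size") <- mask$pixel_size
    return(out)
  }
  s <- cc_stats_cpp(lab, n)
  per <- vapply(seq_len(n), function(k) {
    rows <- (s$row0[k] + 1L):(s$row1[k] + 1L)
    cols <- (s$col0[k] + 1L):(s$col1[k] + 1L)
    crofton_perimeter(lab[rows, cols, drop = FALSE] == k)
  }, numeric(1))
  out <- tibble(
    label = seq_len(n),
    area_px = s$area_px,
    area_um2 = s$area_px * mask$pixel_size^2,
    perimeter_px = per,
    circularity = circularity(s$area_px, per),
    centroid_row = s$centroid_row,
    centroid_col = s$centroid_col,
    touches_edge = s$touches_edge,
    row0 = s$row0, col0 = s$col0,
    row1 = s$row1 + 1L, col1 = s$col1 + 1L
  )
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- mask$pixel_size
  out
}

#' Particle selection filter
#'
#' The "circularity = 0.5-1.0, excluding edges and extreme sizes" selection
#' of the capsule-area macro. When the area bounds are `NULL`, "extreme
#' sizes" defaults to \[0.25x, 4x\] the median particle area of the image
#' under analysis, applied at filter time.
#'
#' @param circularity_min,circularity_max Circularity bounds in \[0, 1\].
#' @param area_min_px,area_max_px Absolute pixel-area bounds, or `NULL` for
#'   the median-relative default.
#' @param exclude_edges Drop particles touching the image border?
#' @return A `particle_filter` object.
#' @export
particle_filter <- function(circularity_min = 0.5, circularity_max = 1.0,
                            area_min_px = NULL, area_max_px = NULL,
                            exclude_edges = TRUE) {
  if (circularity_min > circularity_max ||
      circularity_min < 0 || circularity_max > 1)
    abort("circularity bounds must satisfy 0 <= min <= max <= 1.")
  if (!is.null(area_min_px) && !is.null(area_max_px) &&
      area_min_px > area_max_px)
    abort("`area_min_px` must not exceed `area_max_px`.")
  structure(
    list(circularity_min = circularity_min, circularity_max = circularity_max,
         area_min_px = area_min_px, area_max_px = area_max_px,
         exclude_edges = isTRUE(exclude_edges)),
    class = "particle_filter"
  )
}

#' Apply a particle filter
#'
#' @param particles A particle tibble from [label_particles()].
#' @param filter A [particle_filter()].
#' @return The retained rows, order preserved.
#' @export
apply_filter <- function(particles, filter) {
  stopifnot(inherits(filter, "particle_filter"))
  if (nrow(particles) == 0L) return(particles)
  amin <- filter$area_min_px
  amax <- filter$area_max_px
  med <- stats::median(particles$area_px)
  if (is.null(amin)) amin <- 0.25 * med
  if (is.null(amax)) amax <- 4 * med
  keep <- particles$circularity >= filter$circularity_min &
    particles$circularity <= filter$circularity_max &
    particles$area_px >= amin & particles$area_px <= amax
  if (filter$exclude_edges) keep <- keep & !particles$touches_edge
  out <- particles[keep, , drop = FALSE]
  attr(out, "labels") <- attr(particles, "labels")
  attr(out, "pixel_size") <- attr(particles, "pixel_size")
  out
}

#' Write a particle table to CSV
#'
#' @param particles A particle tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(particles, path) {
  cols <- c("label", "area_px", "area_um2", "perimeter_px", "circularity",
            "centroid_row", "centroid_col", "touches_edge")
  readr::write_csv(particles[, cols], path)
  invisible(path)
}

# ---- YAML config ------------------------------------------------------------

#' Read threshold windows and a particle filter from a YAML config
#'
#' The config may contain `capsule_window`, `seed_window`,
#' `birefringence_window` (each with `red_min`, `red_max`, `green_min`,
#' `green_max`, `blue_min`, `blue_max`) and `filter` (with
#' `circularity_min`, `circularity_max`, `area_min_px`, `area_max_px`,
#' `exclude_edges`). Missing entries fall back to the assay defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `capsule_window`, `seed_window`,
#'   `birefringence_window` and `filter`.
#' @export
read_threshold_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  win <- function(entry, default) {
    if (is.null(entry)) return(default)
    threshold_window(
      red = c(entry$red_min, entry$red_max),
      green = c(entry$green_min, entry$green_max),
      blue = c(entry$blue_min, entry$blue_max)
    )
  }
  flt <- cfg$filter
  filter <- if (is.null(flt)) {
    particle_filter()
  } else {
    particle_filter(
      circularity_min = flt$circularity_min %||% 0.5,
      circularity_max = flt$circularity_max %||% 1.0,
      area_min_px = flt$area_min_px,
      area_max_px = flt$area_max_px,
      exclude_edges = flt$exclude_edges %||% TRUE
    )
  }
  list(
    capsule_window = win(cfg$capsule_window, rr_capsule_window()),
    seed_window = win(cfg$seed_window, rr_seed_window()),
    birefringence_window = win(cfg$birefringence_window,
                               birefringence_window()),
    filter = filter
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
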