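# S4B cellulose-stain assay: intensity profiles drawn perpendicular to the
# seed surface, integrated by the trapezoidal rule and expressed relative to
# the reference genotype.

# bilinear interpolation of a single channel at fractional (row, col),
# 0-based; returns NA outside the image
bilinear_at <- function(channel, row, col) {
  nr <- nrow(channel); nc <- ncol(channel)
  out <- rep(NA_real_, length(row))
  ok <- row >= 0 & row <= nr - 1 & col >= 0 & col <= nc - 1
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- channel[cbind(r0 + 1, c0 + 1)]
  i01 <- channel[cbind(r0 + 1, c0 + 2)]
  i10 <- channel[cbind(r0 + 2, c0 + 1)]
  i11 <- channel[cbind(r0 + 2, c0 + 2)]
  out[ok] <- i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
  out
}

#' Extract an intensity profile along a line
#'
#' Samples the chosen channel at unit steps along the line from `start` to
#' `end`, averaging `width_px` bilinear samples spaced 1 px along the
#' perpendicular at each step (ImageJ's wide-line Plot Profile). Samples
#' falling outside the image are dropped from the average with a warning.
#'
#' @param image An [rgb_image()].
#' @param start,end `(row, col)` endpoints, 0-based; must differ.
#' @param width_px Averaging width perpendicular to the line; the published
#'   macro used 200 (covering 4-5 epidermal cells).
#' @param channel Channel carrying the stain signal; S4B emission
#'   (600-650 nm) is imaged in red.
#' @return An `intensity_profile`: tibble with columns `position` (px from
#'   `start`) and `intensity`, plus attributes `width_px` and `auc`.
#' @export
extract_profile <- function(image, start, end, width_px = 200L,
                            channel = c("red", "green", "blue")) {
  stopifnot(inherits(image, "rgb_image"))
  channel <- match.arg(channel)
  ch <- image$pixels[, , match(channel, c("red", "green", "blue"))]
  storage.mode(ch) <- "double"
  dvec <- c(end[1] - start[1], end[2] - start[2])
  len <- sqrt(sum(dvec^2))
  if (len == 0) abort("degenerate profile line: start equals end.")
  u <- dvec / len                      # unit direction
  perp <- c(-u[2], u[1])               # unit perpendicular
  positions <- seq(0, floor(len))
  offs <- seq_len(width_px) - (width_px + 1) / 2  # centred, 1 px spacing
  n_out <- 0L
  intens <- vapply(positions, function(t) {
    rows <- start[1] + t * u[1] + offs * perp[1]
    cols <- start[2] + t * u[2] + offs * perp[2]
    v <- bilinear_at(ch, rows, cols)
    n_out <<- n_out + sum(is.na(v))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  if (n_out > 0L) {
    warn(sprintf("%d of %d width samples fell outside the image and were dropped",
                 n_out, length(positions) * width_px))
  }
  # positions whose whole width-band fell outside the image are dropped
  keep <- is.finite(intens)
  positions <- positions[keep]
  intens <- intens[keep]
  out <- new_intensity_profile(positions, intens, width_px)
  attr(out, "start") <- start
  attr(out, "end") <- end
  out
}

new_intensity_profile <- function(positions, intensities, width_px) {
  if (length(positions) < 2L) abort("a profile needs at least 2 samples.")
  if (is.unsorted(positions, strictly = TRUE))
    abort("`positions` must be strictly increasing.")
  out <- tibble(position = as.numeric(positions),
                intensity = as.numeric(intensities))
  attr(out, "width_px") <- width_px
  attr(out, "auc") <- trapezoid_auc(out)
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Trapezoidal area under an intensity profile
#'
#' Sum over consecutive sample pairs of the position step times the mean of
#' the two intensities. Exact for affine profiles.
#'
#' @param profile An `intensity_profile`, or any data frame with `position`
#'   and `intensity` columns.
#' @return The area (intensity x px).
#' @export
trapezoid_auc <- function(profile) {
  x <- profile$position
  y <- profile$intensity
  if (length(x) < 2L) abort("trapezoidal rule needs at least 2 samples.")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Place boundary-normal profiles automatically
#'
#' The published protocol drew profile lines by hand, perpendicular to the
#' seed surface. This helper places them deterministically: start points are
#' evenly spaced along the boundary of the largest particle in `seed_mask`
#' (ordered by polar angle around its centroid) and each profile runs
#' outward along the local radial direction.
#'
#' @param image An [rgb_image()].
#' @param seed_mask A `binary_mask` containing at least one particle.
#' @param n_profiles Number of profiles to place.
#' @param length_px Profile length in pixels.
#' @param width_px Averaging width (see [extract_profile()]).
#' @param channel Channel to sample.
#' @return List of `intensity_profile`s (possibly fewer than requested if
#'   the boundary is short, with a warning).
#' @export
auto_place_profiles <- function(image, seed_mask, n_profiles = 2L,
                                length_px = 100L, width_px = 200L,
                                channel = "red") {
  parts <- label_particles(seed_mask, fill_holes = TRUE)
  if (nrow(parts) == 0L) abort("`seed_mask` contains no particles.")
  main <- parts[which.max(parts$area_px), ]
  lab <- attr(parts, "labels")
  m <- lab == main$label
  # boundary pixels: foreground with at least one 4-neighbor background
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- which(core & !nb, arr.ind = TRUE)
  if (nrow(boundary) < n_profiles) {
    warn(sprintf("boundary has %d pixels; placing %d profiles instead of %d",
                 nrow(boundary), nrow(boundary), n_profiles))
    n_profiles <- nrow(boundary)
  }
  ctr <- c(main$centroid_row, main$centroid_col)
  brow <- boundary[, 1] - 1; bcol <- boundary[, 2] - 1  # 0-based
  ang <- atan2(brow - ctr[1], bcol - ctr[2])
  ord <- order(ang)
  idx <- ord[floor(seq(1, length(ord), length.out = n_profiles + 1L))[-(n_profiles + 1L)]]
  lapply(idx, function(i) {
    dir <- c(brow[i] - ctr[1], bcol[i] - ctr[2])
    dir <- dir / sqrt(sum(dir^2))
    start <- c(brow[i], bcol[i])
    extract_profile(image, start, start + length_px * dir,
                    width_px = width_px, channel = channel)
  })
}

#' Relative S4B intensity
#'
#' Mean profile area under the curve of the sample divided by the mean for
#' the reference genotype.
#'
#' @param sample_profiles,reference_profiles Non-empty lists of
#'   `intensity_profile`s (or of precomputed AUC numbers).
#' @return A single ratio; the reference against itself gives 1.
#' @export
relative_s4b_intensity <- function(sample_profiles, reference_profiles) {
  auc_of <- function(p) if (is.numeric(p)) p else trapezoid_auc(p)
  if (length(sample_profiles) == 0L || length(reference_profiles) == 0L)
    abort("both profile sets must be non-empty.")
  ref <- mean(vapply(reference_profiles, auc_of, numeric(1)))
  if (ref == 0) abort("reference mean AUC is zero; cannot normalize.")
  mean(vapply(sample_profiles, auc_of, numeric(1))) / ref
}

#' Align profiles to their maximum peak by cross-correlation shift
#'
#' Before group averaging, profiles can be shifted so their global maxima
#' coincide (the manual alignment step of the original workflow). Positions
#' are re-expressed relative to each profile's peak.
#'
#' @param profiles List of `intensity_profile`s.
#' @return List of profiles with shifted `position` columns.
#' @export
align_profiles <- function(profiles) {
  lapply(profiles, function(p) {
    peak <- p$position[which.max(p$intensity)]
    new_intensity_profile(p$position - peak, p$intensity,
                          attr(p, "width_px") %||% NA_integer_)
  })
}

#' Subtract a constant background from a profile
#'
#' AUCs are computed on raw intensities by default; where a dark-current or
#' autofluorescence baseline should be removed first, subtract it here
#' (clamped at zero) before integrating.
#'
#' @param profile An `intensity_profile`.
#' @param background Constant intensity to subtract.
#' @return A new `intensity_profile`.
#' @export
subtract_background <- function(profile, background) {
  new_intensity_profile(profile$position,
                        pmax(profile$intensity - background, 0),
                        attr(profile, "width_px"))
}

#' Plot an intensity profile
#'
#' @param object An `intensity_profile`.
#' @param ... Unused.
#' @return A ggplot of intensity against distance from the seed surface.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from seed surface (px)",
                  y = "Mean intensity",
                  subtitle = sprintf("AUC = %.1f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}
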