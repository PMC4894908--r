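# Polarized-light birefringence assay: total bright crystalline area per
# image, divided by a manual seed count, normalized to the reference.

#' Measure birefringent area per seed
#'
#' Segments bright crystalline regions with the polarized-light threshold
#' window, labels particles with holes included, and sums all particle
#' areas — no circularity or size filter and no edge exclusion, unlike the
#' capsule assay. The total is divided by the number of seeds in the image
#' (counted manually in the original protocol).
#'
#' @param image An [rgb_image()] taken under plane polarized light.
#' @param window A [threshold_window()]; default [birefringence_window()].
#' @param n_seeds Number of seeds in the field (>= 1). Counts below 8 are
#'   flagged `low_count`.
#' @param batch Optional label for the imaging day.
#' @return A `birefringence_result`: list with `total_bright_area_um2`,
#'   `n_seeds`, `area_per_seed_um2`, `low_count`, `batch`.
#' @export
measure_birefringence <- function(image, window = birefringence_window(),
                                  n_seeds, batch = NA_character_) {
  if (missing(n_seeds) || length(n_seeds) != 1L || is.na(n_seeds) ||
      n_seeds < 1) {
    abort("`n_seeds` must be a count >= 1 (manually counted seeds).")
  }
  parts <- label_particles(segment_by_window(image, window), fill_holes = TRUE)
  total <- sum(parts$area_um2)
  structure(
    list(
      total_bright_area_um2 = total,
      n_seeds = as.integer(n_seeds),
      area_per_seed_um2 = total / n_seeds,
      low_count = n_seeds < 8L,
      batch = batch
    ),
    class = "birefringence_result"
  )
}

#' @export
print.birefringence_result <- function(x, ...) {
  cat(sprintf("<birefringence_result> %.0f um^2 over %d seeds = %.1f um^2/seed%s\n",
              x$total_bright_area_um2, x$n_seeds, x$area_per_seed_um2,
              if (x$low_count) " (low count, <8)" else ""))
  invisible(x)
}

#' @export
tidy.birefringence_result <- function(x, ...) {
  tibble(batch = x$batch, total_bright_area_um2 = x$total_bright_area_um2,
         n_seeds = x$n_seeds, area_per_seed_um2 = x$area_per_seed_um2,
         low_count = x$low_count)
}

#' Mean birefringence per seed across imaging batches
#'
#' Averages `area_per_seed` over batches (seed sets imaged on different
#' days), optionally normalizing by the same statistic computed for the
#' reference genotype.
#'
#' @param results List of `birefringence_result`s (or numeric
#'   area-per-seed values) for one genotype.
#' @param reference_results Optional list for the reference genotype; when
#'   supplied the return value is relative to the reference.
#' @return Mean area per seed, or the reference-relative ratio.
#' @export
batch_mean_birefringence <- function(results, reference_results = NULL) {
  aps <- function(r) if (is.numeric(r)) r else r$area_per_seed_um2
  if (length(results) == 0L) abort("`results` must be non-empty.")
  m <- mean(vapply(results, aps, numeric(1)))
  if (is.null(reference_results)) return(m)
  ref <- mean(vapply(reference_results, aps, numeric(1)))
  if (ref == 0) abort("reference birefringence is zero; cannot normalize.")
  m / ref
}

#' Count dark seed bodies in a polarized-light image
#'
#' The original protocol counts seeds by eye. For synthetic images this
#' helper counts them automatically by segmenting dark ellipsoidal seed
#' bodies with an inverted window and filtering for large round particles.
#'
#' @param image An [rgb_image()].
#' @param dark_max Upper intensity bound applied to all three channels.
#' @param min_area_px Minimum particle area to count as a seed.
#' @return Integer seed count.
#' @export
count_seed_bodies <- function(image, dark_max = 50L, min_area_px = 50L) {
  win <- threshold_window(red = c(0, dark_max), green = c(0, dark_max),
                          blue = c(0, dark_max))
  parts <- label_particles(segment_by_window(image, win), fill_holes = TRUE)
  sum(parts$area_px >= min_area_px)
}
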