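# Ruthenium-red capsule assay: mucilage area per seed as the difference
# between the capsule (mucilage + seed) particle and the seed particle that
# it encloses.

#' Measure ruthenium-red stained mucilage capsules in a well image
#'
#' Segments the image twice — once with the capsule window (mucilage plus
#' seed) and once with the seed window — labels both masks with holes
#' filled, applies the particle filter to each, then pairs every retained
#' seed with the capsule particle whose filled region contains the seed
#' centroid. Per-seed mucilage area is capsule area minus seed area.
#'
#' @param image An [rgb_image()] of a stained well.
#' @param capsule_window,seed_window [threshold_window()]s; defaults are the
#'   calibrated macro windows ([rr_capsule_window()], [rr_seed_window()]).
#' @param filter A [particle_filter()]; default keeps circularity 0.5-1.0,
#'   excludes edge-touching particles and extreme sizes.
#' @param genotype,replicate Labels carried into the result.
#' @return An `rr_well` object: a list with `seeds` (tibble of per-seed
#'   measurements: `seed_id`, `seed_area_um2`, `capsule_area_um2`,
#'   `mucilage_area_um2`, `seed_centroid_row`, `seed_centroid_col`),
#'   `n_seeds`, `mean_mucilage_area_um2`, `mean_seed_area_um2`,
#'   `low_count` (fewer than 10 paired seeds), `n_unpaired` and the labels.
#' @export
measure_rr_well <- function(image,
                            capsule_window = rr_capsule_window(),
                            seed_window = rr_seed_window(),
                            filter = particle_filter(),
                            genotype = NA_character_,
                            replicate = NA_character_) {
  caps <- apply_filter(label_particles(segment_by_window(image, capsule_window),
                                       fill_holes = TRUE), filter)
  seeds <- apply_filter(label_particles(segment_by_window(image, seed_window),
                                        fill_holes = TRUE), filter)
  if (nrow(caps) == 0L || nrow(seeds) == 0L) {
    abort(sprintf(
      "no paired seeds: %d capsule and %d seed particles after filtering",
      nrow(caps), nrow(seeds)))
  }
  cap_labels <- attr(caps, "labels")
  # capsule label under each seed centroid (labels matrix is hole-filled)
  ri <- round(seeds$centroid_row) + 1L
  ci <- round(seeds$centroid_col) + 1L
  cap_at <- cap_labels[cbind(ri, ci)]
  paired <- cap_at %in% caps$label
  n_unpaired <- sum(!paired)
  if (!any(paired)) {
    abort(sprintf(
      "no paired seeds: %d capsule and %d seed particles after filtering",
      nrow(caps), nrow(seeds)))
  }
  sm <- seeds[paired, , drop = FALSE]
  cap_row <- match(cap_at[paired], caps$label)
  muc <- pmax(caps$area_um2[cap_row] - sm$area_um2, 0)
  if (any(caps$area_um2[cap_row] < sm$area_um2)) {
    warn("capsule area below seed area for some pairs; mucilage clamped at 0")
  }
  out <- tibble(
    seed_id = seq_len(nrow(sm)),
    seed_area_um2 = sm$area_um2,
    capsule_area_um2 = caps$area_um2[cap_row],
    mucilage_area_um2 = muc,
    seed_centroid_row = sm$centroid_row,
    seed_centroid_col = sm$centroid_col
  )
  structure(
    list(
      genotype = genotype, replicate = replicate,
      seeds = out, n_seeds = nrow(out),
      mean_mucilage_area_um2 = mean(out$mucilage_area_um2),
      mean_seed_area_um2 = mean(out$seed_area_um2),
      low_count = nrow(out) < 10L,
      n_unpaired = n_unpaired
    ),
    class = "rr_well"
  )
}

#' @export
print.rr_well <- function(x, ...) {
  cat(sprintf(
    "<rr_well> %s/%s: %d seeds%s, mean mucilage %.0f um^2, mean seed %.0f um^2\n",
    x$genotype, x$replicate, x$n_seeds,
    if (x$low_count) " (low count, <10)" else "",
    x$mean_mucilage_area_um2, x$mean_seed_area_um2))
  invisible(x)
}

#' Tidy per-seed measurements of a well
#'
#' @param x An `rr_well`.
#' @param ... Unused.
#' @return The per-seed tibble with genotype and replicate columns.
#' @export
tidy.rr_well <- function(x, ...) {
  dplyr::mutate(x$seeds, genotype = x$genotype, replicate = x$replicate,
                .before = 1)
}

#' One-row well summary
#'
#' @param x An `rr_well`.
#' @param ... Unused.
#' @return A one-row tibble with seed count, means and the low-count flag.
#' @export
glance.rr_well <- function(x, ...) {
  tibble(
    genotype = x$genotype, replicate = x$replicate, n_seeds = x$n_seeds,
    mean_mucilage_area_um2 = x$mean_mucilage_area_um2,
    mean_seed_area_um2 = x$mean_seed_area_um2,
    low_count = x$low_count, n_unpaired = x$n_unpaired
  )
}

#' Semi-quantitative mucilage capsule score
#'
#' Maps the ratio of a genotype's mean capsule (mucilage) area to the
#' reference genotype's area onto the five-point vocabulary used as a GWAS
#' phenotype: larger (1.2), similar (1.0), partly smaller (0.8), moderately
#' smaller (0.6), very small (0.4). Bin edges are the midpoints between the
#' printed scores: ratio >= 1.1 scores 1.2; \[0.9, 1.1) scores 1.0;
#' \[0.7, 0.9) scores 0.8; \[0.5, 0.7) scores 0.6; below 0.5 scores 0.4.
#'
#' @param mean_mucilage_area Per-genotype mean mucilage area (same units as
#'   the reference).
#' @param reference_area Reference-genotype mean mucilage area (> 0).
#' @return The score(s), in \{1.2, 1.0, 0.8, 0.6, 0.4\}.
#' @export
score_capsule_ratio <- function(mean_mucilage_area, reference_area) {
  if (any(reference_area <= 0)) abort("`reference_area` must be positive.")
  ratio <- mean_mucilage_area / reference_area
  edges <- c(-Inf, 0.5, 0.7, 0.9, 1.1, Inf)
  scores <- c(0.4, 0.6, 0.8, 1.0, 1.2)
  scores[findInterval(ratio, edges, left.open = FALSE)]
}
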