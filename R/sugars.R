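# HPAEC-PAD monosaccharide workflow: ribose internal-standard correction,
# conversion to ug per mg seed, per-batch reference normalization, and
# glucose-contamination flagging.

#' The nine quantified monosaccharides
#'
#' Fucose, rhamnose, arabinose, galactose, glucose, xylose, mannose,
#' galacturonic acid, glucuronic acid — the sugar mixture used for HPAEC-PAD
#' calibration.
#' @return Character vector of column names.
#' @export
sugar_names <- function() {
  c("Fuc", "Rha", "Ara", "Gal", "Glc", "Xyl", "Man", "GalA", "GlcA")
}

check_sugar_table <- function(table) {
  need <- c("sample", "genotype", "batch", sugar_names(), "ribose_measured")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(paste0("sugar table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(as.matrix(table[sugar_names()]) < 0, na.rm = TRUE))
    abort("sugar amounts must be non-negative.")
  invisible(table)
}

#' Correct sugar amounts by the ribose internal standard
#'
#' Each extraction receives a known mass of ribose before mixing (30 ug in
#' 1 mL of water under the published protocol), of which a fixed aliquot
#' fraction (800 uL of 1 mL, i.e. 0.8) is carried through hydrolysis.
#' Measured sugar amounts are multiplied by (expected ribose in the
#' aliquot) / (measured ribose), which cancels sample-specific recovery
#' losses. Samples with non-positive measured ribose are dropped with a
#' warning.
#'
#' @param table Data frame with columns `sample`, `genotype`, `batch`, the
#'   nine sugars ([sugar_names()], ug in the injected eluate) and
#'   `ribose_measured` (ug).
#' @param ribose_added_ug Ribose spiked into the full extraction volume.
#' @param aliquot_fraction Fraction of the extract carried forward
#'   (defaults to the column `aliquot_fraction` if present, else 0.8).
#' @return The table with sugar columns corrected and a
#'   `ribose_correction` column appended.
#' @export
internal_standard_correct <- function(table, ribose_added_ug = 30,
                                      aliquot_fraction = NULL) {
  check_sugar_table(table)
  table <- tibble::as_tibble(table)
  af <- aliquot_fraction %||% table[["aliquot_fraction"]] %||% 0.8
  if (any(af <= 0 | af > 1)) abort("`aliquot_fraction` must be in (0, 1].")
  bad <- table$ribose_measured <= 0 | is.na(table$ribose_measured)
  if (any(bad)) {
    warn(sprintf("dropping %d sample(s) with non-positive measured ribose: %s",
                 sum(bad), paste(table$sample[bad], collapse = ", ")))
    table <- table[!bad, , drop = FALSE]
    if (length(af) > 1L) af <- af[!bad]
  }
  expected <- ribose_added_ug * af
  factor <- expected / table$ribose_measured
  table <- dplyr::mutate(
    table,
    dplyr::across(dplyr::all_of(sugar_names()), ~ .x * factor),
    ribose_correction = factor
  )
  if (is.null(table[["aliquot_fraction"]])) table$aliquot_fraction <- af
  table
}

#' Convert corrected aliquot amounts to ug per mg seed
#'
#' The aliquot contains `aliquot_fraction` of the sugars extracted from
#' `seed_mass_mg` of seeds (5 mg under the published protocol), so the
#' per-seed-mass amount is the corrected aliquot amount divided by the
#' aliquot fraction and the seed mass.
#'
#' @param corrected Output of [internal_standard_correct()].
#' @param seed_mass_mg Seed mass per extraction (defaults to a
#'   `seed_mass_mg` column if present, else 5).
#' @return Tibble with sugar columns in ug per mg seed and a
#'   `total_mucilage` column (sum over the nine sugars).
#' @export
to_ug_per_mg_seed <- function(corrected, seed_mass_mg = NULL) {
  check_sugar_table(corrected)
  sm <- seed_mass_mg %||% corrected[["seed_mass_mg"]] %||% 5
  if (any(sm <= 0)) abort("`seed_mass_mg` must be positive.")
  af <- corrected[["aliquot_fraction"]] %||% 0.8
  out <- dplyr::mutate(
    tibble::as_tibble(corrected),
    dplyr::across(dplyr::all_of(sugar_names()), ~ .x / af / sm)
  )
  out$total_mucilage <- rowSums(out[sugar_names()])
  out
}

#' Normalize each batch to its own reference-genotype extracts
#'
#' Reference extracts are prepared alongside every batch; each genotype x
#' sugar value is divided by the arithmetic mean of the reference samples
#' in the same batch, cancelling between-batch drift. The reference's own
#' per-batch relative value is 1 by construction.
#'
#' @param comp Per-mg composition from [to_ug_per_mg_seed()]; columns
#'   `sample`, `genotype`, `batch`, the nine sugars and `total_mucilage`.
#' @param reference_genotype Reference label (e.g. `"Col-0"`).
#' @return Tibble of per-sample relative values (reference mean of the same
#'   batch = 1) for the nine sugars and `total_mucilage`.
#' @export
batch_relative_to_reference <- function(comp, reference_genotype = "Col-0") {
  cols <- c(sugar_names(), "total_mucilage")
  cols <- intersect(cols, names(comp))
  batches <- unique(comp$batch)
  missing_ref <- batches[!vapply(batches, function(b) {
    any(comp$genotype == reference_genotype & comp$batch == b)
  }, logical(1))]
  if (length(missing_ref)) {
    abort(paste0("batch(es) without reference '", reference_genotype, "': ",
                 paste(missing_ref, collapse = ", ")))
  }
  ref_means <- comp |>
    dplyr::filter(.data$genotype == reference_genotype) |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  out <- dplyr::left_join(
    tibble::as_tibble(comp), ref_means,
    by = "batch", suffix = c("", "..ref")
  )
  for (cl in cols) {
    ref <- out[[paste0(cl, "..ref")]]
    out[[cl]] <- ifelse(ref > 0, out[[cl]] / ref,
                        ifelse(out[[cl]] == 0, 1, NA_real_))
    out[[paste0(cl, "..ref")]] <- NULL
  }
  out
}

#' Flag inconsistent glucose spikes
#'
#' Mucilage extraction can pick up free-glucose contamination that is not a
#' mucilage polysaccharide signal: within-genotype replicate variation of
#' Glc far above that of the other sugars. A genotype is flagged when the
#' coefficient of variation (sd/mean) of its Glc replicates exceeds
#' `cv_threshold` (default 0.4); an individual sample is spike-flagged when
#' its Glc is at least `spike_fold` (default 5) times the reference mean.
#'
#' @param comp Per-mg composition (absolute, not reference-relative), with
#'   `genotype` and `Glc` columns.
#' @param reference_genotype Reference label for the spike-fold comparison.
#' @param cv_threshold CV above which a genotype is flagged.
#' @param spike_fold Per-sample fold over the reference Glc mean.
#' @return List with `genotypes` (tibble: `genotype`, `glc_cv`,
#'   `glc_spike`; CV is `NA` and the flag `NA` with a single replicate) and
#'   `samples` (tibble: `sample`, `genotype`, `Glc`, `spike_flag`).
#' @export
flag_glc_spikes <- function(comp, reference_genotype = "Col-0",
                            cv_threshold = 0.4, spike_fold = 5) {
  gt <- comp |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      glc_cv = ifelse(dplyr::n() >= 2L & mean(.data$Glc) > 0,
                      stats::sd(.data$Glc) / mean(.data$Glc), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(glc_spike = .data$glc_cv > cv_threshold)
  ref_mean <- mean(comp$Glc[comp$genotype == reference_genotype])
  smp <- tibble(
    sample = comp$sample, genotype = comp$genotype, Glc = comp$Glc,
    spike_flag = comp$Glc >= spike_fold * ref_mean
  )
  list(genotypes = gt[, c("genotype", "glc_cv", "glc_spike")], samples = smp)
}

#' Welch t-test of a trait against the reference
#'
#' Per-trait significance as used for the phenotype heatmap: a two-sample
#' unequal-variance t-test at the raw 0.05 level, no multiplicity
#' correction (optionally Holm-adjust across a family of traits with
#' [adjust_trait_pvalues()]).
#'
#' @param values_sample,values_reference Replicate values (>= 2 each).
#' @param alpha Significance level.
#' @return List with `p_value`, `significant`, `estimate` (mean
#'   difference). With fewer than 2 replicates on either side, `p_value`
#'   is `NA` and `significant` is `NA`.
#' @export
trait_ttest <- function(values_sample, values_reference, alpha = 0.05) {
  if (length(values_sample) < 2L || length(values_reference) < 2L) {
    return(list(p_value = NA_real_, significant = NA, estimate = NA_real_))
  }
  if (stats::sd(values_sample) == 0 && stats::sd(values_reference) == 0) {
    same <- isTRUE(all.equal(mean(values_sample), mean(values_reference)))
    return(list(p_value = if (same) 1 else 0, significant = !same,
                estimate = mean(values_sample) - mean(values_reference)))
  }
  tt <- stats::t.test(values_sample, values_reference, var.equal = FALSE)
  list(p_value = tt$p.value, significant = tt$p.value < alpha,
       estimate = unname(diff(rev(tt$estimate))))
}

#' Holm-adjust a vector of trait p-values
#'
#' @param p Numeric p-values.
#' @return Adjusted p-values (Holm step-down).
#' @export
adjust_trait_pvalues <- function(p) stats::p.adjust(p, method = "holm")
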