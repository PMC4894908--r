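# End-to-end cohort pipeline: generate (or accept) assay data for every
# genotype, run the four assays, assemble reference-relative phenotype
# vectors, classify, and write deterministic CSV outputs.

#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' For each genotype in the cohort: generates ruthenium-red well images
#' (one per biological replicate) and measures capsule areas; generates two
#' S4B fields (two sets of epidermal cells, as in the emulated protocol)
#' and profiles them; generates two polarized-light fields (two imaging
#' batches) and measures birefringence; generates the cohort sugar and Cq
#' tables and runs the composition and expression workflows. Traits are
#' expressed relative to the cohort's reference genotype, tested per trait
#' (Welch t-test, P < 0.05), assembled into phenotype vectors and
#' classified.
#'
#' All randomness derives from `spec$rng_seed` through per-genotype,
#' per-assay stream seeds, so two runs with the same spec produce
#' byte-identical CSV outputs.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, writes `rr_wells.csv`,
#'   `rr_seeds.csv`, `s4b.csv`, `birefringence.csv`,
#'   `composition_relative.csv`, `qpcr_folds.csv`, `phenotypes.csv`,
#'   `classes.csv` and `gwas_scores.csv`.
#' @param s4b_image_size,s4b_seed_radius_px,s4b_profile_length_px,s4b_width_px
#'   Geometry of the S4B fields and profiles.
#' @param biref_image_size,biref_n_seeds Geometry of the birefringence
#'   fields.
#' @param n_profiles Profiles per S4B field.
#' @return A `cohort_result` list: `phenotypes` (classified
#'   `phenotype_vector`s), `tables` (the per-assay tibbles), and
#'   `gwas_scores`.
#' @export
run_cohort_pipeline <- function(spec, out_dir = NULL,
                                s4b_image_size = 512L,
                                s4b_seed_radius_px = 110,
                                s4b_profile_length_px = 120L,
                                s4b_width_px = 40L,
                                n_profiles = 3L,
                                biref_image_size = 512L,
                                biref_n_seeds = 10L) {
  stopifnot(inherits(spec, "cohort_spec"))
  ref_name <- spec$reference_genotype
  gnames <- names(spec$genotypes)

  # ---- ruthenium-red capsules ----
  rr_wells <- purrr::map_dfr(spec$genotypes, function(g) {
    purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
      gen <- generate_rr_image(
        g, rng_seed = derive_seed(spec$rng_seed, g$name, "rr") + r,
        image_size = spec$image_size, pixel_size = spec$pixel_size,
        noise_sd = spec$noise_sd)
      glance.rr_well(measure_rr_well(gen$image, genotype = g$name,
                                     replicate = paste0("rep", r)))
    })
  })
  rr_by_gt <- rr_wells |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      mucilage = mean(.data$mean_mucilage_area_um2),
      seed = mean(.data$mean_seed_area_um2), .groups = "drop")
  ref_rr <- rr_by_gt[rr_by_gt$genotype == ref_name, ]

  # ---- S4B profiles (two sets per genotype) ----
  s4b_sets <- purrr::map(stats::setNames(gnames, gnames), function(nm) {
    g <- spec$genotypes[[nm]]
    vapply(1:2, function(s) {
      gen <- generate_s4b_image(
        g, rng_seed = derive_seed(spec$rng_seed, nm, "s4b") + s,
        image_size = s4b_image_size, seed_radius_px = s4b_seed_radius_px)
      profs <- auto_place_profiles(gen$image, gen$seed_mask,
                                   n_profiles = n_profiles,
                                   length_px = s4b_profile_length_px,
                                   width_px = s4b_width_px)
      mean(vapply(profs, trapezoid_auc, numeric(1)))
    }, numeric(1))
  })
  s4b_tab <- purrr::imap_dfr(s4b_sets, function(aucs, nm) {
    tibble(genotype = nm, set = 1:2, mean_auc = aucs)
  })

  # ---- birefringence (two imaging batches per genotype) ----
  biref_sets <- purrr::map(stats::setNames(gnames, gnames), function(nm) {
    g <- spec$genotypes[[nm]]
    vapply(1:2, function(b) {
      gen <- generate_birefringence_image(
        g, rng_seed = derive_seed(spec$rng_seed, nm, "biref") + b,
        image_size = biref_image_size, n_seeds = biref_n_seeds)
      measure_birefringence(gen$image, n_seeds = gen$truth$n_seeds,
                            batch = paste0("day", b))$area_per_seed_um2
    }, numeric(1))
  })
  biref_tab <- purrr::imap_dfr(biref_sets, function(aps, nm) {
    tibble(genotype = nm, batch = paste0("day", 1:2), area_per_seed_um2 = aps)
  })

  # ---- monosaccharide composition ----
  sugars <- generate_sugar_table(spec)
  comp <- sugars$table |>
    internal_standard_correct() |>
    to_ug_per_mg_seed()
  rel <- batch_relative_to_reference(comp, ref_name)
  sugar_cols <- c("Rha", "GalA", "Gal", "Glc", "Man", "Xyl", "total_mucilage")

  # ---- qPCR ----
  cqs <- generate_cq_table(spec)
  folds <- fold_change(cqs$table, cqs$efficiencies, target = "MUCI10",
                       control_genotype = ref_name)
  fold_summary <- summarize_fold_changes(folds, control_genotype = ref_name)

  # ---- assemble reference-relative vectors ----
  vectors <- purrr::map(stats::setNames(gnames, gnames), function(nm) {
    traits <- c(
      mucilage_area = rr_by_gt$mucilage[rr_by_gt$genotype == nm] /
        ref_rr$mucilage,
      seed_area = rr_by_gt$seed[rr_by_gt$genotype == nm] / ref_rr$seed,
      s4b_intensity = mean(s4b_sets[[nm]]) / mean(s4b_sets[[ref_name]]),
      birefringence = mean(biref_sets[[nm]]) / mean(biref_sets[[ref_name]])
    )
    sig <- c(
      mucilage_area = isTRUE(trait_ttest(
        rr_wells$mean_mucilage_area_um2[rr_wells$genotype == nm],
        rr_wells$mean_mucilage_area_um2[rr_wells$genotype == ref_name]
      )$significant),
      seed_area = isTRUE(trait_ttest(
        rr_wells$mean_seed_area_um2[rr_wells$genotype == nm],
        rr_wells$mean_seed_area_um2[rr_wells$genotype == ref_name]
      )$significant),
      s4b_intensity = isTRUE(trait_ttest(
        s4b_sets[[nm]], s4b_sets[[ref_name]])$significant),
      birefringence = isTRUE(trait_ttest(
        biref_sets[[nm]], biref_sets[[ref_name]])$significant)
    )
    for (sc in sugar_cols) {
      smp <- rel[[sc]][rel$genotype == nm]
      rf <- rel[[sc]][rel$genotype == ref_name]
      traits[sc] <- mean(smp)
      sig[sc] <- isTRUE(trait_ttest(smp, rf)$significant)
    }
    assign_class(assemble_vector(nm, traits, sig,
                                 reference_genotype = ref_name))
  })

  scores <- export_gwas_scores(unname(vectors))
  pheno_tab <- phenotype_table(unname(vectors))
  class_tab <- pheno_tab |>
    dplyr::distinct(.data$genotype, .data$class_label)

  result <- structure(
    list(
      phenotypes = vectors,
      gwas_scores = scores,
      tables = list(
        rr_wells = rr_wells, s4b = s4b_tab, birefringence = biref_tab,
        composition_relative = rel, qpcr_folds = folds,
        qpcr_summary = fold_summary, phenotypes = pheno_tab,
        classes = class_tab
      )
    ),
    class = "cohort_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    wr(rr_wells, "rr_wells.csv")
    wr(s4b_tab, "s4b.csv")
    wr(biref_tab, "birefringence.csv")
    wr(rel, "composition_relative.csv")
    wr(folds, "qpcr_folds.csv")
    wr(pheno_tab, "phenotypes.csv")
    wr(class_tab, "classes.csv")
    wr(scores, "gwas_scores.csv")
  }
  result
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  print(x$tables$classes)
  invisible(x)
}
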