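# Reference-relative phenotype vectors, the five mucilage classes, and the
# heatmap / GWAS-score exports.

phenotype_trait_names <- function() {
  c("mucilage_area", "seed_area", "s4b_intensity", "birefringence",
    "Rha", "GalA", "Gal", "Glc", "Man", "Xyl", "total_mucilage")
}

#' Assemble a per-genotype phenotype vector
#'
#' Collects reference-relative trait values from the four assays into one
#' vector per genotype (reference = 1.0 for every trait). Missing assays
#' are recorded as absent (`NA`), never as zero.
#'
#' @param genotype Genotype label.
#' @param traits Named numeric vector of relative trait values; recognized
#'   names are `mucilage_area`, `seed_area`, `s4b_intensity`,
#'   `birefringence`, the sugars `Rha`, `GalA`, `Gal`, `Glc`, `Man`, `Xyl`,
#'   and `total_mucilage`.
#' @param significance Named logical vector: is the trait significantly
#'   different from the reference (t-test, P < 0.05)? Traits without an
#'   entry are treated as not significant.
#' @param reference_genotype The reference label; the reference genotype is
#'   forced to all-ones and class `reference-like`.
#' @return A `phenotype_vector`: list with `genotype`, `traits`,
#'   `significance` and `class_label` (assigned lazily by
#'   [assign_class()]).
#' @export
assemble_vector <- function(genotype, traits, significance = logical(),
                            reference_genotype = "Col-0") {
  known <- phenotype_trait_names()
  bad <- setdiff(names(traits), known)
  if (length(bad))
    abort(paste0("unknown trait(s): ", paste(bad, collapse = ", ")))
  if (any(traits < 0, na.rm = TRUE))
    abort("relative trait values must be >= 0.")
  tr <- stats::setNames(rep(NA_real_, length(known)), known)
  tr[names(traits)] <- as.numeric(traits)
  sg <- stats::setNames(rep(FALSE, length(known)), known)
  sg[names(significance)] <- as.logical(significance)
  if (identical(genotype, reference_genotype)) {
    tr[] <- 1.0
    sg[] <- FALSE
  }
  structure(
    list(genotype = genotype, traits = tr, significance = sg,
         class_label = NA_character_,
         reference_genotype = reference_genotype),
    class = "phenotype_vector"
  )
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("<phenotype_vector> %s (class %s)\n", x$genotype,
              ifelse(is.na(x$class_label), "unassigned", x$class_label)))
  tv <- x$traits[!is.na(x$traits)]
  cat(paste0("  ", names(tv), " = ", signif(tv, 3),
             ifelse(x$significance[names(tv)], " *", ""), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Default class-rule thresholds
#'
#' Numeric boundaries for the five mucilage classes. The published
#' classification is descriptive; these defaults anchor it: class B needs
#' at least 40% less Gal and/or Man (`gal_man_low = 0.6`); class A pairs
#' significantly larger seeds with roughly half the pectin
#' (`total_mucilage_low = 0.55`); "severely disrupted mucilage properties"
#' is S4B at or below 0.55 or birefringence at or below 0.2; "minor
#' reductions or no change" in birefringence is 0.45 or above; vectors
#' within `reference_band` of 1.0 on every measured trait count as
#' reference-like.
#'
#' @return Named list of thresholds.
#' @export
class_rule_defaults <- function() {
  list(
    total_mucilage_low = 0.55,  # class A: about half as much pectin
    gal_man_low = 0.6,          # class B: >= 40% less Gal and/or Man
    s4b_low = 0.55,             # class C: severely reduced S4B
    birefringence_low = 0.2,    # classes C/D: almost no birefringence
    birefringence_normal = 0.45,# class E: minor reduction or no change
    reference_band = 0.1
  )
}

#' Assign one of the five mucilage phenotype classes
#'
#' Ordered rules (first match wins), mirroring the five published classes:
#' \describe{
#'   \item{A}{significantly larger seeds with `total_mucilage` at or below
#'     `total_mucilage_low` (the "large seeds, half the pectin" profile).}
#'   \item{D}{significantly more Man *and* Gal, with birefringence at or
#'     below `birefringence_low`.}
#'   \item{E}{significantly more Man, Gal not increased, birefringence at
#'     or above `birefringence_normal` despite reduced S4B.}
#'   \item{B}{Gal or Man at or below `gal_man_low` (the GGM-deficient,
#'     muci10-like profile).}
#'   \item{C}{Gal and Man within (`gal_man_low`, 1\] but S4B at or below
#'     `s4b_low` or birefringence at or below `birefringence_low`.}
#' }
#' A vector matching no rule is `reference-like` when every measured trait
#' lies within `reference_band` of 1.0, otherwise `unclassified`.
#'
#' @param vector A `phenotype_vector`.
#' @param thresholds See [class_rule_defaults()].
#' @return The vector with `class_label` filled in.
#' @export
assign_class <- function(vector, thresholds = class_rule_defaults()) {
  stopifnot(inherits(vector, "phenotype_vector"))
  th <- utils::modifyList(class_rule_defaults(), thresholds)
  tr <- vector$traits
  sg <- vector$significance
  need <- c("Gal", "Man", "seed_area", "total_mucilage", "s4b_intensity",
            "birefringence")
  if (anyNA(tr[need])) {
    vector$class_label <- "unclassified"
    vector$class_reason <- paste0("missing trait(s): ",
                                  paste(need[is.na(tr[need])], collapse = ", "))
    return(vector)
  }
  sig_up <- function(trait) isTRUE(sg[[trait]]) && tr[[trait]] > 1
  label <- if (sig_up("seed_area") && tr[["total_mucilage"]] <= th$total_mucilage_low) {
    "A"
  } else if (sig_up("Man") && sig_up("Gal") &&
             tr[["birefringence"]] <= th$birefringence_low) {
    "D"
  } else if (sig_up("Man") && !sig_up("Gal") &&
             tr[["birefringence"]] >= th$birefringence_normal) {
    "E"
  } else if (tr[["Gal"]] <= th$gal_man_low || tr[["Man"]] <= th$gal_man_low) {
    "B"
  } else if (tr[["Gal"]] <= 1 && tr[["Man"]] <= 1 &&
             (tr[["s4b_intensity"]] <= th$s4b_low ||
              tr[["birefringence"]] <= th$birefringence_low)) {
    "C"
  } else {
    measured <- tr[!is.na(tr)]
    if (all(abs(measured - 1) <= th$reference_band)) "reference-like"
    else "unclassified"
  }
  vector$class_label <- label
  vector
}

#' Phenotype vectors as a tidy table
#'
#' @param x A list of `phenotype_vector`s (or a single one).
#' @param ... Unused.
#' @return Tibble with `genotype`, `trait`, `relative_value`,
#'   `significant`, `class_label`.
#' @export
tidy.phenotype_vector <- function(x, ...) {
  tibble(
    genotype = x$genotype,
    trait = names(x$traits),
    relative_value = unname(x$traits),
    significant = unname(x$significance),
    class_label = x$class_label
  )
}

#' Combine phenotype vectors into one tidy table
#'
#' @param vectors List of `phenotype_vector`s.
#' @return Long tibble, one row per genotype x trait.
#' @export
phenotype_table <- function(vectors) {
  if (inherits(vectors, "phenotype_vector")) vectors <- list(vectors)
  purrr::map_dfr(vectors, tidy.phenotype_vector)
}

#' Export semi-quantitative GWAS phenotype scores
#'
#' Maps each genotype's relative mucilage capsule area onto the five-point
#' score of [score_capsule_ratio()], yielding a two-column accession/score
#' table usable as a GWAS phenotype file.
#'
#' @param vectors List of `phenotype_vector`s with the `mucilage_area`
#'   trait present.
#' @param path Optional CSV output path.
#' @return Tibble with `accession` and `score`.
#' @export
export_gwas_scores <- function(vectors, path = NULL) {
  if (inherits(vectors, "phenotype_vector")) vectors <- list(vectors)
  rel <- vapply(vectors, function(v) v$traits[["mucilage_area"]], numeric(1))
  if (anyNA(rel)) abort("every vector needs the mucilage_area trait.")
  out <- tibble(
    accession = vapply(vectors, function(v) v$genotype, character(1)),
    score = score_capsule_ratio(rel, 1)
  )
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Heatmap of reference-relative phenotypes
#'
#' Percent-of-reference heatmap over genotypes x traits, rows sorted by
#' the chosen trait (Man by default, as in the published figure), with
#' significant cells outlined.
#'
#' @param vectors List of `phenotype_vector`s.
#' @param sort_by Trait used to order rows (ascending).
#' @param path Optional output file (`.png` or `.svg`), written with
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if `path` is given.
#' @export
render_heatmap <- function(vectors, sort_by = "Man", path = NULL) {
  tab <- phenotype_table(vectors)
  ord <- tab |>
    dplyr::filter(.data$trait == sort_by) |>
    dplyr::arrange(.data$relative_value)
  tab$genotype <- factor(tab$genotype, levels = ord$genotype)
  tab$trait <- factor(tab$trait, levels = phenotype_trait_names())
  p <- ggplot2::ggplot(
    tab, ggplot2::aes(x = .data$trait, y = .data$genotype,
                      fill = 100 * .data$relative_value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(
      data = dplyr::filter(tab, .data$significant),
      fill = NA, color = "black", linewidth = 0.8) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$relative_value), "",
                                  sprintf("%.0f", 100 * .data$relative_value))),
      size = 3) +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac", midpoint = 100,
      name = "% of reference", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 1 + 0.4 * nlevels(tab$genotype))
    return(invisible(p))
  }
  p
}

#' @rdname render_heatmap
#' @param object List of `phenotype_vector`s.
#' @param ... Passed to [render_heatmap()].
#' @export
autoplot.phenotype_set <- function(object, ...) render_heatmap(object, ...)
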