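# Efficiency-corrected relative qRT-PCR quantification: serial-dilution
# primer efficiencies and Pfaffl fold changes against the geometric mean of
# two reference genes.

#' Estimate primer amplification efficiency from a serial dilution
#'
#' Least-squares regression of Cq on log10(relative template concentration)
#' over a dilution series. The per-cycle amplification factor is
#' `E = 10^(-1/slope)`; a perfect doubling gives a slope of -3.3219 and
#' E = 2.
#'
#' @param dilutions Relative template concentrations (e.g.
#'   `1, 0.1, 0.01, ...`), at least 3 strictly decreasing points.
#' @param cq_values Mean Cq at each dilution.
#' @param gene Optional gene label.
#' @return A `primer_efficiency`: list with `gene`, `efficiency`, `slope`,
#'   `r_squared` and the fitted `lm` object.
#' @export
estimate_efficiency <- function(dilutions, cq_values, gene = NA_character_) {
  if (length(dilutions) < 3L || length(dilutions) != length(cq_values))
    abort("need >= 3 dilution points with matching Cq values.")
  if (any(diff(dilutions) >= 0))
    abort("`dilutions` must be strictly decreasing concentrations.")
  fit <- stats::lm(cq_values ~ log10(dilutions))
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope >= 0)
    abort("non-negative dilution slope: amplification failure.")
  structure(
    list(gene = gene, efficiency = 10^(-1 / slope), slope = slope,
         # summary.lm warns on an exactly collinear (noise-free) series;
         # such series are legitimate validation inputs here
         r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit),
    class = "primer_efficiency"
  )
}

#' @export
print.primer_efficiency <- function(x, ...) {
  cat(sprintf("<primer_efficiency> %s: E = %.3f (slope %.3f, R^2 %.4f)\n",
              x$gene, x$efficiency, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.primer_efficiency <- function(x, ...) {
  tibble(gene = x$gene, efficiency = x$efficiency, slope = x$slope)
}

#' @export
glance.primer_efficiency <- function(x, ...) {
  tibble(gene = x$gene, efficiency = x$efficiency, slope = x$slope,
         r_squared = x$r_squared,
         n = length(stats::residuals(x$fit)))
}

check_efficiency <- function(E, gene) {
  if (is.null(E) || is.na(E)) abort(paste0("missing efficiency for gene ", gene))
  if (E <= 1 || E > 2.2)
    abort(sprintf("efficiency %.3f for %s outside (1, 2.2]", E, gene))
  E
}

#' Efficiency-corrected fold change (Pfaffl method)
#'
#' Relative expression of a target gene in each sample versus the mean of
#' the control genotype, normalized to two reference genes:
#' \deqn{fold = \frac{E_t^{\Delta Cq_t}}{\sqrt{E_{r1}^{\Delta Cq_{r1}}
#'   \cdot E_{r2}^{\Delta Cq_{r2}}}}}
#' where \eqn{\Delta Cq = Cq_{control} - Cq_{sample}} and the control Cq of
#' each gene is the mean over the control genotype's biological replicates
#' (technical replicates are Cq-averaged first). The geometric mean is
#' taken over the per-reference Pfaffl ratios. Fold changes are finally
#' rescaled so the control genotype's mean is exactly 1.
#'
#' @param cq Data frame with columns `sample`, `genotype`, `gene`, `cq`
#'   (one row per technical replicate is fine).
#' @param efficiencies Named numeric vector of per-gene amplification
#'   factors in (1, 2.2\], or a list of [estimate_efficiency()] results.
#' @param target Target gene name.
#' @param references Two reference gene names (the published assay used
#'   *UBQ5* and *elF4A1*).
#' @param control_genotype Genotype whose mean expression defines 1.0.
#' @return Tibble with `sample`, `genotype` and `fold_change`.
#' @export
fold_change <- function(cq, efficiencies, target,
                        references = c("UBQ5", "elF4A1"),
                        control_genotype = "Col-0") {
  need <- c("sample", "genotype", "gene", "cq")
  miss <- setdiff(need, names(cq))
  if (length(miss))
    abort(paste0("Cq table is missing columns: ", paste(miss, collapse = ", ")))
  if (length(references) != 2L) abort("exactly two reference genes required.")
  if (is.list(efficiencies) && !is.numeric(efficiencies)) {
    efficiencies <- vapply(efficiencies, function(e) e$efficiency, numeric(1),
                           USE.NAMES = FALSE) |>
      stats::setNames(vapply(efficiencies, function(e) e$gene, character(1)))
  }
  genes <- c(target, references)
  E <- vapply(genes, function(g) {
    check_efficiency(
      if (g %in% names(efficiencies)) efficiencies[[g]] else NULL, g)
  }, numeric(1))
  if (any(!genes %in% cq$gene))
    abort(paste0("Cq table lacks gene(s): ",
                 paste(setdiff(genes, cq$gene), collapse = ", ")))
  # average technical replicates per sample x gene
  m <- cq |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$sample, .data$genotype, .data$gene) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "cq")
  missing_ref <- genes[vapply(genes, function(g) anyNA(m[[g]]), logical(1))]
  if (length(missing_ref))
    abort(paste0("samples missing Cq for: ", paste(missing_ref, collapse = ", ")))
  ctrl <- m[m$genotype == control_genotype, , drop = FALSE]
  if (nrow(ctrl) == 0L)
    abort(paste0("no samples for control genotype ", control_genotype))
  ctrl_cq <- vapply(genes, function(g) mean(ctrl[[g]]), numeric(1))
  ratio_per_gene <- function(g) E[[g]]^(ctrl_cq[[g]] - m[[g]])
  fold <- ratio_per_gene(target) /
    sqrt(ratio_per_gene(references[1]) * ratio_per_gene(references[2]))
  # pin the control genotype mean at exactly 1.0
  fold <- fold / mean(fold[m$genotype == control_genotype])
  tibble(sample = m$sample, genotype = m$genotype, fold_change = fold)
}

#' Summarize fold changes per genotype with significance versus control
#'
#' Welch t-test of per-biological-replicate fold changes against the
#' control genotype's replicates.
#'
#' @param folds Output of [fold_change()].
#' @param control_genotype Control label.
#' @param alpha Significance level.
#' @return Tibble with `genotype`, `n`, `mean_fold`, `sd_fold`, `p_value`,
#'   `significant`.
#' @export
summarize_fold_changes <- function(folds, control_genotype = "Col-0",
                                   alpha = 0.05) {
  ctrl <- folds$fold_change[folds$genotype == control_genotype]
  folds |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold_change),
      sd_fold = stats::sd(.data$fold_change),
      p_value = trait_ttest(.data$fold_change, ctrl, alpha)$p_value,
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = .data$p_value < alpha)
}
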