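sugar_row <- function(sample = "s1", genotype = "Col-0", batch = "b1",
                      amounts = NULL, ribose = 24) {
  a <- stats::setNames(rep(1, 9), sugar_names())
  if (!is.null(amounts)) a[names(amounts)] <- amounts
  tibble::tibble(sample = sample, genotype = genotype, batch = batch,
                 !!!as.list(a), ribose_measured = ribose)
}

test_that("ribose internal-standard correction scales by expected/measured", {
  t1 <- internal_standard_correct(sugar_row(ribose = 24))
  expect_equal(t1$Gal, 1)          # 30 ug x 0.8 aliquot = 24 expected
  t2 <- internal_standard_correct(sugar_row(ribose = 12))
  expect_equal(t2$Gal, 2)          # factor 24/12
  expect_equal(t2$ribose_correction, 2)
  set.seed(71)
  for (i in 1:20) {
    amt <- runif(9, 0, 30)
    rib <- runif(1, 10, 30)
    tab <- internal_standard_correct(sugar_row(amounts = stats::setNames(
      amt, sugar_names()), ribose = rib))
    expect_equal(unlist(tab[sugar_names()]), amt * 24 / rib,
                 ignore_attr = TRUE)
  }
  expect_warning(
    out <- internal_standard_correct(
      dplyr::bind_rows(sugar_row("s1"), sugar_row("s2", ribose = 0))),
    "non-positive")
  expect_equal(out$sample, "s1")
})

test_that("per-mg conversion divides by aliquot fraction and seed mass", {
  tab <- sugar_row(amounts = c(Gal = 10))
  out <- to_ug_per_mg_seed(internal_standard_correct(tab))
  expect_equal(out$Gal, 10 / 0.8 / 5)  # 2.5 ug/mg
  z <- to_ug_per_mg_seed(internal_standard_correct(
    sugar_row(amounts = stats::setNames(rep(0, 9), sugar_names()))))
  expect_equal(z$total_mucilage, 0)
  expect_equal(out$total_mucilage, sum(out[, sugar_names()]))
})

test_that("correction and conversion commute with uniform dilution", {
  set.seed(72)
  amt <- stats::setNames(runif(9, 1, 20), sugar_names())
  base <- to_ug_per_mg_seed(internal_standard_correct(
    sugar_row(amounts = amt, ribose = 20)))
  # dilute everything (sugars and the measured ribose) two-fold
  dil <- to_ug_per_mg_seed(internal_standard_correct(
    sugar_row(amounts = amt / 2, ribose = 10)))
  expect_equal(unlist(dil[sugar_names()]), unlist(base[sugar_names()]))
})

test_that("per-batch reference normalization cancels batch drift", {
  set.seed(73)
  tabs <- list()
  true_gal <- c(`Col-0` = 1, mutant = 0.5)
  for (b in 1:3) {
    drift <- runif(1, 0.5, 2)
    for (g in names(true_gal)) {
      tabs[[paste(b, g)]] <- sugar_row(
        sample = paste0(g, b), genotype = g, batch = paste0("b", b),
        amounts = c(Gal = 4 * true_gal[[g]] * drift))
    }
  }
  comp <- to_ug_per_mg_seed(internal_standard_correct(dplyr::bind_rows(tabs)))
  rel <- batch_relative_to_reference(comp, "Col-0")
  expect_equal(rel$Gal[rel$genotype == "mutant"], rep(0.5, 3))
  expect_equal(rel$Gal[rel$genotype == "Col-0"], rep(1, 3))
  comp_bad <- comp[comp$genotype != "Col-0" | comp$batch != "b2", ]
  expect_error(batch_relative_to_reference(comp_bad, "Col-0"), "b2")
})

test_that("glucose spike flags follow the CV and fold rules", {
  mk <- function(glc, genotype = "g") {
    dplyr::bind_rows(lapply(seq_along(glc), function(i)
      sugar_row(sample = paste0(genotype, i), genotype = genotype,
                amounts = c(Glc = glc[i]))))
  }
  comp <- dplyr::bind_rows(mk(c(1, 1, 1), "Col-0"), mk(c(1, 1, 6), "spiky"))
  fl <- flag_glc_spikes(comp, "Col-0")
  ref_row <- fl$genotypes[fl$genotypes$genotype == "Col-0", ]
  expect_equal(ref_row$glc_cv, 0)
  expect_false(ref_row$glc_spike)
  spk <- fl$genotypes[fl$genotypes$genotype == "spiky", ]
  # hand oracle: mean 8/3, sd sqrt(sum((x-m)^2)/2)
  expect_equal(spk$glc_cv, sd(c(1, 1, 6)) / mean(c(1, 1, 6)))
  expect_gt(spk$glc_cv, 0.4)
  expect_true(spk$glc_spike)
  expect_equal(fl$samples$spike_flag[fl$samples$sample == "spiky3"], TRUE)
  expect_equal(sum(fl$samples$spike_flag), 1L)
  # single replicate: CV undefined, flag unknown
  single <- flag_glc_spikes(dplyr::bind_rows(mk(c(1, 1), "Col-0"),
                                             mk(2, "lonely")), "Col-0")
  expect_true(is.na(single$genotypes$glc_spike[
    single$genotypes$genotype == "lonely"]))
})

test_that("trait t-test handles identical, separated and degenerate groups", {
  same <- trait_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  expect_false(same$significant)
  far <- trait_ttest(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_true(far$significant)
  expect_true(is.na(trait_ttest(1, c(1, 2))$p_value))
})
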