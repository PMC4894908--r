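full_traits <- function(...) {
  tr <- class_archetype("reference")
  over <- c(...)
  tr[names(over)] <- over
  tr
}

test_that("vectors pass trait values through field-wise", {
  v <- assemble_vector("x", c(Gal = 0.5, Man = 0.7), c(Gal = TRUE))
  expect_equal(v$traits[["Gal"]], 0.5)
  expect_equal(v$traits[["Man"]], 0.7)
  expect_true(is.na(v$traits[["s4b_intensity"]]))  # absent, not zero
  expect_true(v$significance[["Gal"]])
  expect_false(v$significance[["Man"]])
  set.seed(91)
  vals <- runif(11)
  names(vals) <- names(class_archetype("reference"))
  v2 <- assemble_vector("y", vals)
  expect_equal(v2$traits, vals)
  expect_error(assemble_vector("z", c(bogus = 1)), "unknown trait")
  expect_error(assemble_vector("z", c(Gal = -0.1)), ">= 0")
})

test_that("the reference genotype is forced to an all-ones reference-like vector", {
  v <- assemble_vector("Col-0", c(Gal = 0.5), c(Gal = TRUE),
                       reference_genotype = "Col-0")
  expect_true(all(v$traits == 1))
  expect_equal(assign_class(v)$class_label, "reference-like")
})

test_that("ordered class rules reproduce the five published profiles", {
  expect_equal(assign_class(assemble_vector(
    "ones", class_archetype("reference")))$class_label, "reference-like")
  # muci10-like: about half the Gal and Man
  expect_equal(assign_class(assemble_vector(
    "b", full_traits(Gal = 0.5, Man = 0.45)))$class_label, "B")
  # high Man, normal Gal, birefringence largely retained (Dr-0-like)
  expect_equal(assign_class(assemble_vector(
    "e", full_traits(Man = 1.7, Gal = 1.0, birefringence = 0.83,
                     s4b_intensity = 0.34),
    c(Man = TRUE)))$class_label, "E")
  # high Man and Gal with almost no birefringence (Sei-0-like)
  expect_equal(assign_class(assemble_vector(
    "d", full_traits(Man = 1.7, Gal = 1.5, birefringence = 0.14),
    c(Man = TRUE, Gal = TRUE)))$class_label, "D")
  # larger seeds, half the pectin (Lc-0-like); A fires before B
  expect_equal(assign_class(assemble_vector(
    "a", full_traits(seed_area = 1.24, total_mucilage = 0.44, Gal = 0.4,
                     Man = 0.5, birefringence = 0.05),
    c(seed_area = TRUE)))$class_label, "A")
  # minor Gal/Man changes but severely disrupted staining
  expect_equal(assign_class(assemble_vector(
    "c", full_traits(Gal = 0.85, Man = 0.9, s4b_intensity = 0.4,
                     birefringence = 0.15)))$class_label, "C")
  # missing required trait
  expect_equal(assign_class(assemble_vector(
    "m", c(Gal = 0.5)))$class_label, "unclassified")
})

test_that("classification is a pure function: order and repetition invariant", {
  set.seed(92)
  vals <- lapply(1:10, function(i) {
    tr <- class_archetype(sample(c("A", "B", "C", "D", "E"), 1))
    assemble_vector(paste0("g", i), tr,
                    stats::setNames(runif(11) < 0.5, names(tr)))
  })
  l1 <- vapply(vals, function(v) assign_class(v)$class_label, character(1))
  l2 <- vapply(rev(vals), function(v) assign_class(v)$class_label,
               character(1))
  expect_equal(l1, rev(l2))
  expect_equal(l1, vapply(vals, function(v) assign_class(v)$class_label,
                          character(1)))
})

test_that("gwas score export maps relative areas onto the five scores", {
  vs <- list(
    assemble_vector("Col-0", full_traits()),
    assemble_vector("small", full_traits(mucilage_area = 0.58)),
    assemble_vector("tiny", full_traits(mucilage_area = 0.2)),
    assemble_vector("big", full_traits(mucilage_area = 1.3))
  )
  sc <- export_gwas_scores(vs)
  expect_equal(sc$score, c(1.0, 0.6, 0.4, 1.2))
  expect_true(all(sc$score %in% c(1.2, 1.0, 0.8, 0.6, 0.4)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_gwas_scores(vs, tmp)
  expect_equal(nrow(readr::read_csv(tmp, show_col_types = FALSE)), 4L)
})

test_that("heatmap rows are ordered by the sorting trait", {
  set.seed(93)
  vs <- lapply(1:25, function(i) {
    tr <- class_archetype("reference")
    tr["Man"] <- runif(1, 0.3, 2)
    assemble_vector(paste0("g", i), tr)
  })
  p <- render_heatmap(vs, sort_by = "Man")
  expect_s3_class(p, "ggplot")
  lv <- levels(p$data$genotype)
  man <- vapply(vs, function(v) v$traits[["Man"]], numeric(1))
  names(man) <- vapply(vs, function(v) v$genotype, character(1))
  expect_equal(lv, names(sort(man)))
})

test_that("phenotype vectors tidy into a long table", {
  v <- assign_class(assemble_vector("b", full_traits(Gal = 0.5, Man = 0.45)))
  td <- phenotype_table(list(v))
  expect_equal(nrow(td), 11L)
  expect_equal(unique(td$class_label), "B")
})
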