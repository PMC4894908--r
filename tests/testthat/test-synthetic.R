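small_rr_params <- function(name = "Col-0", ...) {
  genotype_params(name, n_seeds = 5, seed_radius_um = 28,
                  seed_radius_sd_um = 3, halo_um = 14, halo_sd_um = 2, ...)
}

test_that("generators are bitwise deterministic under a fixed seed", {
  g <- small_rr_params()
  a <- generate_rr_image(g, rng_seed = 42, image_size = 256, pixel_size = 1)
  b <- generate_rr_image(g, rng_seed = 42, image_size = 256, pixel_size = 1)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  s1 <- generate_s4b_image(g, rng_seed = 7, image_size = 128,
                           seed_radius_px = 30)
  s2 <- generate_s4b_image(g, rng_seed = 7, image_size = 128,
                           seed_radius_px = 30)
  expect_identical(s1$image$pixels, s2$image$pixels)
  spec <- cohort_spec(list(g), rng_seed = 3)
  expect_identical(generate_sugar_table(spec)$table,
                   generate_sugar_table(spec)$table)
  expect_identical(generate_cq_table(spec)$table,
                   generate_cq_table(spec)$table)
})

test_that("generated wells are segmentable by the printed windows by construction", {
  gen <- generate_rr_image(small_rr_params(), rng_seed = 5, image_size = 256,
                           pixel_size = 1)
  caps <- segment_by_window(gen$image, rr_capsule_window())
  seeds <- segment_by_window(gen$image, rr_seed_window())
  # every non-debris truth center is foreground in both masks
  ctr <- gen$truth[gen$truth$kind == "seed", ]
  idx <- cbind(round(ctr$center_row) + 1, round(ctr$center_col) + 1)
  expect_true(all(caps$pixels[idx]))
  expect_true(all(seeds$pixels[idx]))
  # capsule foreground strictly exceeds seed foreground (halos exist)
  expect_gt(sum(caps$pixels), sum(seeds$pixels))
})

test_that("zero halo thickness yields zero mucilage area end to end", {
  g <- genotype_params("flat", n_seeds = 4, seed_radius_um = 25,
                       seed_radius_sd_um = 2, halo_um = 0, halo_sd_um = 0)
  gen <- generate_rr_image(g, rng_seed = 9, image_size = 256, pixel_size = 1)
  w <- measure_rr_well(gen$image)
  expect_true(all(w$seeds$mucilage_area_um2 / w$seeds$seed_area_um2 < 0.02))
})

test_that("edge seeds and debris are constructed as advertised", {
  gen <- generate_rr_image(small_rr_params(), rng_seed = 11, image_size = 256,
                           pixel_size = 1, n_edge_seeds = 2, n_debris = 3)
  expect_equal(sum(gen$truth$touches_edge), 2L)
  w <- measure_rr_well(gen$image)
  # only the interior true seeds survive edge exclusion + circularity
  expect_equal(w$n_seeds, sum(gen$truth$kind == "seed"))
})

test_that("s4b amplitude zero leaves only background-level AUC", {
  g0 <- genotype_params("null", s4b_amplitude = 0)
  g1 <- genotype_params("Col-0")
  auc <- function(g, s) {
    gen <- generate_s4b_image(g, rng_seed = s, image_size = 192,
                              seed_radius_px = 40)
    profs <- auto_place_profiles(gen$image, gen$seed_mask, n_profiles = 3,
                                 length_px = 45, width_px = 9)
    mean(vapply(profs, trapezoid_auc, numeric(1)))
  }
  expect_lt(auc(g0, 1) / auc(g1, 1), 0.05)
})

test_that("s4b genotype ranking is reproducible under a shared seed", {
  lo <- genotype_params("lo", s4b_amplitude = 0.3)
  hi <- genotype_params("hi", s4b_amplitude = 1)
  for (s in 1:3) {
    a <- generate_s4b_image(lo, rng_seed = s, image_size = 128,
                            seed_radius_px = 30)
    b <- generate_s4b_image(hi, rng_seed = s, image_size = 128,
                            seed_radius_px = 30)
    expect_lt(sum(a$image$pixels[, , 1]), sum(b$image$pixels[, , 1]))
  }
})

test_that("birefringence truth area matches the measured bright area", {
  gen <- generate_birefringence_image(genotype_params("Col-0"), rng_seed = 2,
                                      image_size = 256, n_seeds = 5,
                                      noise_sd = 0)
  r <- measure_birefringence(gen$image, n_seeds = gen$truth$n_seeds)
  expect_equal(r$total_bright_area_um2, gen$truth$total_patch_area_px)
  z <- generate_birefringence_image(
    genotype_params("none", birefringence_density = 0), rng_seed = 3,
    image_size = 128, n_seeds = 3)
  expect_equal(z$truth$total_patch_area_px, 0)
  expect_equal(measure_birefringence(z$image, n_seeds = 3)$total_bright_area_um2, 0)
})

test_that("sugar tables carry the documented composition structure", {
  ref <- reference_sugar_means()
  frac <- (ref[["Rha"]] + ref[["GalA"]]) / sum(ref)
  expect_gt(frac, 0.88)
  expect_lt(frac, 0.92)
  expect_equal(ref[["Glc"]] / sum(ref), 0.01, tolerance = 0.2)
  spec <- cohort_spec(list(genotype_params("Col-0")), n_batches = 2,
                      n_replicates = 3, rng_seed = 13)
  st <- generate_sugar_table(spec)
  comp <- to_ug_per_mg_seed(internal_standard_correct(st$table))
  got <- colMeans(comp[, c("Rha", "GalA")]) / mean(comp$total_mucilage)
  expect_equal(sum(got), 0.9, tolerance = 0.03)
})

test_that("spike-free cohorts produce no spike flags downstream", {
  spec <- cohort_spec(list(genotype_params("Col-0"),
                           genotype_params("v", glc_spike_probability = 0)),
                      n_batches = 1, n_replicates = 3, rng_seed = 17)
  st <- generate_sugar_table(spec)
  expect_false(any(st$truth$samples$glc_spike))
  comp <- to_ug_per_mg_seed(internal_standard_correct(st$table))
  fl <- flag_glc_spikes(comp, "Col-0")
  expect_false(any(fl$genotypes$glc_spike, na.rm = TRUE))
})

test_that("cq tables encode the expression factor in the target Cq shift", {
  spec <- cohort_spec(list(genotype_params("Col-0"),
                           genotype_params("lo", expression_factor = 0.1)),
                      n_replicates = 3, rng_seed = 19)
  cq <- generate_cq_table(spec, bio_sd = 0, tech_sd = 0)
  m <- aggregate(cq ~ genotype + gene, cq$table, mean)
  shift <- m$cq[m$gene == "MUCI10" & m$genotype == "lo"] -
    m$cq[m$gene == "MUCI10" & m$genotype == "Col-0"]
  expect_equal(shift, -log(0.1) / log(cq$efficiencies[["MUCI10"]]),
               tolerance = 1e-9)
  # reference genes stay flat across genotypes
  expect_equal(m$cq[m$gene == "UBQ5" & m$genotype == "lo"],
               m$cq[m$gene == "UBQ5" & m$genotype == "Col-0"])
})
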