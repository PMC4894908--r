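# Synthetic-data generators with known ground truth for every assay:
# ruthenium-red wells, S4B fluorescence, polarized-light birefringence,
# HPAEC-PAD sugar tables and qPCR Cq tables. Each generator draws from its
# own RNG stream seeded from the cohort seed plus a stable per-genotype
# offset, so adding a genotype never perturbs the others.

# stable small hash of a genotype name
name_hash <- function(name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 999983
  h
}

derive_seed <- function(rng_seed, name, assay) {
  offs <- c(rr = 11L, s4b = 23L, biref = 37L, sugar = 53L, cq = 71L,
            pheno = 89L)
  (as.integer(rng_seed) * 7919 + name_hash(name) * 131 +
      offs[[assay]]) %% (2^31 - 1)
}

#' Per-genotype parameters for the synthetic cohort
#'
#' Defaults emulate the reference genotype: around 12 seeds per well, seeds
#' of roughly 175 um radius with a mucilage halo about 100 um thick, full
#' S4B ray amplitude, full crystalline patch density, a sugar profile in
#' which Rha + GalA make up about 90% of the total and Glc about 1%, no
#' glucose contamination, and unchanged target-gene expression.
#'
#' @param name Genotype label.
#' @param n_seeds Seeds per well image.
#' @param seed_radius_um,seed_radius_sd_um Major semi-axis of the seed
#'   ellipse (um), mean and between-seed sd.
#' @param halo_um,halo_sd_um Mucilage halo thickness (um).
#' @param axis_ratio Minor/major axis ratio of the seed ellipse.
#' @param seed_scale,halo_scale Multiplicative genotype effects on seed
#'   size and halo thickness.
#' @param s4b_amplitude Ray amplitude relative to the reference.
#' @param birefringence_density Crystalline patch density relative to the
#'   reference.
#' @param sugar_factors Named multiplicative effects on the reference sugar
#'   means (names from [sugar_names()]).
#' @param glc_spike_probability Per-sample probability of a glucose
#'   contamination spike.
#' @param expression_factor Target-gene expression relative to the
#'   reference.
#' @return A `genotype_params` list.
#' @export
genotype_params <- function(name,
                            n_seeds = 12L,
                            seed_radius_um = 175, seed_radius_sd_um = 12,
                            halo_um = 100, halo_sd_um = 8,
                            axis_ratio = 0.85,
                            seed_scale = 1, halo_scale = 1,
                            s4b_amplitude = 1,
                            birefringence_density = 1,
                            sugar_factors = NULL,
                            glc_spike_probability = 0,
                            expression_factor = 1) {
  sf <- stats::setNames(rep(1, 9), sugar_names())
  if (!is.null(sugar_factors)) sf[names(sugar_factors)] <- sugar_factors
  stopifnot(seed_radius_um > 0, halo_um >= 0, axis_ratio > 0,
            axis_ratio <= 1, s4b_amplitude >= 0,
            birefringence_density >= 0, all(sf >= 0),
            glc_spike_probability >= 0, glc_spike_probability <= 1,
            expression_factor > 0)
  structure(
    list(name = name, n_seeds = as.integer(n_seeds),
         seed_radius_um = seed_radius_um,
         seed_radius_sd_um = seed_radius_sd_um,
         halo_um = halo_um, halo_sd_um = halo_sd_um,
         axis_ratio = axis_ratio,
         seed_scale = seed_scale, halo_scale = halo_scale,
         s4b_amplitude = s4b_amplitude,
         birefringence_density = birefringence_density,
         sugar_factors = sf,
         glc_spike_probability = glc_spike_probability,
         expression_factor = expression_factor),
    class = "genotype_params"
  )
}

#' Reference monosaccharide means of the synthetic generator
#'
#' ug per mg seed for the nine sugars. Rha + GalA sum to about 90% of the
#' total and Glc to about 1%, matching the composition structure the
#' pipeline is designed for.
#' @return Named numeric vector.
#' @export
reference_sugar_means <- function() {
  c(Fuc = 0.05, Rha = 7.0, Ara = 0.15, Gal = 0.8, Glc = 0.2, Xyl = 0.35,
    Man = 0.25, GalA = 11.0, GlcA = 0.05)
}

#' Cohort specification for the synthetic study
#'
#' Bundles the genotypes, replication structure, imaging geometry and RNG
#' seed that define one simulated experiment: by default three biological
#' replicates per genotype and three chromatography batches, imaged at
#' 1024 x 1024 px and 2.5 um/px with additive Gaussian pixel noise
#' (sd 5, clipped to \[0, 255\]).
#'
#' @param genotypes List of [genotype_params()]; must include
#'   `reference_genotype`.
#' @param reference_genotype Name of the reference.
#' @param n_batches Chromatography batches.
#' @param n_replicates Biological replicates per genotype.
#' @param rng_seed Integer master seed; identical seeds give bitwise
#'   identical cohorts.
#' @param image_size Image side length in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param noise_sd Gaussian pixel-noise sd.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(genotypes, reference_genotype = "Col-0",
                        n_batches = 3L, n_replicates = 3L, rng_seed = 1L,
                        image_size = 1024L, pixel_size = 2.5,
                        noise_sd = 5) {
  names(genotypes) <- vapply(genotypes, function(g) g$name, character(1))
  if (!reference_genotype %in% names(genotypes))
    abort(paste0("cohort must include the reference genotype ",
                 reference_genotype))
  structure(
    list(genotypes = genotypes, reference_genotype = reference_genotype,
         n_batches = as.integer(n_batches),
         n_replicates = as.integer(n_replicates),
         rng_seed = as.integer(rng_seed),
         image_size = as.integer(image_size), pixel_size = pixel_size,
         noise_sd = noise_sd),
    class = "cohort_spec"
  )
}

# paint additive Gaussian noise, round and clip to [0, 255]
add_noise <- function(arr, sd) {
  if (sd > 0) arr <- arr + stats::rnorm(length(arr), 0, sd)
  arr <- round(arr)
  arr[arr < 0] <- 0
  arr[arr > 255] <- 255
  storage.mode(arr) <- "integer"
  arr
}

# fill a rotated ellipse into logical matrix m (in place value TRUE);
# returns the updated matrix. Center 0-based.
paint_ellipse <- function(m, center, a, b, angle) {
  nr <- nrow(m); nc <- ncol(m)
  rmax <- max(a, b)
  r0 <- max(1L, floor(center[1] - rmax) + 1L)
  r1 <- min(nr, ceiling(center[1] + rmax) + 1L)
  c0 <- max(1L, floor(center[2] - rmax) + 1L)
  c1 <- min(nc, ceiling(center[2] + rmax) + 1L)
  if (r0 > r1 || c0 > c1) return(m)
  rows <- (r0:r1) - 1
  cols <- (c0:c1) - 1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  x <- cos(angle) * dx + sin(angle) * dy
  y <- -sin(angle) * dx + cos(angle) * dy
  inside <- (x / a)^2 + (y / b)^2 <= 1
  sub <- m[r0:r1, c0:c1]
  m[r0:r1, c0:c1] <- sub | inside
  m
}

#' Generate a synthetic ruthenium-red well image
#'
#' Dark ellipsoidal seeds surrounded by pink-staining annular halos on a
#' pale background, with optional edge-touching seeds and low-circularity
#' debris, plus additive Gaussian noise. Seed bodies fall inside the seed
#' threshold window, halos inside the capsule window but outside the seed
#' window, and the background outside both — by construction, so every
#' generated image is segmentable with the printed windows. The halo of a
#' seed with semi-axes `(a, b)` is the ellipse with semi-axes
#' `(a + t, b + t)`, so its analytic annulus area is
#' `pi * ((a + t) * (b + t) - a * b)`.
#'
#' @param params A [genotype_params()].
#' @param rng_seed Integer seed for this image's RNG stream.
#' @param image_size Side length in px.
#' @param pixel_size Micrometres per pixel.
#' @param noise_sd Gaussian pixel noise sd.
#' @param n_edge_seeds Extra seeds deliberately touching the border.
#' @param n_debris Thin dark debris streaks (circularity well below 0.5).
#' @return List with `image` (an [rgb_image()]) and `truth` (tibble:
#'   `seed_id`, `kind`, centers, semi-axes `a_px`, `b_px`, halo `t_px`,
#'   analytic `seed_area_px`, `annulus_area_px`, `seed_area_um2`,
#'   `annulus_area_um2`, `touches_edge`).
#' @export
generate_rr_image <- function(params, rng_seed, image_size = 1024L,
                              pixel_size = 2.5, noise_sd = 5,
                              n_edge_seeds = 0L, n_debris = 0L) {
  set.seed(rng_seed %% (2^31 - 1))
  n <- image_size
  col_bg <- c(235, 225, 230)
  col_halo <- c(200, 80, 150)
  col_seed <- c(70, 50, 45)

  a_mean <- params$seed_radius_um * params$seed_scale / pixel_size
  a_sd <- params$seed_radius_sd_um / pixel_size
  t_mean <- params$halo_um * params$halo_scale / pixel_size
  t_sd <- params$halo_sd_um / pixel_size

  placed <- list()
  truth <- list()
  too_close <- function(center, rad) {
    for (p in placed) {
      if (sqrt(sum((center - p$center)^2)) < rad + p$outer + 4) return(TRUE)
    }
    FALSE
  }
  place_one <- function(kind) {
    a <- max(5, stats::rnorm(1, a_mean, a_sd))
    b <- a * params$axis_ratio
    t <- max(0, stats::rnorm(1, t_mean, t_sd))
    outer_r <- a + t
    for (try in 1:200) {
      if (kind == "edge_seed") {
        side <- sample(4L, 1L)
        along <- stats::runif(1, outer_r, n - 1 - outer_r)
        off <- stats::runif(1, 0, 0.5 * b)  # center within b/2 of the border
        center <- switch(side, c(off, along), c(n - 1 - off, along),
                         c(along, off), c(along, n - 1 - off))
      } else {
        center <- stats::runif(2, outer_r + 2, n - 3 - outer_r)
      }
      if (!too_close(center, outer_r)) {
        placed[[length(placed) + 1L]] <<- list(center = center,
                                               outer = outer_r)
        angle <- stats::runif(1, 0, pi)
        truth[[length(truth) + 1L]] <<- tibble(
          kind = kind, center_row = center[1], center_col = center[2],
          a_px = a, b_px = b, t_px = t, angle = angle
        )
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(params$n_seeds)) place_one("seed")
  for (i in seq_len(n_edge_seeds)) place_one("edge_seed")

  seed_mask <- matrix(FALSE, n, n)
  outer_mask <- matrix(FALSE, n, n)
  for (tr in truth) {
    ctr <- c(tr$center_row, tr$center_col)
    outer_mask <- paint_ellipse(outer_mask, ctr, tr$a_px + tr$t_px,
                                tr$b_px + tr$t_px, tr$angle)
    seed_mask <- paint_ellipse(seed_mask, ctr, tr$a_px, tr$b_px, tr$angle)
  }
  debris_mask <- matrix(FALSE, n, n)
  if (n_debris > 0L) {
    for (i in seq_len(n_debris)) {
      for (try in 1:100) {
        ctr <- stats::runif(2, 40, n - 41)
        # keep debris clear of seeds and halos so it stays a separate particle
        if (!too_close(ctr, 36)) break
      }
      if (too_close(ctr, 36)) next
      ang <- stats::runif(1, 0, pi)
      # a 3 x 60 px streak: strongly elongated, circularity far below 0.5
      debris_mask <- paint_rect(debris_mask, ctr, 30, 1.5, ang)
    }
  }

  img <- array(0, dim = c(n, n, 3))
  halo_only <- outer_mask & !seed_mask
  for (k in 1:3) {
    ch <- matrix(col_bg[k], n, n)
    ch[halo_only] <- col_halo[k]
    ch[seed_mask | debris_mask] <- col_seed[k]
    img[, , k] <- ch
  }
  img <- add_noise(img, noise_sd)

  truth_tb <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(kind = character(), center_row = numeric(), center_col = numeric(),
           a_px = numeric(), b_px = numeric(), t_px = numeric(),
           angle = numeric())
  truth_tb <- dplyr::mutate(
    truth_tb,
    seed_id = dplyr::row_number(),
    seed_area_px = pi * .data$a_px * .data$b_px,
    annulus_area_px = pi * ((.data$a_px + .data$t_px) *
                              (.data$b_px + .data$t_px) -
                              .data$a_px * .data$b_px),
    seed_area_um2 = .data$seed_area_px * pixel_size^2,
    annulus_area_um2 = .data$annulus_area_px * pixel_size^2,
    touches_edge = .data$kind == "edge_seed",
    .before = 1
  )
  list(image = rgb_image(img, pixel_size = pixel_size,
                         source = paste0("synthetic-rr:", params$name)),
       truth = truth_tb)
}

# thin rotated rectangle (half-length hl along angle, half-width hw)
paint_rect <- function(m, center, hl, hw, angle) {
  nr <- nrow(m); nc <- ncol(m)
  rmax <- hl + hw + 1
  r0 <- max(1L, floor(center[1] - rmax) + 1L)
  r1 <- min(nr, ceiling(center[1] + rmax) + 1L)
  c0 <- max(1L, floor(center[2] - rmax) + 1L)
  c1 <- min(nc, ceiling(center[2] + rmax) + 1L)
  rows <- (r0:r1) - 1
  cols <- (c0:c1) - 1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  inside <- abs(u) <= hl & abs(v) <= hw
  m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] | inside
  m
}

#' Generate a synthetic S4B confocal image
#'
#' One seed per field: a dim disk-shaped seed body with a red-channel
#' fluorescence field outside it that decays exponentially with distance
#' from the seed surface and is modulated by periodic angular peaks — the
#' ray-like signal above columellae. The recoverable ground truth is the
#' ray amplitude; the reference genotype's amplitude defines relative
#' intensity 1.0.
#'
#' @param params A [genotype_params()] (uses `s4b_amplitude`).
#' @param rng_seed Integer RNG seed.
#' @param image_size Side length in px.
#' @param seed_radius_px Seed body radius.
#' @param decay_px Exponential decay length of the halo signal.
#' @param n_rays Number of angular peaks.
#' @param peak_intensity Red intensity at the seed surface for amplitude 1.
#' @param noise_sd Gaussian pixel noise sd.
#' @return List with `image`, `seed_mask` (a `binary_mask` of the seed
#'   body) and `truth` (amplitude, geometry).
#' @export
generate_s4b_image <- function(params, rng_seed, image_size = 512L,
                               seed_radius_px = 110, decay_px = 35,
                               n_rays = 24L, peak_intensity = 180,
                               noise_sd = 2) {
  set.seed(rng_seed %% (2^31 - 1))
  n <- image_size
  ctr <- (n - 1) / 2
  coords <- seq_len(n) - 1
  dy <- outer(coords - ctr, rep(1, n))
  dx <- outer(rep(1, n), coords - ctr)
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  phase <- stats::runif(1, 0, 2 * pi)
  rays <- 0.5 + 0.5 * cos(n_rays * theta + phase)^2
  red <- matrix(0, n, n)
  outside <- d > seed_radius_px
  red[outside] <- params$s4b_amplitude * peak_intensity *
    exp(-(d[outside] - seed_radius_px) / decay_px) * rays[outside]
  red[!outside] <- 25  # dim seed body
  img <- array(0, dim = c(n, n, 3))
  img[, , 1] <- red
  img <- add_noise(img, noise_sd)
  list(
    image = rgb_image(img, pixel_size = 1,
                      source = paste0("synthetic-s4b:", params$name)),
    seed_mask = binary_mask(d <= seed_radius_px, 1),
    truth = tibble(genotype = params$name,
                   amplitude = params$s4b_amplitude,
                   seed_radius_px = seed_radius_px, decay_px = decay_px,
                   n_rays = n_rays)
  )
}

#' Generate a synthetic polarized-light birefringence image
#'
#' A dark field with darker seed bodies and sparse bright crystalline
#' patches near the seed rims, sampled at a density proportional to the
#' genotype's `birefringence_density`. Patches fall inside the
#' polarized-light threshold window by construction; the ground truth is
#' the exact painted patch area and the seed count.
#'
#' @param params A [genotype_params()].
#' @param rng_seed Integer RNG seed.
#' @param image_size Side length in px.
#' @param n_seeds Seeds in the field.
#' @param seed_radius_px Seed body radius.
#' @param patches_per_seed Bright patches per seed at density 1.
#' @param noise_sd Gaussian pixel noise sd.
#' @return List with `image` and `truth` (`total_patch_area_px`,
#'   `n_seeds`, `n_patches`).
#' @export
generate_birefringence_image <- function(params, rng_seed,
                                         image_size = 512L, n_seeds = 10L,
                                         seed_radius_px = 40,
                                         patches_per_seed = 6,
                                         noise_sd = 3) {
  set.seed(rng_seed %% (2^31 - 1))
  n <- image_size
  col_field <- c(28, 24, 26)
  col_seedb <- c(8, 8, 8)
  col_patch <- c(225, 215, 205)

  centers <- matrix(NA_real_, n_seeds, 2)
  k <- 0L
  for (i in seq_len(n_seeds)) {
    for (try in 1:200) {
      ctr <- stats::runif(2, seed_radius_px + 12, n - 13 - seed_radius_px)
      if (k == 0L ||
          all(sqrt(rowSums((centers[seq_len(k), , drop = FALSE] -
                              matrix(ctr, k, 2, byrow = TRUE))^2)) >
              2 * seed_radius_px + 14)) {
        k <- k + 1L
        centers[k, ] <- ctr
        break
      }
    }
  }
  centers <- centers[seq_len(k), , drop = FALSE]

  seed_mask <- matrix(FALSE, n, n)
  for (i in seq_len(k))
    seed_mask <- paint_ellipse(seed_mask, centers[i, ], seed_radius_px,
                               seed_radius_px, 0)
  patch_mask <- matrix(FALSE, n, n)
  n_patches <- stats::rpois(1, params$birefringence_density *
                              patches_per_seed * k)
  placed <- 0L
  if (n_patches > 0L) {
    for (p in seq_len(n_patches)) {
      for (try in 1:50) {
        i <- sample(k, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- seed_radius_px * stats::runif(1, 0.95, 1.25)
        ctr <- centers[i, ] + dist * c(sin(ang), cos(ang))
        pr <- stats::runif(1, 2, 5)
        if (any(ctr < pr + 1) || any(ctr > n - 2 - pr)) next
        cand <- paint_ellipse(matrix(FALSE, n, n) , ctr, pr, pr, 0)
        if (!any(cand & patch_mask)) {
          patch_mask <- patch_mask | cand
          placed <- placed + 1L
          break
        }
      }
    }
  }

  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    m <- matrix(col_field[ch], n, n)
    m[seed_mask] <- col_seedb[ch]
    m[patch_mask] <- col_patch[ch]
    img[, , ch] <- m
  }
  img <- add_noise(img, noise_sd)
  list(
    image = rgb_image(img, pixel_size = 1,
                      source = paste0("synthetic-biref:", params$name)),
    truth = tibble(genotype = params$name,
                   total_patch_area_px = sum(patch_mask),
                   n_seeds = k, n_patches = placed,
                   density = params$birefringence_density)
  )
}

#' Generate a synthetic HPAEC-PAD sugar table
#'
#' Raw per-sample sugar amounts (ug in the injected aliquot) with the
#' structure the composition workflow assumes: reference means from
#' [reference_sugar_means()], multiplicative genotype effects, per-batch
#' multiplicative drift, sample-specific extraction recovery shared with
#' the ribose internal standard, replicate noise, and Bernoulli glucose
#' contamination spikes of at least five-fold.
#'
#' @param spec A [cohort_spec()].
#' @param rng_seed Integer seed (defaults to the cohort's).
#' @param seed_mass_mg,aliquot_fraction,ribose_added_ug Extraction
#'   constants (5 mg, 0.8, 30 ug under the emulated protocol).
#' @param replicate_cv Lognormal replicate coefficient of variation.
#' @param batch_factor_range Range of per-batch multiplicative drift.
#' @param recovery_range Range of sample extraction recovery.
#' @return List with `table` (ready for [internal_standard_correct()]) and
#'   `truth` (per genotype: the injected sugar factors; per batch: drift;
#'   per sample: recovery and spike indicator).
#' @export
generate_sugar_table <- function(spec, rng_seed = spec$rng_seed,
                                 seed_mass_mg = 5, aliquot_fraction = 0.8,
                                 ribose_added_ug = 30,
                                 replicate_cv = 0.08,
                                 batch_factor_range = c(0.5, 2),
                                 recovery_range = c(0.7, 1.05)) {
  set.seed(derive_seed(rng_seed, "cohort", "sugar"))
  ref <- reference_sugar_means()
  batch_factors <- stats::runif(spec$n_batches, batch_factor_range[1],
                                batch_factor_range[2])
  rows <- list()
  truth_samples <- list()
  for (g in spec$genotypes) {
    gmeans <- ref * g$sugar_factors
    for (b in seq_len(spec$n_batches)) {
      for (r in seq_len(spec$n_replicates)) {
        recovery <- stats::runif(1, recovery_range[1], recovery_range[2])
        noise <- exp(stats::rnorm(9, -replicate_cv^2 / 2, replicate_cv))
        true_per_mg <- gmeans * noise
        spike <- stats::runif(1) < g$glc_spike_probability
        if (spike) {
          true_per_mg[["Glc"]] <- true_per_mg[["Glc"]] +
            ref[["Glc"]] * stats::runif(1, 5, 15)
        }
        raw <- true_per_mg * seed_mass_mg * aliquot_fraction *
          batch_factors[b] * recovery
        id <- sprintf("%s_b%d_r%d", g$name, b, r)
        rows[[id]] <- tibble(
          sample = id, genotype = g$name, batch = paste0("batch", b),
          replicate = paste0("rep", r), !!!as.list(raw),
          ribose_measured = ribose_added_ug * aliquot_fraction * recovery,
          seed_mass_mg = seed_mass_mg, aliquot_fraction = aliquot_fraction
        )
        truth_samples[[id]] <- tibble(sample = id, genotype = g$name,
                                      batch = paste0("batch", b),
                                      recovery = recovery, glc_spike = spike)
      }
    }
  }
  list(
    table = dplyr::bind_rows(rows),
    truth = list(
      sugar_factors = purrr::map_dfr(spec$genotypes, function(g)
        tibble(genotype = g$name, !!!as.list(g$sugar_factors))),
      batch_factors = tibble(batch = paste0("batch", seq_len(spec$n_batches)),
                             factor = batch_factors),
      samples = dplyr::bind_rows(truth_samples)
    )
  )
}

#' Generate a synthetic qPCR Cq table
#'
#' Two stable reference genes and one target gene whose Cq is shifted by
#' `-log_E(expression_factor)` relative to the reference genotype, with
#' biological and technical replicate noise.
#'
#' @param spec A [cohort_spec()].
#' @param rng_seed Integer seed (defaults to the cohort's).
#' @param target Target gene name.
#' @param efficiencies Named per-gene amplification factors.
#' @param base_cq Named baseline Cq of each gene in the reference genotype.
#' @param n_technical Technical replicates per well.
#' @param bio_sd,tech_sd Cq noise standard deviations.
#' @return List with `table` (columns `sample`, `genotype`, `gene`,
#'   `role`, `cq`), `efficiencies`, and `truth` (per-genotype expression
#'   factors).
#' @export
generate_cq_table <- function(spec, rng_seed = spec$rng_seed,
                              target = "MUCI10",
                              efficiencies = c(MUCI10 = 1.95, UBQ5 = 2.0,
                                               elF4A1 = 1.98),
                              base_cq = c(MUCI10 = 26, UBQ5 = 21,
                                          elF4A1 = 23),
                              n_technical = 2L, bio_sd = 0.1,
                              tech_sd = 0.1) {
  set.seed(derive_seed(rng_seed, "cohort", "cq"))
  genes <- c(target, "UBQ5", "elF4A1")
  rows <- list()
  for (g in spec$genotypes) {
    for (r in seq_len(spec$n_replicates)) {
      id <- sprintf("%s_r%d", g$name, r)
      for (gene in genes) {
        mu <- base_cq[[gene]]
        if (gene == target)
          mu <- mu - log(g$expression_factor) / log(efficiencies[[gene]])
        bio <- stats::rnorm(1, 0, bio_sd)
        cqs <- mu + bio + stats::rnorm(n_technical, 0, tech_sd)
        rows[[paste(id, gene)]] <- tibble(
          sample = id, genotype = g$name, gene = gene,
          role = ifelse(gene == target, "target", "reference"), cq = cqs
        )
      }
    }
  }
  list(
    table = dplyr::bind_rows(rows),
    efficiencies = efficiencies,
    truth = purrr::map_dfr(spec$genotypes, function(g)
      tibble(genotype = g$name, expression_factor = g$expression_factor))
  )
}

#' Class archetype parameters for the five mucilage classes
#'
#' Reference-relative trait means that typify each published class:
#' A (larger seeds, about half the pectin), B (muci10-like loss of Gal and
#' Man), C (near-normal Gal/Man but severely disrupted staining),
#' D (more Man *and* Gal with almost no birefringence), E (more Man,
#' normal Gal, birefringence largely retained despite weak S4B).
#'
#' @param class One of `"A"` to `"E"`, or `"reference"`.
#' @return Named numeric vector of relative trait means.
#' @export
class_archetype <- function(class = c("A", "B", "C", "D", "E", "reference")) {
  class <- match.arg(class)
  switch(class,
    reference = c(mucilage_area = 1, seed_area = 1, s4b_intensity = 1,
                  birefringence = 1, Rha = 1, GalA = 1, Gal = 1, Glc = 1,
                  Man = 1, Xyl = 1, total_mucilage = 1),
    A = c(mucilage_area = 0.35, seed_area = 1.24, s4b_intensity = 0.9,
          birefringence = 0.05, Rha = 0.44, GalA = 0.44, Gal = 0.4,
          Glc = 1, Man = 0.5, Xyl = 0.9, total_mucilage = 0.44),
    B = c(mucilage_area = 0.55, seed_area = 1.0, s4b_intensity = 0.4,
          birefringence = 0.1, Rha = 0.85, GalA = 0.85, Gal = 0.5,
          Glc = 1, Man = 0.45, Xyl = 0.95, total_mucilage = 0.8),
    C = c(mucilage_area = 0.5, seed_area = 1.0, s4b_intensity = 0.4,
          birefringence = 0.15, Rha = 0.85, GalA = 0.85, Gal = 0.85,
          Glc = 1, Man = 0.9, Xyl = 0.95, total_mucilage = 0.85),
    D = c(mucilage_area = 0.6, seed_area = 1.0, s4b_intensity = 0.5,
          birefringence = 0.14, Rha = 0.9, GalA = 0.9, Gal = 1.5,
          Glc = 1, Man = 1.7, Xyl = 1.0, total_mucilage = 0.95),
    E = c(mucilage_area = 0.65, seed_area = 1.0, s4b_intensity = 0.34,
          birefringence = 0.83, Rha = 0.9, GalA = 0.9, Gal = 1.0,
          Glc = 1, Man = 1.6, Xyl = 1.1, total_mucilage = 0.95)
  )
}

#' Simulate a replicate-level phenotype cohort for one genotype
#'
#' A lightweight generator for class-assignment studies: draws lognormal
#' replicate values around the genotype's relative trait means and around
#' 1.0 for the reference, computes per-trait Welch t-tests, and assembles
#' a classified [assemble_vector()].
#'
#' @param trait_means Named relative trait means (see [class_archetype()]).
#' @param genotype Label for the simulated genotype.
#' @param n_replicates Replicates per group.
#' @param noise_cv Lognormal replicate coefficient of variation.
#' @param rng_seed Integer seed.
#' @param thresholds Class-rule thresholds.
#' @return A classified `phenotype_vector`.
#' @export
simulate_phenotype_vector <- function(trait_means, genotype = "synthetic",
                                      n_replicates = 3L, noise_cv = 0.05,
                                      rng_seed = 1L,
                                      thresholds = class_rule_defaults()) {
  set.seed(rng_seed %% (2^31 - 1))
  draw <- function(mu) mu * exp(stats::rnorm(n_replicates,
                                             -noise_cv^2 / 2, noise_cv))
  traits <- numeric(0)
  sig <- logical(0)
  for (tn in names(trait_means)) {
    smp <- draw(trait_means[[tn]])
    ref <- draw(1)
    traits[tn] <- mean(smp) / mean(ref)
    sig[tn] <- isTRUE(trait_ttest(smp, ref)$significant)
  }
  assign_class(assemble_vector(genotype, traits, sig), thresholds)
}
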