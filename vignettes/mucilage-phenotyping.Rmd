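---
title: "Quantifying Arabidopsis seed mucilage phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Arabidopsis seed mucilage phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucilager)
```

## The measurement problem

Hydrated Arabidopsis seeds release a polysaccharide capsule — mucilage —
whose architecture varies widely between natural accessions. Four
complementary assays quantify it:

1. **Ruthenium-red (RR) capsule area.** RR stains pectin; a stained well
   image is segmented twice with color-threshold windows, once for
   mucilage-plus-seed ("capsule") regions and once for the seed bodies, and
   per-seed mucilage area is the difference between the paired particles.
2. **S4B cellulose staining.** Pontamine Fast Scarlet 4B fluoresces on
   cellulose; intensity profiles drawn perpendicular to the seed surface are
   integrated by the trapezoidal rule and expressed relative to the
   reference genotype.
3. **Birefringence.** Crystalline polymers rotate plane-polarized light;
   total bright area per image, divided by the number of seeds, measures
   crystalline structure abundance.
4. **Monosaccharide composition.** HPAEC-PAD quantities of nine sugars are
   corrected by a ribose internal standard, converted to µg per mg seed,
   and normalized per chromatography batch to reference extracts.

Trait values relative to the reference genotype (Col-0), with per-trait
Welch t-tests, are assembled into a phenotype vector per genotype,
classified into five mucilage classes, and exported as a heatmap and a
semi-quantitative GWAS phenotype score.

## Image segmentation and particle analysis

A pixel is selected by a `threshold_window()` iff **every** channel lies
inclusively within its `(min, max)` bounds — the semantics of ImageJ's
Color Threshold, on which the original macros were built. The calibrated
windows are exposed as defaults:

| window | red | green | blue | selects |
|---|---|---|---|---|
| `rr_capsule_window()` | (0, 255) | (0, 115) | (0, 255) | mucilage + seed |
| `rr_seed_window()` | (0, 120) | (0, 255) | (0, 255) | seed bodies |
| `birefringence_window()` | (55, 255) | (140, 255) | (60, 255) | crystalline regions |

`label_particles()` labels foreground under **8-connectivity** (the
foreground connectivity of ImageJ's Analyze Particles), optionally
absorbing enclosed holes first ("include holes"): background is labeled
under 4-connectivity and components not touching the border are merged
into the enclosing particle. Label order is the deterministic
first-encounter order of a column-major scan.

**Perimeter and circularity.** Circularity is `4πA/P²`, clamped at 1 (as
ImageJ clamps small particles). Because the 0.5 circularity cutoff sits in
a regime where discrete perimeter estimators disagree, the estimator is
frozen: a 4-direction Crofton (integral-geometry) estimate computed from
2×2 pixel-configuration counts. It is accurate for smooth outlines — a
rasterized disk of radius 20 px scores ≈ 0.97, where naive edge counting
would score ≈ 0.6 and wrongly approach the cutoff — and a thin 1×30 px
streak scores ≈ 0.11, far below it. The disk perimeter value (127.7137) is
kept as a regression fixture.

**Particle filtering.** The capsule assay keeps circularity 0.5–1.0,
drops border-touching particles, and excludes "extreme sizes". No size
bounds were ever published, so the default is relative: keep areas in
[0.25×, 4×] the median particle area of the image under analysis,
overridable with absolute bounds. The birefringence assay deliberately
applies **no** filter and no edge exclusion — a border-touching bright
patch counts there but would be excluded in the capsule assay (a fixture
asserts exactly this asymmetry).

**Pairing.** Each retained seed particle is paired with the capsule
particle whose (hole-filled) region contains the seed centroid; unpaired
particles are dropped with a logged count. Mucilage area is capsule minus
seed per pair, clamped at zero with a warning if segmentation noise ever
inverts a pair. Wells with fewer than 10 paired seeds are flagged
`low_count` rather than rejected, so small test fixtures stay usable.

## S4B profiles

`extract_profile()` samples the red channel (S4B emission at 600–650 nm is
imaged in red; configurable) at unit steps along the line, averaging
`width_px` bilinear samples spaced 1 px along the perpendicular — the
wide-line Plot Profile. The published width of 200 is taken to be pixels.
Positions whose entire width band leaves the image are dropped with a
warning. The AUC is the trapezoidal rule, exact for affine profiles;
relative S4B intensity is the ratio of mean AUCs, and is exactly linear in
any global intensity scale because the rule is linear.

The original workflow drew lines by hand. `auto_place_profiles()` replaces
that with a deterministic rule — start points evenly spaced by polar angle
on the boundary of the largest seed particle, directed along the outward
radial direction — so placement is reproducible; manually chosen endpoints
remain supported through `extract_profile()` directly. Profile alignment
before averaging (`align_profiles()`) shifts each profile so its global
maximum sits at position zero; AUC is shift-invariant, so this only
matters for plotting and group averaging of shapes. AUCs are computed on
raw intensities; `subtract_background()` is available where a baseline
should be removed first.

## Birefringence

Segment with the polarized-light window, label with holes included, sum
**all** particle areas, divide by the seed count (counted manually in the
original protocol; `count_seed_bodies()` offers an automatic count for
synthetic images). Counts below 8 are flagged. Two imaging days form a
batch dimension: `batch_mean_birefringence()` averages area-per-seed over
batches before dividing by the reference statistic.

## Monosaccharide composition

Each extraction of 5 mg seeds in 1 mL water carries 30 µg ribose; 800 µL
of supernatant (aliquot fraction 0.8) proceeds to hydrolysis, so the
expected ribose in the aliquot is 24 µg. Measured sugars are multiplied by
`24 / ribose_measured`, cancelling sample-specific recovery; per-mg values
divide by the aliquot fraction and seed mass (the aliquot correction is
applied by default and configurable). Batch drift cancels by dividing each
genotype × sugar value by the arithmetic mean of the same batch's
reference samples.

Glucose contamination is flagged two ways: a genotype whose replicate CV
of Glc exceeds 0.4, and individual samples with Glc at least 5× the
reference mean. With a single replicate the CV is undefined and the flag
is `NA`, never silently `FALSE`.

Per-trait significance uses Welch's unequal-variance t-test at raw
P < 0.05 — no multiplicity correction, matching how the heatmap
significance was reported; `adjust_trait_pvalues()` offers Holm correction
for users who want it. Welch rather than Student because at n = 3
replicates the equal-variance assumption buys nothing and costs
robustness.

## qPCR

Primer efficiency comes from the serial-dilution slope of Cq on
log10(concentration), `E = 10^(-1/slope)`; efficiencies outside (1, 2.2]
are rejected. The fold change is the Pfaffl ratio

$$\mathrm{fold} = \frac{E_t^{\,\Delta Cq_t}}
  {\sqrt{E_{r1}^{\,\Delta Cq_{r1}}\; E_{r2}^{\,\Delta Cq_{r2}}}},
\qquad \Delta Cq = Cq_{\text{control}} - Cq_{\text{sample}},$$

with technical replicates Cq-averaged first and the control Cq taken as
the mean over the control genotype's biological replicates. The
literature's variants differ in where the two-gene geometric mean is
taken; this package takes it over the per-reference ratios (equivalently,
the exponent-averaged normalization factor) and finally rescales all folds
so the control genotype's mean is exactly 1.0. Useful identities hold by
construction: with all E = 2 the ratio reduces to `2^(-ΔΔCq)`; swapping
the reference genes changes nothing; adding a constant to every Cq
changes nothing.

## Classification

Rules are applied in the order A → D → E → B → C; first match wins, so
labels are deterministic and mutually exclusive:

- **A** — seeds significantly larger than the reference *and* total
  mucilage ≤ 0.55 (larger seeds, about half the pectin);
- **D** — Man and Gal both significantly increased, birefringence ≤ 0.2;
- **E** — Man significantly increased, Gal not increased, birefringence
  ≥ 0.45 despite reduced S4B;
- **B** — Gal ≤ 0.6 or Man ≤ 0.6 (at least 40% less Gal and/or Man, the
  GGM-deficient profile);
- **C** — Gal and Man within (0.6, 1] but S4B ≤ 0.55 or birefringence
  ≤ 0.2 (minor composition change, severely disrupted structure).

The published classification is descriptive, so every boundary is exposed
in `class_rule_defaults()`. One boundary is this package's own addition:
when no rule fires, a vector counts as `reference-like` only if every
measured trait lies within ±0.1 of 1.0, otherwise `unclassified` — the
published account did not need this distinction because every screened
accession had a visible defect. Borderline accessions near the B/C
boundary may classify differently from the original letters; that is a
property of any numeric anchoring of a descriptive scheme.

## What the synthetic generators emulate

The study's raw images and chromatograms are not deposited, so the
package ships generators whose outputs have known ground truth:

- **RR wells**: dark ellipsoidal seeds (inside the seed window), halo
  annuli built by growing both semi-axes by the halo thickness *t*
  (inside the capsule window only), pale background (outside both),
  Gaussian pixel noise (sd 5, clipped). The analytic annulus area
  `π((a+t)(b+t) − ab)` is exact for this construction, which is what makes
  5%-level recovery checks meaningful. Optional border-touching seeds and
  thin debris streaks (circularity ≪ 0.5) exercise the exclusion rules;
  debris is placed clear of seeds, since a streak that touches a seed
  merges with it under 8-connectivity and would change the constructed
  truth.
- **S4B fields**: red-channel signal decaying exponentially from the seed
  surface, modulated by periodic angular peaks (rays above columellae);
  the recoverable truth is the amplitude, and the reference amplitude
  defines relative intensity 1.
- **Birefringence fields**: dark background, darker seed bodies, sparse
  bright patches near seed rims placed without overlap at a density
  proportional to the genotype parameter; truth is the exact painted area.
  Patch counts are Poisson, so single images are noisy and density
  recovery is assessed over ~20 RNG seeds.
- **Sugar tables**: reference means with Rha+GalA ≈ 90% of total and Glc
  ≈ 1%, multiplicative genotype effects, per-batch drift up to 2×,
  extraction recovery shared between sugars and the ribose standard
  (which is exactly what the internal standard cancels), lognormal
  replicate noise (CV 0.08), and Bernoulli ≥5× Glc spikes.
- **Cq tables**: stable reference genes, target Cq shifted by
  `−log_E(expression factor)`, biological and technical noise of 0.1
  cycles.

Every generator draws from its own stream seeded by the cohort seed plus
a stable per-genotype hash, so cohorts are bitwise reproducible and adding
a genotype does not perturb the others.

What the generators do **not** emulate: uneven illumination and staining
gradients, out-of-focus blur, seed clumping and touching seeds,
chromatographic peak overlap, or detector nonlinearity. Passing recovery
tests therefore validate the computation, not robustness to those
real-data artifacts; on real images the threshold windows and the size
filter are the knobs a user should expect to recalibrate.

For class-recovery studies at scale, `simulate_phenotype_vector()` draws
replicate-level trait values directly (lognormal noise around the class
archetype means from `class_archetype()`) rather than rendering hundreds
of image cohorts; the image-level path is exercised end-to-end by the
pipeline, which recovers a class-B label from images and tables alone.

## Numerical choices

- Coordinates are row-major, origin top-left, 0-based; bounding boxes are
  half-open. Threshold bounds are inclusive on both ends.
- Bilinear interpolation at fractional coordinates for profile sampling;
  width samples spaced 1 px.
- Trapezoidal AUC accumulates pairwise; the linearity and
  reduction identities are asserted at 1e-12 relative tolerance (floating
  point addition is not associative), while order-symmetry identities
  (reference-gene swap) are asserted bit-exact.
- Degenerate inputs fail loudly: zero-length profile lines, empty masks in
  profile placement, non-positive pixel sizes, reference means of zero,
  non-positive dilution slopes, batches without reference samples.
- Ties in capsule pairing (a centroid on two capsules cannot happen for
  disjoint filled particles) would resolve to the containing label in the
  label image; unpaired seeds are dropped and counted.

## Problem sizes used by the tests

The suite builds everything it measures at run time: wells of 4–7 seeds at
224–512 px, S4B fields of 128–384 px, 20-seed RNG ensembles for density
and geometry recovery, 10,000 null simulations for t-test calibration, an
exhaustive sweep of all 65,536 4×4 masks plus 1,000 random 32×32 masks
against a brute-force flood-fill oracle, and a two-genotype end-to-end
cohort run twice to byte-identity. The full-scale defaults
(1024 × 1024 px at 2.5 µm/px, three replicates, three batches) are the
generator's study conditions and remain the defaults of
`cohort_spec()`.

## A worked example

```{r example, eval = FALSE}
library(mucilager)

spec <- cohort_spec(
  list(
    genotype_params("Col-0"),
    genotype_params("muci10-like",
                    halo_scale = 0.5, s4b_amplitude = 0.4,
                    birefringence_density = 0.1,
                    sugar_factors = c(Gal = 0.5, Man = 0.45),
                    expression_factor = 0.08)
  ),
  rng_seed = 1
)
res <- run_cohort_pipeline(spec, out_dir = "cohort_out")
res$tables$classes
autoplot(structure(unname(res$phenotypes), class = "phenotype_set"))
```

## Known limitations

- The Crofton perimeter differs from ImageJ's outline-tracing perimeter by
  a few percent on angular shapes; particles with circularity within that
  margin of 0.5 can be selected differently than by the original macro.
  The published account does not record ImageJ's estimator version, so
  exact agreement is not verifiable.
- The original "extreme sizes" bounds are unrecorded; the median-relative
  default is robust but not identical to the original macro.
- Automatic profile placement is a reproducible stand-in for manual line
  drawing, not a claim about where an expert would draw.
- Class boundaries are numeric anchors of a descriptive scheme; borderline
  genotypes can land differently than in the original letter assignments.
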