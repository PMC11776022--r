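---
title: "Methods: simulated placental stereology and activity-exposure models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated placental stereology and activity-exposure models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villistry)
```

## Scope and design

villistry models a three-stage observational analysis: maternal physical
activity measured by hip-worn accelerometers at three gestational
periods, term placental sections immunostained for the endothelial
marker CD34, and a regression layer relating the averaged exposures to
normalized stereological outcomes. The original specimens and recordings
are not distributable, so the package pairs every analysis stage with a
generator whose parameters *are* the study conditions; correctness is
then demonstrated by parameter recovery under those conditions. This
vignette records the models, the tunable parameters, and the design
decisions taken where the underlying procedure left a choice open.

## Synthetic slides

**Tissue geometry.** Villous tissue is carved from a smooth Gaussian
random field (iid normals blurred to a correlation length of 50 µm;
25 µm for fibrin) thresholded at the upper quantile matching the
requested pixel fraction. This gives irregular, connected blob shapes
with *exact* control of the villous fraction, which downstream density
recovery is judged against. Fibrin is drawn the same way on the
remaining pixels; staining artifacts are small dark discs confined to
the intervillous space. Class label counts always partition the canvas.

**Vessels.** Vessel cross-sections are discs with radii uniform on
4–8 µm, placed with a Poisson count proportional to villous area
(default 1324/mm², the cohort mean being emulated). The radius range is
chosen so the implied vessel area fraction, `density × E[πr²] ≈ 15.5 %`
of the villous area, matches the reported cohort mean (15.6 %) without a
separate dial. Discs must fit inside villi (checked against the distance
transform), which enforces the vessel ⊆ villi invariant; 10 % of
placements may touch a neighbour so the watershed separation step is
genuinely exercised.

**Rendering.** Classes are rendered through the Beer–Lambert model
`I = 255·10^(−M c)` with fixed published absorbance vectors for
hematoxylin and AEC (plus a normalized cross-product residual vector to
complete the basis). Villi carry hematoxylin 0.6; vessels AEC 0.9 over
hematoxylin 0.2; fibrin a faint AEC 0.15 + hematoxylin 0.05 (pale pink);
the intervillous space is near-white (≈ 250) and artifacts dark gray.
Gaussian sensor noise (sd 2) is added before 8-bit quantization. Using
the same vectors for rendering and deconvolution makes the stain
extraction analytically invertible, which the tests exploit.

Default pixel size is 2 µm/px — a deliberate desk-scale choice (real 20×
scans are ≈ 0.5 µm/px); all geometric parameters are expressed in µm so
resolution can be changed freely.

## Segmentation

* **Tissue threshold.** The 8-bit intensity threshold of 210 is applied
  to the *arithmetic mean of R, G, B rounded half-up*, with tissue
  strictly below 210. The underlying procedure states only the threshold
  value; both the luminance formula and the direction are conventions
  fixed and documented here, not inferred.
* **Classification.** The default classifier is deliberately simple and
  CPU-deterministic: decision rules on luminance and channel spread
  (artifacts are dark and achromatic; fibrin is pale tissue; the rest of
  the tissue is villous, including vessel pixels). The rules were fitted
  once on generated labelled tiles and frozen in
  `classifier_params()`. Artifact components whose border is
  predominantly background are reassigned to background, mirroring the
  treatment of intervillous staining artifacts; the pre-reassignment
  artifact fraction is retained for quality control.
* **Stain extraction.** AEC optical density via 3×3 colour
  deconvolution, clipped at zero.
* **Vessels.** Per-slide Otsu threshold computed *within villous pixels*
  (no cross-slide normalization is modelled, so per-slide adaptivity is
  the right granularity), hole filling so lumina count toward
  cross-section area, distance-transform watershed (tolerance 1) to
  split touching vessels, and a minimum instance area of 20 µm² — a
  capillary lower bound; no size filter was stated, so this default is
  explicit and configurable. An instance belongs to the villous area iff
  its centroid lies on a villi pixel.
* **QC.** A slide fails when the artifact share of tissue exceeds 0.15
  or the 90th percentile of villous AEC OD falls below 0.2 (weak
  staining); both thresholds are configurable.

## Stereology

Density of villi (%) uses the denominator villi + fibrin + intervillous.
The alternative fibrin-free denominator that appears in some figure
annotations is available behind `legend_denominator = TRUE`; the
methods-text formula is the default and the two are not silently mixed.
Excluded (manually masked) pixels are removed from every term. Counts
use the centroid rule on both whole sections and regions, with the
region denominator being the villous area inside the circle; no
unbiased-counting-frame edge correction is applied because none was
described for the procedure being modelled.

Region placement emulates "two to three 1-mm circles on villous
structures": a seeded candidate grid is scored by villous fraction
(computed by convolution), circles must reach a villous-fraction floor
of 0.30, may not overlap each other (to avoid double counting; the
source is silent on this), and are picked greedily. With stride 1 the
greedy pick provably equals the exhaustive argmax for k = 1, which the
tests check.

## Accelerometry

Freedson cut-points classify each wear minute (sedentary < 100, light
100–1951, MVPA > 1951 counts/min). Non-wear is defined as runs of ≥ 60
consecutive zero minutes and a valid day needs ≥ 600 wear minutes —
standard conventions declared here because the epoch handling of the
source device software is unstated. Diary swimming minutes are added to
MVPA but *not* to wear time, since % ST is defined on accelerometer wear
time only. Periods need ≥ 3 valid days; pregnancy exposures are
unweighted means over ≥ 2 valid periods, with subjects below that
excluded and logged. Light activity is computed and reported but kept
out of the regression models (it is collinear with the other two
fractions).

The generator gives each woman a persistent activity level: daily MVPA
minutes gamma-distributed with mean 39.5 and shape 4 (shape picked once
so the interquartile range ≈ 25 min matches the cohort summary), and a
sedentary wear-fraction normal with mean 0.723 and sd 0.076, over an
840-minute wear day. Per-woman levels are drawn by stratified
inverse-CDF sampling (one stratum per woman, shuffled), a
variance-reduction choice that keeps each woman's level random with the
correct marginal while preventing the n = 92 cohort summary from
drifting; calibration targets here are cohort-level only, as no
per-woman distributions are available. Minute counts are drawn uniformly
within the Freedson band of a multinomially drawn intensity category;
non-wear zeros flank the wear block in ≥ 60-minute runs.

## Cohort generation and the outcome model

Covariates follow the cohort summaries of the population being emulated:
age N(33.3, 5.4²); BMI log-normal with median 32.9 and IQR 4.2,
truncated at the BMI ≥ 29 inclusion threshold; GDM 34.8 %, smoking
10.9 %, PE/PIH 9.0 %; nine countries assigned round-robin with a
N(0, 1.8²) random intercept (cluster variance ≈ 3.2). Outcomes are
linear: `y = β₀ + β₁·MVPA + β₂·%ST + β₃·age + β₄·BMI + β₅·GDM + β₆·sex
+ u(country) + ε`.

The exposure coefficients of each outcome preset are the reported
adjusted estimates. The outcome SD is *derived from the reported
standardized betas*: `sd(y) = β·sd(x)/SB` agrees between the MVPA and ST
columns of every outcome (e.g. ≈ 6.6 for whole-section density, ≈ 9.3
for region density, consistent with the printed region SD 8.9), and the
residual SD is then `sqrt(sd(y)² − explained variance)`. Covariate
coefficients other than the exposures are not reported; small non-zero
defaults keep the adjustment set active without materially changing
sd(y). This calibration means simulated cohorts reproduce not only the
effect sizes but also their reported precision, so confidence-interval
coverage is a meaningful test (the suite checks 93–97 % coverage at
n = 92 over 1000 replicates).

## Statistical layer

* **Tertiles** cut at the 33.33rd/66.67th percentiles
  (linear-interpolation definition, `quantile` type 7), ties to the
  lower group. The tertile boundaries of simulated cohorts land near the
  observed ones (≈ 30.7 and ≈ 49.3 min/day MVPA) — a consequence of the
  gamma calibration, not a fitted quantity.
* **Tertile comparison** gates between ANOVA + Tukey HSD and
  Kruskal–Wallis + Bonferroni-corrected pairwise Mann–Whitney with a
  per-group Shapiro–Wilk test at α = 0.05; the source used both test
  families without stating the rule, so the gate is explicit and can be
  overridden.
* **Adjusted models** are OLS on complete cases with MVPA and % ST
  jointly, t-based 95 % CIs, standardized betas `β·sd(x)/sd(y)`, an
  optional sex-interaction check, and a hard error naming collinear
  terms on rank-deficient designs.
* **Mixed models** are random-intercept fits by maximum likelihood
  (lme4), with the cluster variance's SE taken from the observed
  information of the profiled ML likelihood (reported as NA on the
  zero-variance boundary). The random-slope LRT compares ML fits and is
  referred to χ² with df = 2 (slope variance + covariance); because the
  null pins the slope variance to the boundary of its space this
  reference is conservative, which is noted rather than corrected.
* **Sensitivity analyses** refit the adjusted model excluding smokers,
  GDM and PE/PIH in turn; the GDM covariate is dropped in the GDM-free
  subset where it is constant; undersized subsets are flagged, not
  fatal.

## Problem sizes and tolerances

Recovery runs use 500 simulated cohorts of n = 92 for the regression
layer, 92 women × 3 periods × 4 days of minute data for the
accelerometry stage, and 20 slides of 768 × 768 px at 2 µm/px
(≈ 2.4 mm² each) for imaging — sizes chosen so the whole validation
completes in minutes on one CPU while keeping Monte-Carlo error well
inside the acceptance bands (± 2 Monte-Carlo SEs for coefficient means,
10 % relative for activity summaries, ± 5 percentage points for villous
density, 15 % for vessel counts). Numerical conventions worth knowing:
pixel-centred coordinates, origin top-left, row-major; areas in µm² via
`pixel_size_um²`; exact-fraction field thresholds resolve ties by field
value order; the watershed uses tolerance 1 and ext 1; per-slide Otsu on
256 bins.

## What passing tests do and do not show

The generator's colour classes are separable by construction, so
classifier accuracy on synthetic slides (≥ 0.99 here) says nothing about
performance on real scans with stain variability, folds, blur, or
out-of-focus regions; the segmentation surface is the contract a trained
model (e.g. a small U-NET behind the same interface) would have to meet.
Vessel shapes are discs, so watershed separation is easier than for real
elongated or collapsed vessels. Activity simulation draws minutes
independently within a day and therefore understates bout structure; the
wear-time rules are exercised, but compliance patterns of real cohorts
are richer. The exposure–outcome layer is exactly linear by
construction, so recovery there validates the estimation code, not the
causal or functional form of any real association.
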