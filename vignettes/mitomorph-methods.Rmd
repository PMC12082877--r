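---
title: "Quantifying mitochondrial morphology, membrane integrity and mass: models and methods"
author: "mitomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial morphology, membrane integrity and mass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

# Overview

`mitomorph` quantifies three properties of mitochondria in two-channel
confocal optical sections of neurons, where one channel carries an outer
mitochondrial membrane (OMM) marker such as TOMM20 and the other an inner
membrane / matrix marker such as PMPCB:

* **morphology** — per-object aspect ratio (elongation) and form factor
  (branching/complexity), measured on the IMM/matrix channel;
* **membrane integrity** — Mander's M1/M2 colocalization between the two
  channels, with Costes automatic thresholding and a block-randomization
  control; a mitochondrion that has lost integrity appears in only one
  channel, which depresses both coefficients;
* **mass** — the count of marker-positive objects passing a size
  calibration, with oversized aggregated-like structures counted as
  multiple organelles.

Downstream, per-neuron metrics are compared across sex × genotype with a
random-intercept linear mixed model (animals as the grouping factor) and
Tukey-adjusted pairwise contrasts of the estimated marginal means, and
integrated by a factor analysis of mixed data (FAMD) over the quantitative
metrics plus the sex and genotype labels.

Because raw micrographs of this kind are rarely redistributable, the
package ships a synthetic-data module that generates ground-truthed images
and cohort tables with the statistical structure the analyses assume.
Every numerical claim in this vignette is recomputed by the package's test
suite or by `scripts/acceptance.R`; nothing is asserted that the code does
not itself compute.

# The synthetic image model

`simulateMitoImage()` renders `nObjects` capsules (rectangles with
semicircular caps — a standard rod/ellipse proxy for mitochondria) at
uniform random positions and orientations. Lengths are drawn uniformly
from `lengthRangeUm` (default 0.7–2.2 µm, the plausible size range of
individual mitochondria under the size rules below); the capsule width
defaults to 0.28 µm. The default pixel calibration is 0.0467 µm/px, the
value implied by equating a 15 px object with 0.7 µm. (Equating 45 px with
2.2 µm would instead give 0.0489 µm/px; the 15 px anchor wins because it
defines the detection floor. Acquisition pixel size and bit depth are
recorded assumptions of the simulator, not facts about any particular
microscope.)

Each channel has a closed-form cross-section as a function of the distance
`d` from the capsule's medial segment (capsule radius `r`, Gaussian width
`edgeSigmaPx` = σ, truncation reach 3σ):

* IMM/matrix: 1 for `d ≤ r`, then a Gaussian roll-off
  `exp(-(d - r)² / 2σ²)` out to `r + 3σ` — a filled rod with the soft edge
  of a diffraction-limited image;
* OMM: a Gaussian ridge `exp(-(d - rm)² / 2σ²)` centred at the membrane
  radius `rm = r + shellOffsetPx`, truncated at `|d - rm| ≤ 3σ`.

This geometry was chosen to reproduce two observations simultaneously:
a line profile drawn across an organelle shows **two OMM peaks flanking a
single IMM peak** (the membranes are a few tens of nanometres apart,
below the lateral resolution, so the ridge is blurred over the interior),
while the **supports of the two channels almost coincide** for an intact
organelle, giving Mander's coefficients near 1. With the default σ = 1.5 px
the ridge reach (4.5 px) covers the interior (`rm` = 4 px), so intact
objects have analytic M1 ≈ 1 and M2 ≈ 0.97–0.99; pushing `shellOffsetPx`
beyond 2 × 3σ separates the supports entirely and drives both to 0.

The `integrityProb` parameter is the probability that an object is
rendered in both channels. A non-intact object is OMM-only with
probability `singleChannelBias`, IMM-only otherwise — emulating organelles
positive for one marker but negative for the other. Integrity draws are
*nested*: one uniform deviate per object is compared against
`integrityProb`, so lowering the probability (same seed) only removes
objects from the intact set. Combined with near-total overlap of intact
objects this makes the analytic M1 + M2 provably non-increasing as
integrity falls, which the tests verify as a Spearman correlation of −1
across the series 1.0, 0.8, …, 0.2.

Noise is the standard confocal approximation: optional Poisson resampling
of signal + constant background, followed by additive Gaussian read noise,
clamped at zero. The ground truth stores the noiseless grids and the
analytic overlap fractions computed on them with support thresholds at
zero (an empty reference channel has overlap fraction 0 by convention).
Everything is bit-reproducible under a fixed seed.

What the simulator does **not** emulate: 3-D stacks, a real PSF
convolution (the Gaussian cross-section is an idealization), detector
gain variation, chromatic shift, tissue autofluorescence, or spatially
varying background. Tests passing on these images therefore validate the
*computations*, not the biology of any particular acquisition.

## The cohort model

`simulateCohort()` draws a two-level hierarchy: animals within
sex × genotype cells, neurons within animals. For each response
(aspect ratio, M2, mitochondrial count) a cell mean, a between-animal
random intercept SD (`sdAnimal`) and a residual SD (`sdResid`) are
specified. The default design is 3/3/5/3 animals contributing
30/20/24/30 neurons each — 90/60/120/90 neurons for WT male, WT female,
KO male, KO female — the study design this package targets. Default means
and SDs are chosen to be realistic for these metrics (M2 near 0.85 with a
female-KO deficit to 0.75; aspect ratio near 2; counts near 60) and are
stated once here; they are inputs to the validation simulations, not
quantities fitted to any outcome. M2 draws are truncated to [0, 1],
aspect ratios to [1, ∞), counts rounded to non-negative integers; the
configured means sit far enough from the bounds that truncation is rare
and does not visibly bias recovery.

# Segmentation and morphometrics

Objects are detected on the IMM/matrix channel. The default threshold is
Otsu's method on a 256-bin histogram of the image, implemented as the
exact maximizer of between-class variance (ties, e.g. an empty gap
between two well-separated classes, are resolved by averaging the tying
cut points); the method is pluggable (`fixed` is available) because the
upstream analysis only specifies "an automatic threshold". Connected
components use 8-connectivity by default, matching Fiji's particle
analysis; 4-connectivity is available.

## Size calibration: the 15/45 px rules

Two length rules calibrate the object set:

* components smaller than **15 px (0.7 µm)** cannot be unambiguously
  attributed to mitochondria and are discarded as background. The source
  convention is contradictory at exactly 15 px (both "≤ 15 discarded" and
  "≥ 15 retained" appear); this package retains size ≥ 15 px, because the
  retention clause defines the analyzable set.
* **45 px (2.2 µm)** is the maximal size of an individual mitochondrion;
  a retained component contributes `ceiling(size / 45)` organelles to the
  **mitochondrial mass** (the per-image object count), so aggregated-like
  structures are counted as multiple individuals by a deterministic rule.

"Size" here is a length in pixels. The default measure is the caliper
extent along the component's principal axis (`major_axis`), with skeleton
length as an alternative — the upstream description does not say which
length was used, and the choice is exposed in `segmentationConfig()`. The
caliper extent (projection range + 1 px) recovers a programmed capsule
length to within 2 px on noiseless simulations; the moment-equivalent
ellipse axis would systematically overshoot an elongated object's length
by ~15% and is therefore reported separately, not used for filtering.

## Shape descriptors

Per retained component:

* **aspect ratio** = major/minor axis of the moment-equivalent ellipse,
  computed from the eigenvalues of the pixel-coordinate covariance
  (divisor n); ≥ 1 by construction.
* **circularity** = 4π·area / perimeter², clamped to ≤ 1;
  **form factor** = 1 / circularity. The perimeter is the
  marching-squares midpoint-polygon boundary length, which has less
  staircase bias than a chain-code trace but still overestimates smooth
  boundaries by a few percent at oblique angles — a digitized disk scores
  ~0.86–0.95 rather than exactly 1. Since the form factor is used
  comparatively (across groups measured identically), this bias cancels.
* **skeleton length** from Zhang–Suen thinning, scored as 1 per axial and
  √2 per diagonal skeleton step (diagonal steps already covered by an
  axial two-step path are not double-counted).

Components with a vanishing minor axis (single pixels, collinear pixels)
are flagged degenerate: excluded from aspect-ratio/form-factor summaries
but still counted in the mass.

Line profiles (`extractLineProfile()`, bilinear interpolation) support
the calibration step: `calibrateMinObjectSize()` scans profiles for
unambiguous peaks (prominence above a stated fraction — default 20% — of
the profile's dynamic range) and returns the smallest full width at half
maximum, a documented heuristic reconstruction of "the smallest size
corresponding to a mitochondrial object".

# Membrane integrity: colocalization

With A the IMM/matrix channel and B the OMM channel:

* **Pearson r** over all analyzed pixels (the analysis unit is the whole
  image; an optional ROI mask is supported).
* **Costes automatic threshold**: an orthogonal (total-least-squares)
  regression B = aA + c is fitted (the slope must be positive, otherwise
  the search is refused with a diagnostic); T_A then descends over the
  *observed intensity levels* of A — an exact, image-adaptive step that
  makes the scan identical to an exhaustive per-level oracle — until the
  Pearson correlation of the sub-threshold pixels
  (A < T_A and B < aT_A + c) is ≤ 0. Steps where that correlation is
  undefined are passed over; reaching the intensity floor sets a flag.
* **Mander's coefficients**: M1 = Σ{A over pixels with A > T_A, B > T_B} /
  Σ{A over A > T_A}, M2 symmetric. This own-channel-above-threshold
  denominator is the thresholded (JaCoP-style) variant and the default;
  `thresholded = FALSE` gives the classic full-denominator form, and the
  two coincide at zero thresholds. M1 and M2 are invariant under positive
  rescaling of either channel with correspondingly scaled thresholds.
* **Costes randomization**: channel B is cut into square tiles
  (default 5 px ≈ one PSF width at 0.0467 µm/px; the upstream block size
  is unstated), tile positions are shuffled `nRounds` times (default 199)
  and Pearson r recomputed each round;
  p = (1 + #{null r ≥ observed r}) / (nRounds + 1), the add-one estimator,
  so p is never 0 and `nRounds = 1` gives p ∈ {½, 1}.

A caveat the calibration tests made explicit: the tile-shuffle null
assumes spatial stationarity. Two *independent* but structured images that
share a large-scale intensity profile (e.g. objects kept away from the
borders by placement margins) are genuinely positively correlated, and the
test will flag them — a known property of Costes randomization, not a bug
in the estimator. The validity check therefore pairs a structured channel
with an independent signal-free channel (background noise only), where the
null holds exactly; the rejection rate at α = 0.05 over 500 replicates
lands within [0.01, 0.12].

Whether the M1/M2 mask threshold should itself be the Costes pair or a
histogram threshold is not decidable from the upstream description; both
are selectable in `colocalize()`, Costes being the default since it is the
named control.

# Hierarchical group statistics

Each per-neuron response y is modelled as

y = Xβ + u_animal + ε,  u ~ N(0, σ_u²), ε ~ N(0, σ_e²),

with genotype, sex and their interaction as fixed effects — repeated
measures within an animal are controlled by the random intercept. The fit
profiles β and σ_e² out of the REML criterion and optimizes the single
remaining parameter λ = σ_u²/σ_e² by Brent search on the log scale over
[1e−8, 1e6] (tolerance below 1e−8 on λ, with λ = 0 checked explicitly as
a boundary candidate). Per-animal sufficient statistics make each
criterion evaluation O(animals). Tests verify the optimum beats a
64-point λ grid evaluated by an independent dense-matrix implementation,
equality with `lme4::lmer` on the study design, and equality with the
closed-form ANOVA moment estimators in balanced designs (to 1e−6).

Estimated marginal means over the 2 × 2 grid are the model-based cell
means Lβ with standard errors from the fixed-effect covariance; under
neuron-per-animal imbalance they match a generalized-least-squares oracle
rather than raw pooled means. All 6 pairwise contrasts are tested with
the studentized-range (Tukey) adjustment at k = 4 means and **containment
degrees of freedom, animals − 4**. Packages built on Satterthwaite or
Kenward–Roger approximations will give slightly different p-values —
a documented deviation; containment is simple, deterministic and
conservative at these sizes. Responses are modelled on the raw scale
(M2 is not logit-transformed) to match how such data are usually
presented; counts are modelled as Gaussian, not Poisson.

Null simulations at the study design put the family-wise error of the
adjusted contrasts in [0.02, 0.08] at α = 0.05, and a programmed
female-only M2 deficit of 2σ_e is detected in ≥ 90% of replicates while
the male contrast stays near nominal.

# Factor analysis of mixed data

Quantitative columns are standardized to mean 0, variance 1 with divisor
**n** (the convention of the R FAMD ecosystem; using n−1 would perturb
eigenvalues only at order 1/n). Each qualitative variable is expanded to
category indicators; each indicator is divided by the square root of its
category proportion and centred — the MCA scaling that gives a variable
with c categories total inertia c − 1, balancing the influence of the two
variable sets. The combined n × (K + Σc_q) matrix divided by √n is
decomposed by SVD; eigenvalues are squared singular values, row scores
are √n·U·D, quantitative correlation-circle coordinates are correlations
between each variable and the scores, and contributions are squared
loadings (categories aggregated per qualitative variable, summing to 100%
per dimension). The sign of each dimension is fixed by making its
largest-magnitude quantitative loading positive.

With 3 quantitative metrics and two 2-level labels the decomposition has
exactly K + Σ(c_q − 1) = 5 nontrivial dimensions and total inertia 5.
The three-variable quantitative set (aspect ratio, M2, count) is the
canonical one here; a narrower two-variable variant appears in some
descriptions of such analyses, but the contribution and correlation
outputs require aspect ratio, so it is included. With no qualitative
variables the analysis reduces exactly to correlation-matrix PCA, which
is the oracle used in tests. No missing-data imputation, supplementary
elements or rotation are provided.

# Numerical and design choices, collected

* Otsu ties → mean of tying cut points; constant images are an error.
* Costes scan step = one observed intensity level (exact oracle
  equality); sub-threshold correlations over fewer than 2 pixels or a
  constant sub-channel are skipped.
* REML: λ profiled on the log scale, tolerance 1e−8, boundary λ = 0
  explicit; error df = animals − 4.
* Degenerate objects: flagged, excluded from shape summaries, kept in
  mass counts. Circularity clamped to ≤ 1 before inversion.
* Aggregate splitting: `ceiling(size / 45)`, deterministic.
* FAMD divisor n; dimension signs fixed by the largest quantitative
  loading.
* Determinism: every stochastic routine takes a seed; images, tables and
  all stage CSV outputs are bit-reproducible given the same
  configuration (run manifests record configuration, versions and seeds;
  the manifest's timestamp is the one intentionally non-reproducible
  field).

## Problem sizes used in validation

The shipped validation uses 64–256 px synthetic fields with 3–12 objects,
500-replicate calibrations for the randomization test (199 rounds) and
REML recovery at the 3/3/5/3 × 30/20/24/30 study design, 200 replicates
for the power surrogate, and 400 replicates for the null family-wise
error check. These sizes give Monte-Carlo standard errors comfortably
inside the asserted bands while keeping the whole suite fast enough to
run routinely.

# Worked example

```{r example, eval = FALSE}
## ground-truthed image -> integrity readout
sim <- simulateMitoImage(imageSimConfig(fieldSizePx = c(128, 128),
                                        nObjects = 8, integrityProb = 0.7,
                                        seed = 1))
colocalize(sim$image, nRounds = 199, seed = 1)

## morphology and mass on the IMM channel
cfg  <- segmentationConfig()
mask <- thresholdChannel(immChannel(sim$image), cfg)
summarizeMorphology(labelAndFilter(mask, cfg))

## cohort -> mixed model -> Tukey contrasts -> FAMD
tab <- simulateCohort(cohortSimConfig(seed = 1))
fit <- fitMitoLMM(tab, "m2")
tukeyContrasts(fit)
famd(tab, c("aspect_ratio", "m2", "mito_count"), c("sex", "genotype"))
```

# Known limitations

* 2-D only: no optical stacks, no 3-D skeletons, no deconvolution (raw
  intensities are used for all quantification by design).
* One image = one neuron record; multi-ROI images are out of scope.
* The perimeter estimator's residual staircase bias makes absolute form
  factors comparable only within analyses run with this package.
* Containment df (not Kenward–Roger/Satterthwaite) for contrasts.
* The Costes randomization test inherits the stationarity assumption of
  tile shuffling; strongly non-stationary fields inflate it.
* The synthetic generator validates computation, not acquisition physics.
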