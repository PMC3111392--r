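---
title: "Methods: mixed-effects delta-delta-Ct analysis, screening and densitometry"
author: "qpcrlmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-effects delta-delta-Ct analysis, screening and densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrlmm)
```

# The scientific problem

Hypogonadal knockout mice (e.g. *Gpr54* or *Kiss1* null animals) differ
from wild type both in genotype and in their hormonal milieu, because
they fail to undergo puberty. A transcript that looks "knockout
regulated" in intact animals may in reality only track circulating
testosterone. The experimental remedy is a factorial design: castrate
wild-type and knockout males, implant either an empty or a
testosterone-releasing capsule, and measure transcription by QPCR in all
four genotype-by-hormone cells, always pairing each test gene with a
stably expressed loading control. qpcrlmm implements the statistical
machinery for exactly this design, plus the discovery-array screen that
selects candidate genes and the chromogenic image densitometry used for
anatomical validation.

# The Ct mixed model

The unit of observation is one raw cycle-threshold value
$Y_{ijklm}$ for gene role $i$ (loading control or test gene), genotype
$j$ (wild type or knockout), hormone arm $k$ (placebo or testosterone),
animal $l$ nested in $(j,k)$, technical replicate $m$:

$$Y_{ijklm} = \mu + \delta_i + \gamma_j + \tau_k + \delta\gamma_{ij} +
\delta\tau_{ik} + \gamma\tau_{jk} + \delta\gamma\tau_{ijk} +
\alpha_{l(jk)} + \varepsilon_{m(ijkl)}$$

with $\alpha \sim N(0, \sigma_\alpha^2)$ a per-animal random intercept
(biological replication) and $\varepsilon \sim N(0,
\sigma_\varepsilon^2)$ independent technical noise. We store the fixed
effects in a reference-cell (treatment-contrast) parameterization with
loading control / wild type / placebo as reference levels, so that each
coefficient is directly a delta-delta-Ct quantity:

* `gene:genotype` ($\delta\gamma$) is the $\Delta\Delta C_t$ of knockout
  versus wild type in the placebo arm;
* `gene:genotype + gene:genotype:hormone` is the same contrast in the
  testosterone arm;
* `gene:hormone` ($\delta\tau$) is the hormonal $\Delta\Delta C_t$ within
  wild type, and adding the three-way term gives it within the knockout.

Because one PCR cycle is a doubling, $-\Delta\Delta C_t$ is the log2
fold change. We report fold changes as $2^{|\Delta\Delta C_t|}$ together
with a direction (`Up` = higher expression in the knockout or with
testosterone), and a 95% CI that exponentiates
$|\Delta\Delta C_t| \mp z\,\mathrm{se}$ with $z = 1.959964$. A normal
rather than a $t$ quantile is used: the contrasts of interest are
within-animal (the animal intercept cancels between the test gene and
the control measured in the same animal), so their effective degrees of
freedom are governed by the technical replication ($n - p \approx 88$ in
the default design), where the difference between $z$ and $t$ is below
half a percent on the fold scale. The CI lower bound may fall below 1
for weak contrasts; it is printed as-is.

## Fitting: profiled REML in one dimension

With a single random intercept the marginal covariance is
$\sigma_\varepsilon^2 (I + \lambda Z Z^\top)$,
$\lambda = \sigma_\alpha^2/\sigma_\varepsilon^2$, and both the ML and
the REML criterion can be profiled analytically over $\beta$ (by
generalized least squares) and $\sigma_\varepsilon^2$, leaving a
one-dimensional criterion in $\log\lambda$. `fit_mixed_model()`
maximizes it with Brent's method on $\lambda \in [10^{-8}, 10^8]$ and
additionally evaluates the boundary $\lambda = 0$, so
$\hat\sigma_\alpha$ is non-negative by construction and degenerates
cleanly to zero when the data carry no animal variance. Because animals
are independent blocks, $V^{-1}$ and $\log|V|$ have closed per-animal
forms ($\log|I + \lambda J| = \log(1 + \lambda n_l)$), making each
criterion evaluation a small fixed-cost linear-algebra step; a full fit
takes a few milliseconds, which is what makes the resampling-heavy test
suites practical. The default convergence tolerance is a relative
criterion change of $10^{-10}$ (exposed via `control`); the tests verify
that the optimizer is never beaten by an exhaustive
$200 \times 200$ grid over $(\sigma_\alpha, \sigma_\varepsilon) \in
[0,2]^2$ and that coefficients, variance components and both
log-likelihoods agree with an independent general-purpose mixed-model
fitter to six decimals.

## Testing: ML likelihood ratios, chi-square reference

Reported coefficients and variance components come from REML, but every
likelihood-ratio comparison of fixed-effect structures fits *both*
models by ML, because restricted likelihoods are not comparable across
different fixed-effect design matrices. Statistics are referred to the
chi-square distribution with df equal to the number of dropped terms;
no Satterthwaite/Kenward-Roger correction is applied. The practical
consequence, which we measure rather than hide, is a mildly
anticonservative finite-sample level: at the default design (3 animals
per cell, 4 technical replicates, 96 observations) the df = 1 tests
reject a true null about 5.7% of the time at nominal 5%. Multiple-test
adjustment uses Benjamini-Hochberg step-up, applied across the genes
analyzed against one loading control within one knockout arm — the
natural analysis family here; applying it over a wider family (both
controls, both arms) would be more conservative, and the choice is
surfaced rather than buried.

## Classification into the four regulation classes

`classify_regulation()` applies a fixed decision tree to one
gene/control pairing:

1. LRT of the three-way term. Significant at $\alpha$ ⇒
   **both, interacting**: report all four within-group contrasts
   (genotype effect within each hormone arm, hormone effect within each
   genotype).
2. Otherwise, from the model without the three-way term, drop
   `gene:genotype` and `gene:hormone` in separate LRTs: both significant
   ⇒ **both, independent**; only the hormone term ⇒ **hormone only**;
   only the genotype term ⇒ **genotype only**; neither ⇒ **none**.

The omnibus p-value is the joint df = 3 LRT of all three
gene-interaction terms. The main-effect contrasts reported for the
non-interacting classes come from the no-three-way model, which is also
the model in which they are interpretable. The fold-change filter
("report only changes of at least 1.5-fold") is applied inclusively to
the 2-decimal rounded point estimate, matching how such tables are
conventionally printed.

This tree has a quantifiable operating characteristic worth knowing: a
pure single-effect gene is recovered only when its own LRT rejects *and*
both nuisance LRTs do not, so even with power near 1 the expected
recovery rate is about $(1 - 0.057)^2 \approx 0.89$ at these sample
sizes — the cost of protecting the interaction class. The interaction
and both-independent classes recover at 95-99%. Null genes classify as
`none` about 84% of the time ($\approx (1-0.057)^3$), with the remainder
spread over spurious single-effect calls.

# The discovery screen

`screen_comparisons()` reproduces the array-stage funnel on a
pre-summarized probe-by-sample log2 matrix: quantile normalization
(every sample forced onto the row-mean order-statistic distribution,
ties averaged; delegated to limma and idempotent by construction), then
for each of the four comparisons — wild type vs both knockouts pooled,
wild type vs each knockout, knockout vs knockout — a per-probe unpaired
pooled-variance Student t-test, BH adjustment within the comparison, and
selection at fold change ≥ 1.5 with adjusted p < 0.05. The union of
per-comparison selections is the "unique genes" candidate set.
Upstream probe-level preprocessing (GC-RMA, exon/gene summarization) is
out of scope: the screen consumes the summarized matrix and carries a
user-supplied gene/exon level tag. The historical screen also admitted
manually chosen volcano-plot outliers; that subjective step is not
automated — instead a ranked near-miss list is emitted for review.

# Chromogenic densitometry

The in situ hybridization pipeline works on 8-bit RGB brightfield
images: take the red channel (least counterstain interference), invert
it (255 − x) so nuclei are bright, estimate the smooth background by
grayscale morphological opening with a disk (the rolling-ball
equivalent; radius configurable, default 15 px, and at least ~3x the
object radius) and subtract it, threshold with Otsu's method on the
256-bin histogram (foreground strictly above the cut; ties between
equally good cuts resolved by their mean, so a clean two-level image
thresholds between the modes), split touching nuclei by a
distance-transform watershed (pixel-conserving by construction), and
measure each object's mean intensity on the *original* red channel. The
absorbance density is $OD = \log_{10}(I_0) - \log_{10}(I)$ with a
single illumination constant $I_0$ per batch — supplied, or estimated
as the modal red background intensity. Base 10 is the optical-density
convention; any base rescales all ODs equally and leaves the two-group
t-tests unchanged. Objects below 20 px (configurable) are discarded.
Group comparisons (antisense vs sense probe, genotype vs genotype) use
the same pooled-variance two-sided t-test as the blot and
region-intensity helpers; both object-level and section-mean units of
analysis can be formed from the per-object table, and both are
reported by the examples since either unit is defensible. Known limitations: the background estimate is unreliable
within one ball radius of the image border (morphological truncation),
and region masks for anatomical quantification are user-supplied —
no atlas registration is attempted.

# The synthetic-data generators

Every stage is exercised against generators with known ground truth, so
the package is testable without any external download.

* `generate_ct_dataset()` draws Ct tables from the model above. The
  default study conditions are 3 animals per cell and 4 technical
  replicates (3 in the intact discovery design), typical replication
  for this kind of experiment. The variance components
  default to $\sigma_\alpha = 0.15$ and $\sigma_\varepsilon = 0.3$
  cycles — fixture choices in the plausible range for hypothalamic
  micro-dissection QPCR, not published estimates, since the study does
  not print its variance components. Non-detects are never simulated
  and never imputed: the model stage rejects non-finite Ct explicitly,
  because no principled imputation rule exists for them.
* `generate_expression_matrix()` plants mean log2 shifts between named
  screen groups on Gaussian noise; the truth table records every
  planted shift.
* `generate_stained_image()` plants disk "nuclei" whose noise-free red
  mean is $I_0 10^{-OD}$, with optional deliberately touching pairs at
  1.5 radii separation to exercise the watershed, Gaussian pixel noise,
  and 0-255 clipping with a warning.

What the generators deliberately do **not** emulate: amplification
curves or primer efficiencies (the analysis starts from Ct), probe-level
array artifacts, spatially varying chromogen texture within a nucleus,
or anatomically structured backgrounds. Passing the recovery suites
therefore demonstrates correctness of the estimators under the stated
model, not robustness to violations of it (e.g. efficiency differences
between test and control amplicons, which bias any delta-delta-Ct
method).

# Numerical and design choices, in one place

* Profiled-likelihood optimizer: Brent on $\log\lambda \in
  [\log 10^{-8}, \log 10^8]$; explicit boundary evaluation at
  $\lambda = 0$; criterion tolerance $10^{-10}$.
* LRT statistics are clamped at 0; two fits that differ only by a
  coefficient that is exactly zero can differ by ~$10^{-10}$ in
  log-likelihood through different Cholesky factorization sizes.
* Quantile-normalization ties: averaged reference values (limma's
  `ties = TRUE`).
* Otsu ties: mean of the maximizing cut points; foreground is strictly
  above the threshold.
* Watershed: tolerance 1 intensity level on the distance map, which
  splits planted 1.5-radii pairs while not oversegmenting single noisy
  disks.
* Degenerate two-group comparisons: zero pooled variance gives p = 1
  for equal means and p = 0 with a warning otherwise.
* Reproducibility: every generator takes an explicit seed; the pipeline
  driver derives per-stage seeds from one top-level seed and writes a
  JSON manifest sufficient to reproduce any artifact byte-identically.

# Problem sizes used by the validation suites

The recovery suites fit 200 simulated datasets per planted effect
(medians of fitted fold changes), 5000 replicates for the null
calibration of the LRT, 500 for CI coverage, 200 per class for the
classifier, 50 images for the exhaustive Otsu cross-check and 20 images
per planted density for end-to-end OD recovery. These sizes put the
Monte-Carlo error comfortably below the tolerances being asserted while
keeping a full run in the low minutes on one core.
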