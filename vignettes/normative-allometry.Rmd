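---
title: "Normative allometry of limbic structures: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative allometry of limbic structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroallom)
```

## The scientific problem

Groups that differ in total brain volume (TBV) — males vs females, or
carriers of supernumerary sex chromosomes (SCA) vs euploid controls — cannot
be compared on raw regional volumes without confounding regional effects
with global ones. Because subcortical structures scale *non-linearly* with
brain size, the two textbook corrections can actively mislead:

* **Normalization** (dividing by TBV) assumes proportionality. If a region
  scales hypoallometrically (power-law exponent $\beta_1 < 1$), the volume
  fraction of a larger brain is genuinely smaller, so dividing builds a
  spurious group effect out of any TBV difference.
* **Covariation** (TBV as a linear covariate) assumes a linear
  volume–volume relationship, which is the first-order approximation of the
  power law and behaves well over moderate TBV ranges.
* **Allometric adjustment** fits the power law itself in an *independent*
  normative sample,
  $$\log_{10} V_{region} = \beta_0 + \beta_1 \log_{10} V_{tbv} + \epsilon,$$
  and compares groups on deviations (observed minus predicted log volume).

`neuroallom` implements all three, vertex-wise surface analogues, and a
synthetic cohort generator calibrated to a published seven-karyotype SCA
study design, so that every stage of the pipeline can be exercised and its
statistical behaviour measured without access to the original MRI data.

## The tiered normative model

`allom()` is the core fitting function. With `tier = "auto"` it applies a
sequential backward selection of sex terms: an interaction model
($\beta_3\,\log_{10}V_{tbv}\times\mathrm{sex}$), then an additive sex model
($\beta_2\,\mathrm{sex}$), then the simple model, dropping a term whenever
its two-sided Wald p-value exceeds `alpha` (default 0.05). Sex is coded
female = 0, male = 1; only labels, p-values, and predictions — all invariant
to the coding — feed downstream. `classify_scaling()` tests
$H_0\!:\beta_1 = 1$ with a t-interval: *hypoallometric* when the upper
confidence bound is below 1, *hyperallometric* when the lower bound exceeds
1, *isometric* otherwise.

```{r allom-demo}
cfg  <- sca_config(seed = 1)
norm <- generate_subjects(cfg, sample = "normative")
fit  <- allom(norm, "amygdala", tier = "auto")
fit
classify_scaling(fit)
```

## Vertex-wise surface allometry

Shape is analysed as local surface area at 5245 mesh vertices (right/left
amygdala 1405/1473, right/left hippocampus 1215/1152). Each vertex is
modelled on the log total bilateral surface area *of its own region* —
amygdala vertices on total amygdala area, hippocampus vertices on total
hippocampus area. The same three-tier sex structure applies, but the tier
is chosen *globally*: the interaction term's p-values are BH-corrected
across all vertices, and only if no vertex survives does the procedure step
down. A single shared tier keeps the per-vertex coefficients comparable
across the surface. Group contrasts are then per-vertex two-group
regressions on deviations, BH-corrected separately for each contrast within
each bilateral region (q = 0.05), and summarized as binarized
contraction/expansion masks. Spatial convergence across karyotypes is
quantified by Pearson correlation of the *uncorrected* t-maps, per region.

## What the generator emulates, and how it is calibrated

`sca_config()` encodes the study conditions; `generate_subjects()` and
`generate_vertex_table()` draw from them. The calibration is tied to the
published per-group descriptive statistics and scaling results, with every
remaining free parameter fixed once, by the reasoning below:

* **Group sizes** 87/79/28/56/25/19/5 (XX, XY, XXX, XXY, XYY, XXYY, XXXXY)
  and an independent normative sample of 79 (34 F). The printed per-group
  counts sum to 299; the source's narrative total of 298 is internally
  inconsistent with its own tables, and the per-group counts win because
  the SD calibration (SD = SEM·$\sqrt{n}$) depends on them.
* **TBV** is log-normal per group: $\log_{10}$TBV is Gaussian with a
  delta-method correction so the *raw-scale* group mean equals the printed
  mean (1261, 1392, 1179, 1287, 1418, 1291, 1131 cm³).
* **Scaling law**: exponents 0.89 (amygdala) and 0.76 (hippocampus);
  intercepts anchor the XY group mean exactly on the law. Karyotype offsets
  (log10 units, 0 for XX and XY) are derived from the printed group means
  relative to that law, so large-sample group means reproduce the published
  table. One published value cannot be honoured simultaneously: with
  $\beta_1 = 0.76$ and the XY anchor, the XX hippocampus mean comes out
  4.24 cm³ rather than the printed 4.30 — the published euploid means are
  not exactly collinear with the published exponent.
* **Residual SD** of log10 regional volume: decomposing the published
  within-group SDs as $\beta_1^2\,\mathrm{var}(\log_{10}\mathrm{TBV}) +
  \sigma^2$ gives $\sigma \approx 0.030$ (amygdala) and 0.031
  (hippocampus); these are the defaults.
* **Surface link**: $S = c\,V^{2/3}10^{\varepsilon}$ (geometric baseline,
  $c = 10$). The coupling noise SD is *computed in closed form* from the
  config so that the log-scale volume–surface correlation equals the
  published targets (0.97 amygdala, 0.89 hippocampus): with
  $\sigma_x = \mathrm{SD}(\log_{10}V_{region})$ over the core mixture,
  $\tau = \tfrac{2}{3}\sigma_x\sqrt{1/r^2 - 1}$. Nothing is hand-tuned;
  changing group sizes or offsets re-derives $\tau$.
* **Vertex areas**: each vertex has a true local exponent drawn from a
  spatially smooth field (Gaussian-kernel bumps over ellipsoidal point
  clouds, length scale 5 mesh units, range clipped to [0.6, 1.4]) — a
  cheap stand-in for diffusion-smoothed surface data. Karyotype focal
  fields are smooth bumps at fixed anatomy-like positions (rostral
  amygdala; mid-body and caudal hippocampus contraction, a small caudal
  expansion patch), shared in location across SCA karyotypes, amplitude
  −0.04 log10 units with XYY at half strength. Vertex residual SD is 0.03
  log10 units (~7% CV), a plausible post-smoothing noise level. Per
  subject, vertex areas are renormalized so their regional sum equals the
  subject's total bilateral area (stored in cm²; vertices in mm²).
* **Covariates**: ages are truncated normal (mean 12.7, SD 5, range 5–26)
  in the core cohort and uniform on 12–14 in the normative sample; Tanner
  stage is a noisy monotone function of age; 3 XY, 1 XX and 1 XXY subjects
  have missing Tanner stage, mirroring the robustness-analysis exclusions.

What the generator does **not** emulate: hemispheric asymmetry beyond
labels, spatially correlated vertex noise (real smoothing induces it; here
noise is iid before renormalization), karyotype-specific age structure,
segmentation error, or any image-level artefact. Passing tests therefore
demonstrate the statistical machinery's behaviour under the declared
generative model, not robustness to real-data pathologies.

## Numerical and design choices

* **OLS engines.** Single fits use `stats::lm`; the mass-univariate vertex
  fits use a vectorized normal-equations solver sharing one design matrix
  per structure (verified against `lm` to 1e-8 in the tests).
* **Multiplicity.** BH via `stats::p.adjust`; Bonferroni as
  $\min(1, m\,p)$ with the family size $m$ an explicit argument (default 5,
  the SCA contrast family) because $m$ need not equal the number of
  p-values computed in a call. The raw post-hoc battery is BH-corrected
  within region; the adjusted batteries use Bonferroni, following the
  source analysis. The deviation analysis' contrast family is ambiguous in
  the source (XXXXY excluded from deviations yet five contrasts corrected
  for); the battery runs all five SCA contrasts with $m = 5$ by default and
  leaves both knobs configurable.
* **Sex contrasts.** Raw and allometric-deviation XX-vs-XY contrasts are
  evaluated in the core sample; normalization and covariation sex contrasts
  in the normative sample, as in the source analysis.
* **Leakage guard.** `allometric_contrast()` refuses a normative model
  whose training subjects overlap the core sample (overridable), since
  deviations tested on the training sample are not exchangeable across
  groups.
* **Degenerate inputs.** Zero-variance vertices are excluded from tier
  gates and flagged; constant t-maps yield `NA` correlations with a
  warning; a zero standard error in `classify_scaling()` falls back to the
  point estimate with a degenerate-interval warning; one-way ANOVA on
  groups with no between-group variation reports F = 0.
* **Determinism.** All randomness flows from one integer seed; module
  streams are derived offsets of it, and identical configurations produce
  bit-identical cohorts. Configurations serialize to YAML at 17 significant
  digits; a serialized config is a fixed point after one read/write cycle.

## A documented limitation: training-error leakage in deviation tests

Deviation-based normative modelling shares one estimated model across all
test subjects. The estimation error $(\hat\beta_1 - \beta_1)$ multiplies
each group's mean log-size offset, producing a *correlated* shift in the
deviations of any group whose size distribution differs from the normative
centre. With a normative sample of 79 and contrast groups of ~50–80 this
inflates the nominal 5% deviation test to roughly 7% when groups differ in
TBV; at contrast groups of 200 the inflation reaches ~17%. Two consequences
for the validation suite:

* the embedded-null calibration runs (type-I error ≈ 0.05; vertex FDR
  ≤ 0.05 per family) equalize TBV distributions across groups in addition
  to zeroing offsets and focal fields, because that is the condition under
  which the downstream null actually holds;
* the normalization-discordance experiment (hypoallometric generation,
  groups differing only in TBV, n = 200 per group) uses a normative sample
  of 400 so that normalization's intrinsic ratio bias — the mechanism under
  study — is not confounded with normative estimation noise.

The vertex-wise analogue of the same mechanism spreads weak, spatially
random significance beyond the focal fields when group sizes differ in
total surface area; the focal masks remain strongly enriched on the
generating bumps, and the XYY contrast remains clearly attenuated, but
mask *extent* should be read with this in mind.

## Problem sizes used by the validation suite

Exponent-recovery runs use 100 normative samples of 79; coupling
calibration uses 50 core samples of 299; the embedded-null calibration uses
500 simulated cohorts at the study's sizes for the bulk contrast and 500
cohorts on a 160-vertex mesh for the vertex FDR; the discordance experiment
uses 30 replicates of two groups of 200. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while keeping
the default test run around a minute of compute.

## Reproducing the headline quantities

`scripts/acceptance.R --seed <int> --out <path>` regenerates 50 default
core cohorts and writes the mean volume–surface Pearson correlations per
region (the two quantities the generator is calibrated to deliver) as
JSON. The README shows a full worked example of the bulk-volume battery
and the vertex-wise pipeline.
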