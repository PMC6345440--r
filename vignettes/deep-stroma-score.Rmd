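---
title: "The deep stroma score: model, assumptions, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deep stroma score: model, assumptions, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepstroma)
```

## The problem

Hematoxylin–eosin (H&E) slides exist for essentially every colorectal cancer
(CRC) patient, and the *stromal* compartment — everything in the tumour that
is not tumour epithelium: desmoplastic stroma, lymphocytes, adipose tissue,
debris, muscle — carries prognostic information that routine reporting does
not quantify. `deepstroma` implements a complete pipeline that turns an H&E
image of a tumour region into a single prognostic number, the **deep stroma
score**, and validates every stage of that pipeline on synthetic data with
known ground truth.

The pipeline has four stages:

1. **Stain normalization** (Macenko): all images are mapped to a common H&E
   colour frame before any classification.
2. **Nine-class tissue classification**: a trainable classifier emits a
   softmax activation vector over the classes ADI, BACK, DEB, LYM, MUC, MUS,
   NORM, STR, TUM (fixed alphabetical order, used everywhere).
3. **Tissue decomposition**: large multitissue regions (1,500 × 1,500 px at
   0.5 µm/px) are covered with partially overlapping 224 px sliding windows;
   the mean tile activation is the region's composition estimate, and a
   patient's vector is the componentwise **maximum** over their regions.
4. **Scoring and survival analysis**: per-class univariable Cox hazard
   ratios and Youden-optimal cutoffs are fitted on a training cohort and
   frozen; the score is applied, dichotomized at the frozen training median,
   and assessed in multivariable Cox models.

## The score

Let $a_c \in [0,1]$ be patient-level pooled activation of class $c$,
$\mathrm{HR}_c$ the hazard ratio from a univariable Cox model with the
continuous (nonthresholded) activation as predictor, and $\tau_c$ the cutoff
maximising the Youden index $J = \text{sensitivity} + \text{specificity} - 1$
for predicting the endpoint's event indicator. With
$\mathcal{S} = \{c : \mathrm{HR}_c > 1\}$ the harmful classes,

$$ S \;=\; \sum_{c \,\in\, \mathcal{S}} \mathrm{HR}_c \cdot
   \mathbf{1}[a_c > \tau_c], $$

an HR-weighted count (0 to $|\mathcal{S}|$ classes) of above-threshold
nontumour components. Patients are called *high* when $S$ strictly exceeds
the training-cohort median, and that median is frozen for any validation
cohort.

The package ships the published reference constants as a frozen model:

```{r}
sm <- published_score_model()
summary(sm)
```

Five classes carry HR > 1. An activation profile exceeding exactly the DEB,
LYM, and STR cutoffs scores $5.967 + 1.226 + 1.154 = 8.347$, which is also
the published median split value — a useful worked example because it is the
unique subset sum of the published weights equal to that median:

```{r}
a <- sm$cutoff / 2
a[c("DEB", "LYM", "STR")] <- sm$cutoff[c("DEB", "LYM", "STR")] * 1.5
compute_score(sm, a)
```

### Conventions chosen where the procedure was open

* **"Above threshold" is strict** (`a > tau`), and **"high" is strict**
  (`S > median`); boundary cases default to the low-risk group.
* The ROC label for cutoff selection is the endpoint's **event indicator at
  end of follow-up**; no time horizon is imposed.
* The Youden tie-break "closer to the median" refers to the median of the
  predictor's values; any residual tie resolves to the smaller cutoff.
* Tied event times use the **Efron** approximation in all Cox fits.
* UICC stage enters multivariable models as a continuous 1–4 covariate, sex
  as binary (0 = female, 1 = male), and age in decades (years/10).
* Subjects with missing endpoint data are excluded, never imputed.

## Stain normalization

Stain mixing is modelled in optical density, $\mathrm{OD} =
-\log_{10}(\max(I,1)/I_0)$ with $I_0 = 255$; zero intensities are clamped to
1 before the log. The stain matrix (two unit OD vectors, hematoxylin and
eosin) is estimated by the Macenko construction: SVD of the tissue-pixel OD
cloud (pixels with max-channel OD above $\beta = 0.15$), robust percentile
angles ($\alpha = 1$) in the leading singular plane, and hematoxylin
identified as the column with the larger blue-channel component.
Concentrations are solved by least squares with projection onto the
nonnegative orthant; the per-stain 99th percentiles serve as reference
concentrations for rescaling into a target profile.

Two numerical choices go beyond the bare construction:

* **Exposure correction.** A global illumination change adds an achromatic
  (equal-channel) OD offset. When an image shows unstained glass (≥ 100
  pixels with max-channel OD ≤ β), the gray component of the glass OD is
  subtracted before estimation, which makes the estimated stain *directions*
  stable (< 1°) under, e.g., a 0.8× intensity rescale. On fully stained
  fields with no visible glass the exposure is not identifiable from the
  stains and no correction is applied — a documented limitation.
* **Reference profile.** A fixed target profile, estimated once from a
  bundled synthetic reference patch and frozen as JSON
  (`inst/extdata/default_stain_profile.json`), makes normalization
  reproducible with no external data.

Degenerate inputs fail loudly: an (almost) all-white image has too few
stained pixels, and a single-stain (rank-1) OD cloud has no second stain
direction to estimate.

## The classifier

The reference implementation of this analysis used an ImageNet-pretrained
deep network; pretrained weights and GPUs are deliberately out of scope
here. The package's desk-scale classifier is a **19-dimensional texture
summary** (per-channel intensity moments, dark/mid/white fractions, gradient
energy and edge density, two-scale contrast, blue chroma, near-white block
fraction, and gray-level autocorrelations at lags 3/8/16 px) feeding a
**single-hidden-layer softmax network** (32 tanh units) trained by
mini-batch SGD with momentum 0.9. The `training_config()` contract — split
fractions (70/15/15), batch size, learning rate, epochs, flip augmentation
flags, seed — is honoured exactly, and the per-epoch loss and validation
accuracy (including epoch 0, the untrained network) are logged in the model
object.

The softmax output is the `ActivationVector` used downstream: nine values in
$[0,1]$ summing to 1, argmax = predicted class, ties broken by the fixed
class order. Horizontal/vertical flips augment training; the texture
features are themselves flip-invariant by construction, so prediction is
stable under mirroring.

A second augmentation matters for decomposition: sliding windows straddling
block borders see two-class *mixtures*, and a network trained on pure
patches is overconfident there, making mean activation a poor composition
estimate. Training therefore also includes composite two-class patches
(random side-by-side splits at fractions 0.3–0.7) with **soft targets equal
to the area fractions** (`mixtures` in `training_config()`, default one
composite per original patch). This teaches the softmax to respond
compositionally and lifts the per-class fraction-vs-activation Spearman
correlation on synthetic regions from ~0.5–0.8 to > 0.9.

Evaluation machinery follows the standard definitions: confusion matrix
over the fixed class order with accuracy = trace/total, and per-class
one-vs-rest ROC statistics over $k = 25$ random class-stratified subsets —
AUC from the class's softmax activation (rank-based, equal to the
trapezoidal area), sensitivity/specificity/PPV/NPV from argmax predictions,
each summarised as median with 5th/95th percentiles.

## The synthetic-data generator

The generator makes three things: patches, regions, and cohorts. It emulates
the *structure* of the real data — class-labeled 224 px patches in
class-named folders, 1,500 px multitissue regions, clinical tables with
stage/sex/age and survival endpoints — not its photorealism. Scanner and
batch effects beyond a global exposure shift are out of scope.

**Patches.** Each class is an archetypal two-stain texture: hematoxylin and
eosin concentration fields built from disks (LYM small and dense, TUM large
and sparse), rings (ADI vacuoles, NORM glands), oriented fibres (MUS broad,
~26 px period; STR narrow, ~9 px), speckle clumps (DEB), smooth pale chroma
(MUC), or near-zero (BACK), rendered through Beer–Lambert with the canonical
H&E OD vectors plus Gaussian sensor noise. Because mixing happens in OD
space with exactly two stain vectors, the Macenko estimator can be validated
against known ground truth on these images. Each class is separable from
every other by at least one documented scalar statistic (e.g. dark-pixel
fraction separates LYM from ADI by ≥ 0.10), which is what makes the ≥ 90%
classifier-accuracy acceptance meaningful rather than incidental.

**Regions.** A region is a randomised mosaic of 150 px square blocks
(Voronoi-like, so sliding-window tiles are class-dominated), with block
counts apportioned to the requested area fractions by largest remainder —
accurate to ±1 block (±1 percentage point at the defaults) — and a pixelwise
ground-truth mask.

**Cohorts.** Patient $i$ has 1–3 region activation vectors drawn from a
sparse Dirichlet prior (total concentration ≈ 0.97, TUM-weighted), pooled
by componentwise maximum; stage ~ uniform 1–4; sex ~ Bernoulli(½); age ~
Normal(68, 10) truncated to [30, 95]. Event times are exponential with
hazard
$h_0 \exp(\sum_c \beta_c a_c + \beta_\text{stage}\,\text{stage} +
\beta_\text{sex}\,\text{sex} + \beta_\text{age}\,\text{age}/10)$,
censored by an independent Uniform(0, C) time. Defaults: $h_0 = 0.03$ per
month, $C = 120$ months, all $\beta = 0$.

Two generator choices deserve justification:

* **The sparse activation prior.** Nothing is published about the
  distribution of activation vectors in real cohorts; the prior is a
  stand-in, not an estimate. Total concentration ≈ 1 makes each region
  dominated by one or two tissues — which is how manually sampled tumour
  regions behave — and gives per-class activations enough dispersion
  (sd ≈ 0.2) that univariable hazard ratios are estimable with useful
  precision at the n = 2,000 scale used by the recovery tests.
* **Exponential survival.** A constant baseline hazard is the simplest law
  consistent with proportional hazards; the recovery tests only require
  that the planted log-linear structure be correctly specified.

What passing tests on these synthetics *does* show: the estimators are
correct on data satisfying their assumptions (two-stain colour model,
separable textures, proportional hazards). What they *cannot* show: that
real H&E tissue is this separable, or that the published hazard ratios
generalise — that requires the real cohorts, which are intentionally outside
this package's scope.

## Numerical choices and degenerate inputs

* Youden candidates are midpoints of consecutive sorted unique values; the
  maximiser is verified in tests against an exhaustive brute-force oracle.
* Score-model and stain-profile JSON is written with 17 significant digits,
  so freezing and reloading reproduces scores and group labels bit-exactly.
* Per-stage Cox fits report `"insufficient events"` for strata with fewer
  than 10 events instead of failing.
* The pipeline's normalization stage passes background-only images through
  unchanged (stain estimation on glass is meaningless by construction),
  while the bare `normalize_stains()` API propagates the estimation error.
* All randomness flows from explicit integer seeds through one internal
  helper; identical configuration and seed reproduce bit-identical patches,
  cohorts, score JSON, and pipeline manifests.

## Problem sizes used in the shipped validation

The test suite exercises the pipeline at desk scale, chosen so the whole
suite runs on one CPU in well under half an hour: classifier acceptance uses
9 × 200 patches (70/15/15 split, 30 epochs); decomposition fidelity uses 50
regions of 1,500² px with Dirichlet(0.5) compositions, requiring per-class
Spearman ρ ≥ 0.8 between true area fraction and mean activation; hazard
recovery uses 50 replicate cohorts of n = 2,000 per planted effect (HR 2
and 6, within ±40% in ≥ 95% of replicates; null CI coverage ≥ 90%); and the
score stage uses a planted-effect cohort of n = 1,000. Unit tests use
smaller fixtures (24 patches per class).

## Known limitations

* The texture archetypes are caricatures: real H&E patches vary in focus,
  compression, folding, and staining protocol in ways the generator does
  not model.
* The classifier's hand-designed features are tuned to textures that differ
  in simple statistics; on real data a learned representation is expected
  to be necessary (the architecture is configurable, the feature extractor
  is not).
* Exposure correction requires visible glass; fully stained fields are
  normalized under the assumption that their white point equals $I_0$.
* The published constants ship as given to three to five decimals; scores
  computed from them inherit that precision.
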