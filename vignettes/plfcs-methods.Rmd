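---
title: "Methods: proportional connectivity loss, tau SUVR and the synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proportional connectivity loss, tau SUVR and the synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plfcs)
```

## The analysis model

Each subject contributes a parcellated BOLD time series (T timepoints × N
atlas regions).  The connectivity model is deliberately plain: static
full-scan Pearson correlation between every pair of regional signals,
giving an N×N association matrix, Fisher z-transformed
(z = arctanh r) to stabilise variance.  Self-connections are stored as 0
and excluded everywhere: arctanh(1) is infinite and a node is not among
its "other nodes".  A node's functional connection strength is its
weighted degree over absolute weights,

$$\mu_i = \sum_{j \ne i} |z_{ij}|,$$

with no thresholding or sparsification; negative correlations contribute
through the absolute value.  Group-level strength is the element-wise mean
of subject strengths.

The proportional loss of functional connectivity strength compares a
subject's node strengths with a normal-control (NC) baseline:

$$\mathrm{Loss}_i = \frac{\mu_i - \sigma}{\sigma}.$$

Two choices are genuinely open here, and the package makes both explicit
rather than silently picking one:

* **Baseline granularity.**  The textual definition makes σ a single
  scalar, the node-average of the NC group-mean strengths
  (`variant = "global_scalar"`, the default).  Under that definition
  Loss_i across regions is dominated by each node's own strength relative
  to the global mean — hub regions have positive Loss, weak regions
  negative Loss, essentially reproducing the strength profile.  A per-node
  baseline (`variant = "per_node"`, σ_i = NC group-mean strength of node
  i) instead measures each node's *proportional change from its own
  baseline*, which is what a hub-vulnerability analysis needs: with a
  global σ the correlation between NC strength and disease-group Loss is
  strongly positive by construction, whereas the reported phenomenon —
  strongly connected regions losing a disproportionate share — is a
  *negative* association and only emerges on the per-node scale.  The
  pipeline therefore uses the global-scalar variant for the loss tables,
  global summaries and node selection, and the per-node variant
  (on un-transformed, r-scale strengths) for the hub-vulnerability stage;
  every result records which variant produced it.
* **Sign convention.**  As printed, Loss_i is positive when strength
  *exceeds* the baseline, so disease groups typically show negative
  values.  Some reports describe "higher loss" in disease, which implies
  the opposite orientation.  The default follows the printed formula;
  `sign = "inverted"` computes (σ − μ_i)/σ for users who prefer loss to
  be positive.  Correlations are unaffected except for their sign.

Regional tau burden is the standardized uptake value ratio,
SUVR_k = (mean uptake in region k) / (mean uptake in the reference
region).  The 246-region atlas this analysis targets excludes the
cerebellum, so the reference ("entire cerebellum" in the intended use) is
supplied as a separate mask volume, and its mean is an unweighted voxel
mean.  SUVR is invariant to global rescaling of the PET volume, which the
tests assert.

### Group statistics

* **Node selection.**  NC vs CI (MCI and AD pooled), one two-sample
  t-test per region on the loss values (pooled variance by default, Welch
  by flag); regions with uncorrected p < 0.05 are flagged.  This mirrors
  the uncorrected biomarker screen customary in this literature;
  Benjamini–Hochberg q-values are reported in an extra column, clearly an
  extension, and play no role in selection.  A subject-label permutation
  test (statistic: absolute difference of group means; add-one estimator
  p = (1 + #{|Δ*| ≥ |Δ|})/(1 + B); exhaustive enumeration whenever
  C(n, n_a) ≤ B) is available as the selection test via the config.
  Labels are permuted jointly across regions, preserving the spatial
  correlation of the data within each shuffle.
* **Cross-modal correlation.**  Within each diagnostic group and each
  selected region, Pearson r and two-sided p between subjects' strength
  (and loss) values and their tau SUVR.  Selection on NC-vs-CI and
  subsequent correlation within the disease groups is a two-stage design
  with a known circularity risk; the package mirrors it because that is
  the analysis under study, and it is the user's responsibility to
  interpret the selected set accordingly.
* **Hub vulnerability.**  Pearson correlation across regions between NC
  group-mean strength (un-transformed r scale) and a disease group's mean
  per-node loss.
* **Global comparisons.**  Per-subject global FCs/PLFCS/SUVR (node means)
  compared across the three groups with one-way ANOVA and Bonferroni post
  hoc (raw pairwise pooled-variance p × 3, capped at 1).
* Degenerate inputs (zero variance, constant scores) are flagged with an
  explicit `degenerate` marker, never silent `NaN`; equal constant groups
  get t = 0, p = 1.

## The synthetic cohort generator

No scans are deposited for studies of this design, so the generator is a
first-class, tested module: it defines the conditions under which the
pipeline's recovery properties are demonstrated.

**Ground truth.**  A factor covariance Σ = LLᵀ + I with dominant loadings
u^h (u ~ U(0.3, 1), h = `hub_exponent`) and a weak mixed-sign second
factor (weight 0.25) that induces some negative correlations, so the
absolute-value strength definition is actually exercised.  h = 0 gives a
near-homogeneous network; h = 2 (the default) a clearly hub-structured
one.  Hubness is the weighted degree of the implied correlation matrix.

**Disease attenuation.**  The hypothesis under test is that strongly
connected regions lose proportionally more.  The minimal generative
mechanism with that property multiplies node i's off-diagonal covariances
by f_i = max(0, 1 − β·h_i), h_i hubness normalised to its maximum, so
entry (i, j) scales by f_i f_j and diagonals are untouched.  This is a
modelling choice of this package, not an empirical claim: it is the
simplest mechanism that reproduces a strong negative strength-loss
association.  Since 0 ≤ f ≤ 1, the attenuated matrix equals
FΣF + diag((1 − f²)σ²) and is automatically positive semi-definite; a
symmetric-eigenvalue check (min λ ≥ −1e-10·max λ) guards the sampling
path regardless.  Each disease subject draws a severity multiplier
s ~ N(1, 0.3) truncated at 0 and is simulated from the network attenuated
with β·s; defaults β = 0.2 (MCI) and 0.4 (AD) produce clearly separated
but overlapping groups.

**Designed loss and tau coupling.**  A subject's *designed* loss at node
i is the noise-free proportional change
(μ_i^att − μ_i^base)/μ_i^base on the correlation scale (zero everywhere
when β = 0).  Regional SUVR couples to it:

SUVR_i = tau_base(group) + c·ρ_i·loss_i + ε,  ε ~ N(0, 0.05),

with coupling scale c = 1, group offsets 1.00/1.05/1.25 (NC/MCI/AD,
reproducing elevated global tau in AD with near-normal MCI), and ρ_i ∈
[−1, 1] setting the sign of the designed loss-tau association per region
(default: +1 for the first half of the regions, −1 for the second half —
an arbitrary but visible default, since no effect sizes exist to copy;
override `rho_region` to change it).  The 5% SUVR noise is in the range
of semi-quantitative PET test-retest variability.  Clinical scores are
linear in the subject's effective attenuation with Gaussian noise, clipped
to [0, 30] (MMSE-like) and [0, 18] (CDR-SB-like).

**Rendered volumes.**  For testing the image path end-to-end, cohorts can
be rendered as NIfTI-1 files on a small synthetic voxel grid (regions laid
out as blocks, reference mask disjoint): region voxels carry the subject's
regional time series / SUVR × reference uptake.  This is deliberately not
a standard brain space; registration and spatial preprocessing
(realignment, nuisance regression, normalisation, smoothing) are out of
scope — the package assumes parcel-ready inputs on congruent grids, and
fMRI/PET volumes must share the atlas grid.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show: no hemodynamic response or autocorrelated noise (rows
are i.i.d. draws), no head motion or scanner artefacts, no partial-volume
effects in PET, no covariate structure (age, sex, education).  Recovery of
the designed structure demonstrates the pipeline's correctness and
statistical calibration, not that real data satisfy the generative
assumptions.

## Numerical and design choices

* **Determinism.**  Every generator is a pure function of (spec, seed);
  child seeds are derived per subject, and the caller's RNG stream is
  restored afterwards.  Fixed-seed pipeline runs produce byte-identical
  TSV outputs.
* **Band-pass filter.**  Implemented as a hard zero-phase frequency mask
  via FFT (coefficients outside [low, high] Hz zeroed), the contract being
  amplitude preservation in-band and suppression out-of-band; with
  low > 0 the DC mean is removed.  It is optional — synthetic data need no
  filtering — and requires the sampling interval.
* **Region bookkeeping.**  The atlas table's row order is the canonical
  node order; every matrix, vector and output table carries region labels
  in that order, and mismatched labels, scales, baselines or reference
  regions are errors, not coercions.
* **Voxel means** are unweighted; NaN voxels are excluded per frame and an
  entirely-NaN region is an error.
* **Problem sizes.**  The validation cohort used by the tests and the
  acceptance script is 60 regions × 20 subjects/group × 200 timepoints
  (calibration checks use 246 regions over 20 replicate cohorts, and 1000
  independent null regions for the permutation test) — large enough for
  stable recovery statistics while keeping a full run in seconds.
  Defaults for real use mirror the intended setting (246 regions, 180
  timepoints, 22/26/36 subjects).
* **Open interpretation points** resolved here: "time-resolved"
  connectivity is read as static full-scan correlation, consistent with
  the rest of the method; permutation tests permute subject labels (not
  region labels); group sizes are always taken from the input manifest.

## Known limitations

* No covariate adjustment (the analysis under study performed none); no
  cluster-level or network-based inference; no FDR-corrected selection by
  default (q-values are informational).
* PLFCS is cross-sectional against a reference group, never longitudinal
  within subject.
* The image path requires congruent fMRI/PET/atlas grids; resampling
  between native resolutions is out of scope.
* The generator's tau-coupling scale and region-class signs are
  conventions, not estimates; conclusions about effect sizes on real data
  cannot be read off the synthetic defaults.
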