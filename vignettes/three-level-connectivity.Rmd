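---
title: "Three-level resting-state functional connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-level resting-state functional connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcnet)
library(dplyr)
```

## The analysis model

`rsfcnet` implements a case-control analysis of resting-state functional
connectivity (FC) on the 90-region AAL parcellation, as used in studies
contrasting early Parkinson's disease (PD) patients against healthy
controls (HC). Each subject contributes a T x 90 matrix of regional BOLD
time series; regional pairwise dependence is summarised by the Pearson
correlation matrix R (90 x 90), and group differences are tested at three
complementary levels:

* **Integrity level** — each node's overall connectedness. The correlations
  incident to node *i* are passed through a strictly increasing exponential
  conversion *c(r)* and averaged over the other 89 nodes, giving the nodal
  degree eta_i = mean_{j != i} c(r_ij). A node whose connections weaken
  shows a lower eta regardless of which particular edges are affected.
* **Network level** — the 90 nodes are grouped into eight resting-state
  networks (RSNs): the seven cortical networks of the Yeo clustering
  convention (VSN, SMN, DAN, VAN, LBN, FPN, DMN) plus a deep gray matter
  network (DGN: bilateral caudate, putamen, pallidum, thalamus). Intra-network
  FC is the mean Fisher-z-transformed correlation over all node pairs inside
  one RSN (8 features); inter-network FC is the mean over all pairs spanning
  two RSNs (28 features).
* **Edge level** — each of the 90*89/2 = 4005 node-pair correlations
  (Fisher z) is analysed as its own feature.

Group contrasts use the general linear model `feature ~ group + age + sex +
education`: the reported statistic is the group-coefficient t from ordinary
least squares, which reduces exactly to the pooled two-sample t when no
covariates are supplied. Multiple testing is handled per level (families of
90, 36 and 4005 features) by Freedman–Lane permutation: the group indicator
and the features are residualised against the covariates, the residualised
indicator is permuted B times (default 5000) and re-residualised, and the
permutation p-value is (1 + #{|t*| >= |t|}) / (B + 1). Benjamini–Hochberg
FDR is applied to the permutation p-values as the headline significance
flag; parametric p-values, a max-T family-wise p, and BH on either scale are
all reported so the two correction routes can be compared. Exploratory
regressions of clinical scores (UPDRS-III, MMSE, MoCA, HAMA, HAMD) on the
significant features, within the patient group and with the same covariates,
are deliberately left uncorrected for multiplicity, and the output metadata
says so.

## Design choices where the convention is genuinely open

**Exponential conversion.** The literature describes converting correlations
to nodal degree "using an exponential conversion method" without a standard
closed form. The package's default is c(r) = exp(r - 1): strictly
increasing, positive, bounded by (e^-2, 1], equal to 1 at r = 1. It is a
named, pluggable choice (`exponential_conversion(cm, conversion = ...)`), so
any alternative monotone map can be substituted without touching the rest of
the pipeline; because the conversion is monotone and shared by both groups,
group contrasts are insensitive to its exact shape.

**Which transform feeds which level.** Integrity uses the exponential
conversion; the network and edge levels use Fisher z, the
variance-stabilising transform appropriate for averaging and group
statistics. Both are configuration keys (`integrity_conversion`,
`network_transform`), since descriptions of such pipelines ambiguously speak
of averaging "correlation coefficients" and "transformed correlation
coefficients" in adjacent breaths. Negative correlations enter all averages
as-is; no thresholding is applied.

**Network assignment.** The AAL-90 to 8-RSN mapping shipped in
`aal90_networks.tsv` is a reconstruction following the common Yeo-style
convention (e.g. Rolandic operculum, Heschl's gyrus and superior temporal
gyrus with the somatomotor network; orbitofrontal, olfactory,
(para)hippocampal, amygdalar and temporal-pole regions with the limbic
network). Individual assignments are legitimately debatable — middle
temporal gyrus, for instance, is placed with the default mode network here —
so the table is treated as configuration: any table with the same four
columns can be supplied to `load_parcellation()`.

**Preprocessing order.** Temporal cleaning is applied as trimming (first 10
volumes) -> linear detrending -> nuisance regression -> band-pass, the order
in which these steps are conventionally listed; the object records the
applied sequence and refuses repetition. The 0.01–0.08 Hz restriction is
implemented as a true band-pass (second-order Butterworth, applied
forward-backward for zero phase), since two cut-offs define a band even when
a pipeline calls it "low-pass filtering". Filter order and family are
parameters. Columns are demeaned before filtering — DC lies outside the pass
band, and removing it first avoids forward-backward edge transients.
Nuisance regression and filtering are sequential, not joint. Zero-variance
ROI columns are flagged and propagated as missing features rather than
silently zeroed, because a constant column has no defined correlation.

**Statistics.** The unified GLM-t (rather than separate two-sample t and
GLM passes) gives one code path whose no-covariate reduction is testable
against the textbook pooled t. Freedman–Lane (residual) permutation is the
default because it respects covariates; raw-label permutation is available
via `scheme = "raw"`. Welch's form is the default for summary-statistic
t-tests (`ttest_from_summary()`), as it reproduces published
cohort-description p-values from printed means and SDs more faithfully than
the pooled form for unequal group variances.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the analysis assumes,
so the whole pipeline can be validated end to end without patient data.
Defaults are fixed at a typical early-PD case-control scale: 47 PD / 50 HC,
T = 373 time points at TR = 0.8 s. Each subject's series is stationary
correlated Gaussian noise: independent normals mixed through the symmetric
square root of the group's target correlation matrix, which is
block-structured with `rho_within` = 0.4 inside each RSN and `rho_between` =
0.15 elsewhere — typical magnitudes for within- versus between-network
resting-state correlation. Patient-group reductions are expressed as
target-correlation deltas on named blocks (default: 0.15 on intra
VSN/SMN/LBN/DGN, 0.10 on intra VAN and on the VAN–DGN pair, emulating the
reported early-PD alteration pattern); a delta that breaks positive
semidefiniteness triggers eigenvalue-clipping repair with the diagonal
re-normalised, the repair distance logged, and an error if any entry must
move by more than 0.05. Covariates mirror the usual cohort table (age ~ 62
years, ~38% male, ~10 education years); clinical scores are linear in the
subject's own empirical network-level Fisher-z FC, centred on the
control-group targets (MoCA and MMSE positively on DGN blocks, HAMA and
HAMD negatively on somatomotor/limbic-or-attention/deep blocks), with
intercepts at control-group means — so lower patient connectivity yields
lower cognition and higher anxiety/depression scores, and regression tests
have a planted truth.

What the generator does *not* emulate: hemodynamic autocorrelation (an
optional AR(1) knob exists for sensitivity analyses, since autocorrelation
inflates correlation variance), head motion, scanner drift, physiological
noise, spatial structure within ROIs, and non-Gaussian BOLD features.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the assumed generative model, not that any
particular clinical finding would replicate on real scanner data.

## Numerical conventions

* Correlations are clipped to |r| <= 0.999999 before `atanh`, so perfectly
  correlated toy inputs stay finite.
* The Z-matrix diagonal is stored as 0 and excluded from every aggregate.
* Edge features flatten the strict upper triangle in row-major order,
  named `"i_j"` with 1-based node ids, i < j.
* Network features follow the fixed canonical label order VSN, SMN, DAN,
  VAN, LBN, FPN, DMN, DGN; the 28 pairs are enumerated in that order, so
  feature indices are reproducible across runs.
* Permutation p-values have floor 1/(B+1); with a family of m features, BH
  significance of a single true effect requires roughly B >= m/q, which is
  why the default is B = 5000 and why small demonstration runs use at least
  B = 1000 at the network level.
* Degenerate inputs fail loudly: zero-variance features are flagged
  "zero residual variance", rank-deficient covariate or confound designs
  are errors (no silent pseudo-inverse), and a group indicator confounded
  with covariates aborts the contrast.
* All randomness (simulation, permutation) flows through a mandatory seed;
  reruns with the same configuration are byte-identical.

## Validation strategy and problem sizes

The test suite checks every operation against an independent oracle: Pearson
correlation against the textbook sum formula, detrending against a
hand-coded least-squares fit, the band-pass against the analytic transfer
function of the designed filter, network averaging and edge flattening
against brute-force double loops on <= 10-node instances across 100 seeds,
the GLM-t against the pooled two-sample t and `lm()`, and permutation
p-values against a naive refit-per-permutation oracle sharing the same
permutation stream.

Calibration is checked at the study's own scale (40 + 40 subjects, T = 373,
36 network features, B = 1000): across 200 null replicates the mean false
discovery proportion at q = 0.05 stays at or below its nominal level within
Monte-Carlo error, and the permutation p-values pooled across replicates are
marginally uniform (mean 1/2, Kolmogorov–Smirnov distance at the pooled
critical value). One caveat worth knowing: a *per-replicate* KS check at the
5% critical value passes in about 86% of replicates rather than the ~95%
that iid uniform p-values would give, because the 36 network features within
a replicate share subjects and a common connectivity factor and their
p-values are therefore positively dependent — a property of the study
design, not a calibration error. A planted within-network correlation
reduction of 0.2 is detected in more than 80% of 100 replicates, and planted
clinical slopes are recovered within 3 SE with ~95% CI coverage. These sizes
keep the default test run at a few minutes on one CPU while matching the
cohort scale the defaults emulate.

## A worked example

```{r example, eval = FALSE}
library(rsfcnet)

cfg <- list(
  input = list(mode = "synthetic",
               spec = list(n_pd = 20, n_hc = 20, n_time = 200)),
  stats = list(B = 1000),
  levels = c("integrity", "network"),
  seed = 42)

res <- run_pipeline(cfg)
res
glance(res$contrasts$network)
dplyr::filter(tidy(res$contrasts$network), significant)
autoplot(res$contrasts$network)
```

## Known limitations

* Spatial preprocessing (slice timing, motion correction, normalisation,
  smoothing) is out of scope; inputs must be aligned 4D volumes or
  pre-extracted ROI tables.
* The shipped network assignment is one defensible reconstruction of the
  Yeo-based convention, not a canonical standard.
* The exponential conversion default is a documented reconstruction of a
  method cited in the literature only by reference.
* Cerebellar regions are excluded by construction of the AAL-90 table.
* No graph-topology metrics (path length, clustering, modularity) and no
  dynamic (sliding-window) connectivity.
* Clinical-score regressions are exploratory by design; their p-values are
  uncorrected and should be treated accordingly.
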