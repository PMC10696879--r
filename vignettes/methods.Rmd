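---
title: "Models and methods behind atacscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atacscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacscreen)
options(atacscreen.verbose = FALSE)
```

`atacscreen` analyzes pooled chemical screens read out by hashed
single-nucleus ATAC-seq. This vignette explains each model in the pipeline,
the assumptions behind it, the tunable parameters and their defaults, what
the synthetic-data generator emulates, and the numerical choices made where
the design was genuinely open. Empirical claims here are limited to what
the test-suite and `scripts/acceptance.R` themselves compute.

## Hash demultiplexing

Each treatment well carries a distinct hash oligo; nuclei absorb it before
pooling, so the per-nucleus vector of hash UMI counts identifies the well.
Real experiments contain ambient hash molecules that label every nucleus at
low rate, so assignment is framed as enrichment over an ambient background
rather than a simple argmax.

The background profile is the mean hash count vector over *debris*
barcodes — barcodes that fail the chromatin QC thresholds (fragments ≥ 500,
TSS enrichment ≥ 3, both inclusive) and therefore represent ambient
material, normalized to proportions. For a nucleus with counts $h$ and
total $n$, the one-sample goodness-of-fit statistic
$\sum_j (h_j - p_j n)^2/(p_j n)$ is referred to $\chi^2$ with
(number of hashes with $p_j>0$) − 1 degrees of freedom. No continuity
correction is applied, and no small-expected-count pooling beyond the
zero-proportion rule: hashes with zero background proportion are pooled
into one extra category whose expected count is zero, so any observed mass
there is infinite enrichment (statistic `Inf`, p = 0). This is the
conservative reading for counts the background deems impossible.

Assignment applies three criteria jointly: total UMIs ≥ 10; BH-adjusted
p < 0.05, with the adjustment computed across all nuclei tested in the run
(the family could also be defined per plate; per-run matches how a single
experiment is processed); and an enrichment score — the ratio of the top to
the second hash count — of at least $\alpha = 2$. The score for a nucleus
with only one observed hash is set to that hash's count to avoid infinite
values. $\alpha$ is a per-experiment knob (floor 2); ties for the top hash
are broken by hash identifier and force a score of 1, i.e. a multiplet call,
the conservative choice.

In species-mixing experiments, a barcode is a chromatin collision when
strictly less than 90% of its fragments map to one species; the report
cross-tabulates those calls against hash-based multiplets.

## QC, TF-IDF/LSI, doublets

Accessibility matrices are binarized cell-by-feature indicators (features:
500-bp tiles or fixed-width peaks, 0-based half-open coordinates
everywhere). Features open in fewer than 0.5% of cells are dropped (1%
within per-drug DA subsets). The embedding is
$\log(1 + 10^4\,\mathrm{TF}) \cdot \log(\mathrm{IDF})$ followed by a
truncated SVD. The $10^4$ scaling inside `log1p` exists because raw
$\log(\mathrm{TF})$ is undefined at zero; $\log(\mathrm{IDF})$ is left
unshifted so a feature present in every cell vanishes exactly. Component
signs are fixed by forcing each component's largest-magnitude feature
loading positive, making embeddings reproducible across BLAS
implementations. The first component, which tracks sequencing depth, is
optionally dropped (and always dropped where 49 of 50 components are used).

The TSS enrichment score is the mean per-base insertion coverage in
TSS ± 50 bp divided by that in two 100-bp flanks centered ± 1950 bp from
the TSS. This is a simplified stand-in for the score produced by dedicated
preprocessing tools; within this package it only serves as a QC filter and
a model covariate, for which the exact flavor is immaterial.

Doublet detection simulates doublets as element-wise ORs of distinct random
cell pairs (`n_sim` defaults to the number of observed cells), transforms
observed and simulated profiles with the IDF *of the observed cells only*
(so simulated profiles cannot distort feature weights), fits the SVD basis
on observed cells and projects the simulated ones — a documented,
switchable choice (`basis = "union"` fits on the concatenation); projection
keeps the observed geometry fixed. Scores are the simulated fraction among
the $k = \lceil 0.5\sqrt{n_\text{obs}+n_\text{sim}} \rceil$ nearest
neighbors in 49 components, and the top 10% of cells are pruned with
deterministic tie-breaking by barcode.

## Dose-response models

For drug $D$, the analysis set $C$ is all cells treated with any dose of
$D$ plus all vehicle cells. Accessibility of each peak over $C$ follows

$$\mathrm{logit}(Y) = \beta_0 + \beta_d d + \beta_f f + \beta_t t$$

where $d$ is log dose, $f$ log fragments and $t$ TSS enrichment. Vehicle
dose is 0, so $d = \log_{10}(\mathrm{dose} + \delta)$ with
$\delta = (\text{smallest nonzero dose})/10$, recorded alongside results;
this keeps vehicle finite while preserving order. Fits use IRLS
(`stats::glm`) run to a tight tolerance; the Wald standard error is
computed from the Fisher information evaluated at the converged
coefficients (the usual summary evaluates the weights one iteration
earlier, which costs several digits of precision). Fits that fail to
converge in 100 iterations or give $|\beta_d| > 15$ are flagged as
separated and excluded from the significant set rather than reported as
huge effects. Raw p-values are pooled across all drugs and peaks before a
single BH adjustment, and significance uses adjusted p < 0.05.

Gene-level dose effects use $\ln E[Y] = \beta_0 + \beta_d d$ with
quasipoisson variance, Pearson-residual dispersion and library size factors
as offsets; ATAC gene-activity and RNA coefficients are compared by Pearson
correlation over genes whose RNA dose term is significant. Viability is the
printed four-parameter log-logistic
$f(x) = c + (d-c)/(1+\exp(b(\ln x - \ln e)))$, fit by Levenberg–Marquardt;
vehicle wells are excluded from this fit since $\ln 0$ is undefined — the
upper asymptote absorbs the baseline. By construction $f(e) = (c+d)/2$.

## Pseudodose trajectories

Graph learning is delegated to a deliberately simple stand-in: k-means
centroids joined by a minimum spanning tree, with cells assigned to their
nearest centroid. Downstream mathematics consumes only node assignments and
geodesic distances, so any imported node/edge table can replace it. The
default of 15 centroids (at the study scale of ~2,000 cells) is a
considered choice: with substantially more centroids, dense terminal
regions of the embedding receive several nodes and the spanning tree
zigzags through them, inflating geodesic distances with spurious path
length and stretching the tail of the pseudodose axis into a plateau where
the trend argmax becomes noise-driven.

Roots are nodes whose assigned cells are strictly majority vehicle;
pseudodose $\psi$ is the minimum geodesic distance from a cell's node to
any root (0 at roots, invariant to rigid rotations of the embedding).
Cells are binned by 1-D k-means on $\psi$ (k = 10) and carry their bin
mean $\tilde\psi$. Within each bin, cells sorted by $\psi$ are chunked into
contiguous groups of 50–100 cells (equal sizes, $\lceil n/100\rceil$
groups; bins under 50 cells merge into the nearest adjacent bin first).
For group $j$, $A_{ij}$ counts cells with peak $i$ accessible, and $S_j$
is the mean accessible-feature count per cell — the "overall cell-wise
accessibility" covariate that absorbs group-level depth differences.

Smoothing fits, per peak,
$\ln E[A] = \beta_0 + f(\tilde\psi) + g(\tilde S) + \log(\text{group
size})$ with negative-binomial errors and natural splines $f, g$. Two
choices deserve note. First, the group-size offset: group sizes legitimately
range 50–100, and without the offset size variation masquerades as trend;
with it, predictions are per-cell rates. Second, spline df = 2 (one
interior knot): the trend families of scientific interest are monotone or
single-bump, which one interior knot represents, while additional knots let
terminal noise tilt the smoothed tail across the classification boundary.
Predictions are evaluated at 100 equally spaced $\tilde\psi$ values with
$\tilde S$ linearly interpolated from the groups at each grid point, so the
curve follows the data manifold rather than a counterfactual fixed-$S$
slice. Classification follows the bin rule: smoothed maximum in bins 1–20 ⇒
closing, 81–100 ⇒ opening, interior ⇒ dynamic; peaks outside the DA set are
static. NB fits that fail fall back to Poisson with a flag.

The FRIP model tests whether treatment shifts global signal-to-noise along
the trajectory: full model FRIP ~ ns($\tilde\psi$, 3) + ns($\tilde\psi$, 3):d
(Gaussian), reduced model without the interaction, compared by LRT with df
equal to the number of interaction columns. The spline main effects appear
in both models so they are properly nested — the printed full model shows
only the product term, but without main effects the models would not nest
and the LRT would be invalid.

## Motif and expression models

Motif-trend enrichment fits one univariate logistic regression per motif
(class membership on motif presence) with a two-tailed Wald z-test and BH
adjustment within each trend-by-condition family; motifs present in all or
no peaks are inestimable and flagged. Gene features: a peak within 500 bp
(inclusive) of a TSS is a promoter peak; promoter features are binary motif
indicators over a gene's promoter peaks; the distal feature per motif is
the highest co-accessibility score (≥ 0.1) from a promoter peak to a
connected non-promoter peak bearing the motif, else 0. Elastic-net models
(mixing 0.5, penalty by 5-fold cross-validation under a fixed seed,
standardized features) predict the RNA dose coefficient for genes whose
RNA dose term is significant; reported variance explained is training
$R^2$ at the selected penalty — a single-number summary matching how one
explained-variance bar per model is typically shown — with cross-validated
$R^2$ also returned, and the fold increase is
$R^2_\text{promoter+distal}/R^2_\text{promoter}$.

## The synthetic-data generator

The generator is the inverse of the models above, with planted truth:

* Hash counts: per-nucleus totals are negative binomial (mean 200,
  size 5 — overdispersed capture); a singlet's counts are multinomial over
  $(1-b)\,e_s + b\,p_\text{amb}$ with ambient fraction $b$ and a
  Dirichlet-drawn ambient profile (the real ambient composition is
  unknown; this is a config knob, not a claim about data). The default
  $b = 0.075$ with 8 near-uniform hashes gives an expected top/second
  ratio $(1-b)H/b + 1 \approx 100$, the enrichment regime reported for
  well-labeled experiments. Doublets sum two singlet draws; debris
  barcodes (5 per cell) draw purely from the ambient profile with small
  Poisson totals and sub-threshold fragment counts, so they feed
  background estimation exactly as in a real run.
* Dose-response accessibility: Bernoulli with
  $\mathrm{logit}(p) = \beta_0 + \beta_d d + 0.25 (f - \ln 3000) +
  0.05 (t - 8)$, $\beta_0 \sim U(-2, 0)$,
  $f \sim N(\ln 3000, 0.5^2)$, $t \sim N(8, 2^2)$ truncated at 0 —
  plausible per-cell ranges for fragment depth and TSS enrichment. The
  default effect sizes plant $\beta_d = +2$ on 10% of features, $-2$ on
  10%, 0 elsewhere.
* Genes and motifs: gene TSSs sit inside their promoter peaks; links from
  promoter to random distal peaks carry Uniform(0,1) scores, and only
  links ≥ 0.1 transmit the planted distal motif effect into the gene's
  RNA dose coefficient, mirroring the pipeline's connection threshold.
  RNA counts are Poisson with log-mean linear in $d$ and lognormal size
  factors.
* Trajectory: the latent position is the dose rank (scaled to [0, 1]) plus
  N(0, 0.12) noise, clamped — doses are discrete, so the top-dose cells
  form a terminal blob, which is exactly the regime that motivated the
  centroid-count choice above. Opening/closing features follow
  $\mathrm{logit}^{-1}(\mp 2 \pm 4\psi)$, dynamic features a Gaussian bump
  at $\psi = 0.5$ (width 0.12), static features 0.3 throughout. FRIP is
  $0.3 + \gamma\,\psi\,d + N(0, 0.02)$ with interaction $\gamma = 0.05$ by
  default.

What passing tests on these data do **not** show: robustness to batch
structure, to peak-calling artifacts, to non-multinomial hash chemistry
(e.g. well-to-well cross-contamination), to continuous dose designs, or to
branching trajectories — none of which the generator emulates. Conversely,
because every stage is checked against planted truth and independent
statistical oracles (hand-coded Newton/IRLS fits, closed-form saturated
models), a failure on real data is more likely a data or preprocessing
issue than an arithmetic one.

## Problem sizes and numerical choices

The default study is 2,000 cells × 500 features, which keeps the full
suite and the acceptance script to a couple of minutes on one CPU while
leaving all rates estimable (Monte-Carlo error on a 5% rate over 600 null
fits is about ±0.9%). GLM fits run IRLS to epsilon 1e-14 with a 100
iteration cap; the 4PL uses Levenberg–Marquardt with ftol/ptol 1e-14 and a
positivity bound on the ED50; k-means steps use fixed seeds and multiple
starts; degenerate inputs (all-zero cells or genes, constant dose,
vehicle-only designs, empty debris sets) raise early, descriptive errors
rather than propagating NaNs.

## Known limitations

Single-drug designs per fit (no interaction terms); no replicate random
effects; no dispersion shrinkage across peaks; the principal-graph stand-in
cannot represent branching responses; hash barcode sequence errors and
UMI-collapse chemistry are upstream of this package; co-accessibility
scores are consumed, never computed.
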