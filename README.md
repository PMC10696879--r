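# atacscreen

Analysis of pooled chemical screens read out by single-nucleus ATAC-seq with
nuclear hash labels. In these experiments every treatment well receives a
distinct single-stranded DNA "hash" oligo that permeabilized nuclei absorb;
after pooling, combinatorial-indexing ATAC-seq recovers, per nucleus, both a
chromatin accessibility profile and a vector of hash UMI counts that
identifies the well (drug, dose, replicate) the nucleus came from. The
package implements the full downstream computational pipeline and a
synthetic-data generator with planted ground truth so every stage is
testable without any sequencing data.

## What the pipeline computes

**Hash demultiplexing.** For nucleus *i* with hash UMI vector *h<sub>i</sub>*
(total *n<sub>i</sub>*), enrichment over the ambient background
*p* (estimated by averaging hash counts over sub-threshold "debris"
barcodes) is tested with the goodness-of-fit statistic

    X2_i = sum_j (h_ij - p_j n_i)^2 / (p_j n_i),  df = #hashes - 1

with BH correction across nuclei. A nucleus is a **singlet** when
*n<sub>i</sub>* ≥ 10, adjusted *p* < 0.05, and the enrichment score
(top / second hash count) is at least α = 2; enriched nuclei failing only
the score criterion are **multiplets**.

**Doublet detection.** Doublets are simulated as binarized sums of random
cell pairs; observed and simulated profiles are embedded by
log(1 + 10⁴·TF)·log(IDF) + truncated SVD (IDF frozen on observed cells,
first component dropped, 49 components), and each cell is scored by the
simulated fraction among its k nearest neighbors; the top decile is pruned.

**Dose-response differential accessibility.** Per peak and drug, the
logistic model `logit(Y) = b0 + bd*d + bf*f + bt*t` (d = log dose,
f = log fragments, t = TSS enrichment) is fit over the drug's cells plus
vehicle controls; peaks accessible in < 1% of those cells are dropped.
Wald p-values for *b<sub>d</sub>* are pooled across all drugs and peaks
before one BH adjustment. Gene-level dose effects use quasipoisson models
with size-factor offsets; viability curves use the four-parameter
log-logistic `f(x) = c + (d - c) / (1 + exp(b(ln x - ln e)))` with ED50 `e`.

**Pseudodose trajectories.** A principal-graph stand-in (k-means centroids +
minimum spanning tree) is fit on the LSI embedding; nodes whose assigned
cells are majority-vehicle become roots, and each cell's pseudodose ψ is
the geodesic distance from its node to the nearest root. Cells are grouped
(k-means, k = 10; then 50–100-cell subgroups) and per-peak accessibility
counts are smoothed with a negative-binomial natural-spline model of group
pseudodose and overall accessibility. Peaks whose smoothed maximum falls in
the first/last 20 of 100 pseudodose bins are closing/opening; interior
maxima are dynamic; non-DA peaks are static. A Gaussian LRT tests whether
FRIP depends on dose along the trajectory.

**Motifs and expression.** Per-motif logistic regressions test trend
enrichment; elastic-net models predict each gene's RNA dose coefficient from
promoter motifs (peaks within 500 bp of the TSS) alone versus promoter plus
distal motifs routed through co-accessibility links with score ≥ 0.1, and
report the fold increase in variance explained.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the default
synthetic study (2,000 nuclei, 8 hashed samples, four doses plus vehicle,
10% doublets). For example:

```sh
Rscript analysis/02_demux.R
Rscript analysis/05_trajectory.R
```

prints (seed 1):

```
singlet label accuracy: 100.00% (1787 cells)
heterotypic doublets flagged as multiplets: 69.1% (178)
chromatin collision rate: 10.0%; hash flags 74.5% of them;
species label accuracy on chromatin singlets: 100.00%
...
pseudodose vs planted latent: Spearman rho = 0.934
accuracy on planted monotone trends: 0.956
FRIP x dose interaction LRT: stat = 245.9 (df 3), p = 5.12e-53
```

i.e. every demultiplexed singlet recovers its planted well label, about
two-thirds of planted heterotypic doublets are caught from hash counts
alone, the recovered pseudodose tracks the planted latent position, and the
planted FRIP-by-dose interaction is detected. Result tables land in
`results/`.

In R, the same pieces compose directly:

```r
library(atacscreen)
cfg <- sim_config(seed = 1)
hx  <- simulate_hash_experiment(cfg)
bg  <- estimate_background(hx$hash_counts, hx$debris_barcodes)
asn <- assign_samples(hx$hash_counts[hx$truth$status != "debris", ], bg)
table(asn$call)
#> multiplet   singlet
#>       123      1877
```

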