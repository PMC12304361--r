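---
title: "Differential TF occupancy from single-nucleus tagmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential TF occupancy from single-nucleus tagmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occupeak)
```

## The problem

Antibody-directed tagmentation assays (CUT&Tag and its derivatives) read out
where a transcription factor (TF) sits on the genome as a coverage signal of
sequenced fragments. At single-nucleus resolution each cell contributes only a
few hundred fragments, so deciding whether a TF's occupancy at a given peak
*differs* between two cell states (say, embryonic stem cells versus
epiblast-like cells) requires a statistic that pools sparse per-cell counts
across a peak while accounting for how variable that peak's signal is from
cell to cell. `occupeak` implements that statistic and the processing around
it: peak-window binning, per-cell quality control, per-peak testing with
multiplicity control, promoter-window integration of bulk occupancy with
expression data, cluster-stability scoring, and a generator of synthetic
two-state experiments with known ground truth.

## The peak statistic

Each retained peak is represented by a window of $\pm$ 2.5 kb around the peak
centre, divided into $n_b = 100$ bins of 50 bp. For one condition, let
$c_{ij}$ be the count of cell $i$ ($i = 1,\dots,n$) in bin $j$, after each
cell's counts have been scaled to a common total. The condition summary is
the log2 bin-averaged, cell-summed signal

$$\bar z = \log_2\left(\frac{1}{n_b}\sum_{i=1}^{n}\sum_{j=1}^{n_b} c_{ij}\right),$$

with variance estimate

$$\sigma^2 \;=\; \frac{1}{\ln(2)\,n_b}\cdot
\frac{\sum_{k,l=1}^{n_b}\sum_{m=1}^{n}(c_{mk}-\hat\mu_k)(c_{ml}-\hat\mu_l)}
     {\sum_{i,j} c_{ij}},
\qquad \hat\mu_j = \frac{1}{n}\sum_i c_{ij}.$$

The numerator is the full bin-by-bin covariance summed over all bin pairs, so
signal that co-varies across a window's bins (as real binding signal does)
inflates the variance rather than being averaged away. Algebraically the
double bin sum collapses to $\sum_m (r_m - \bar r)^2$ where $r_m$ is cell
$m$'s row sum; `peak_log_variance()` uses this $O(n\,n_b)$ form, and the test
suite certifies it against a literal quadruple-sum evaluation on random
matrices to $10^{-9}$. Two conditions A and B are compared with

$$z = \frac{\bar z_A - \bar z_B}{\sqrt{\sigma_A^2 + \sigma_B^2}},$$

so positive $z$ means higher occupancy in the first condition. P-values are
two-sided standard-normal tails, adjusted across peaks by Benjamini–Hochberg,
and peaks with adjusted $p < 0.001$ are selected.

Several choices here were genuinely open and are resolved as follows:

* **Null distribution.** The statistic is a difference of means over a pooled
  standard error, so a two-sided standard normal is the natural reference;
  no alternative is suggested by its construction. Calibration is
  characterised empirically (below), not assumed.
* **Multiplicity.** "Adjusted p" is taken as Benjamini–Hochberg, the field's
  convention for peak-level FDR control; peaks with zero total in either
  condition are excluded from the family and carry an explicit status code
  (`zero_total_a/b`, `zero_variance`) instead of a silent `NA`.
* **The variance as printed.** $\sigma^2$ carries a single $\ln 2$ factor
  and divides by the *un-squared* raw total. This differs from the textbook
  first-order delta-method variance of $\log_2$ of a sum,
  $n\,s_r^2/(\ln 2\; T)^2$. The printed form is the authoritative default
  (`variance_mode = "printed"`); the delta form is available as
  `variance_mode = "delta"` for sensitivity analysis.

### Calibration is scale-dependent — a documented property

Because the denominator of $\sigma^2$ is the raw (un-squared) total, the
estimator is *not* invariant under rescaling the counts: multiplying all
counts by $s$ multiplies $\sigma^2$ by $s$. The pipeline scales every cell to
10,000 before testing; when true per-cell depths are far below the scale
target the variance is inflated and the z-scores are conservative (on the
bundled recovery scenario the null z-scores have standard deviation well
below 1, and no peak reaches adjusted $p<0.001$ even at |log2FC| = 2 —
exactly what the independent naive pilot implementation produces). The
*ranking* of peaks is unaffected: the acceptance suite verifies Spearman
concordance $\ge 0.95$ between analytic $|z|$ ranks and 999-permutation
p-value ranks, and that true-effect peaks dominate the top of the ordering.
Users comparing conditions at low depth should therefore read the selected
set as high-specificity and lean on the z-ranking (or the permutation route)
for sensitivity.

## Pipeline order

The testing branch is: `filter_peaks()` (score $\ge$ 1000) →
`make_windows()` (±2.5 kb, 100 × 50 bp bins) → `build_matrix()` →
`filter_cells_by_reads()` (> 250 reads in windows, strict) →
`normalize_total()` (10,000 per cell) → `run_differential()`. The QC and
embedding branch applies `quantile_filter_cells()` (remove cells below the
15% or above the 95% quantile of non-zero peaks; quantiles by linear
interpolation, boundary cells kept) and `log1p_transform()` (natural log),
then `embed_cells()` (10 principal components, 25-neighbour graph, UMAP) on
the peaks the test selected. The two branches are kept separate because
scaling-then-testing and quantile-filtering-then-visualising are distinct
recipes; `run_differential()` refuses log1p input to keep the statistic on
(scaled) counts.

Window centres are interval midpoints (`floor((start+end)/2)`), not summit
positions: summit-based centring would need narrowPeak column 10, which not
all peak callers emit, and the two are one flag apart in window geometry.
Peaks whose window would cross a chromosome boundary are dropped, not
clamped, because the statistic assumes one fixed $n_b$ for every peak.
Fragments are assigned by midpoint by default — each fragment lands in
exactly one bin per matched window, so totals are conserved and the
denominator of $\bar z$ stays interpretable; `mode = "overlap"` reproduces
per-bin interval-coverage counting (which multi-counts straddling
fragments) for parity with coverage-tool workflows. Overlapping peak windows
each receive a fragment independently, since peaks are treated as
independent tests.

Note on re-applying filters: the read filter is idempotent; the quantile
filter is not (its bounds are quantiles of the *current* distribution, so a
second application trims further). It is meant to run once per matrix.

## Key parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_score` | 1000 | narrowPeak score | high-confidence peak sets; note some callers cap the column at 1000 |
| `flank` / `bin_width` | 2500 / 50 | bp | ±2.5 kb windows, 100 bins |
| `min_reads` | 250 | reads/cell (strict >) | drops near-empty nuclei |
| scale `target` | 10,000 | counts/cell | common library-size normalisation |
| `alpha` | 0.001 | adjusted p (strict <) | high-specificity peak selection |
| `lower` / `upper` | 0.15 / 0.05 | quantile fractions | trims low-complexity and doublet-like cells by non-zero peaks |
| `n_components` / `n_neighbors` | 10 / 25 | — | PCA/UMAP embedding geometry |
| stability `threshold` | 0.75 | median Jaccard (strict >) | cluster called stable above it |

## Bulk integration

For bulk occupancy versus expression, `make_tss_windows()` builds
strand-oriented promoter windows (1000 bp upstream, 250 bp downstream of the
TSS — 1250 bp total). `occupancy_ratio_test()` compares per-gene promoter
counts between conditions over a gene set: genes with a zero count in either
condition are excluded (no division by zero), the mean of per-gene log2
ratios is reported (mean-of-logs, not log-of-mean-ratio, so each gene
contributes equally), and a two-sided paired t-test is run on the per-gene
raw count differences (`on_log = TRUE` switches to log2-ratio differences).
The ratio orientation is an explicit argument rather than a hidden
convention. P-values across pathways are deliberately not FDR-corrected —
curated gene sets of modest size are treated as a small family read off a
bubble display. `gsea_rank_score()` pre-ranks transcripts by
$\mathrm{log2FC}\times(-\log_{10} p_\mathrm{adj})$, and `de_gene_filter()`
applies the strict |log2FC| > 0.5, adjusted p < 0.1 cut used for
duplicate-level single-nucleus RNA-seq.

## Cluster stability

`cluster_stability()` scores a full-data clustering against re-clusterings
of subsamples (canonically 20 draws of 80% of cells without replacement):
per original cluster and run, restrict the cluster to the sampled cells and
take the best-match Jaccard index over the run's clusters; the per-cluster
median across runs must exceed 0.75 *strictly*. Matching is independent per
cluster (no global assignment), which matches the per-cluster reading of the
recipe and makes the report invariant to label renaming; clustering itself
is injected by the caller, never computed here.

## The synthetic generator

`simulate_experiment()` emulates the statistical structure the test assumes:
per peak a lognormal base intensity; a fraction `frac_diff` of peaks carries
a true effect ($2^{\pm\mathrm{effect}}$ applied to condition B); per cell a
lognormal depth factor; per (cell, peak) Poisson read counts spread over the
window by a discretised Gaussian profile; reads materialised as 30–120 bp
fragments whose midpoints sit in their assigned bin (so midpoint and overlap
counting are both exercised); background fragments placed uniformly outside
all windows to set FRiP. Peaks sit on one synthetic chromosome spaced so
windows never overlap. Over-dispersion arises from the depth mixture rather
than a per-bin negative binomial — the minimal structure the statistic
presumes (independent cells, bin-correlated signal).

Defaults are the standard recovery scenario used throughout the tests: 500
peaks, 10% differentially occupied at |log2FC| = 2, 150 cells per condition,
0.4 expected reads per peak per cell (≈60 reads per peak per condition,
≈200 in-window reads per cell), depth sigma 0.5, profile sigma 10 bins,
50 background fragments per cell (pooled FRiP ≈ 0.35). The statistic-
validation runs use all 150 cells per condition — at this depth the
\>250-read filter would remove most cells, and that filter's strictness is
exercised by its own dedicated checks.

What the generator does **not** emulate: doublets, batch effects, chromatin
accessibility confounding, mappability artefacts, overlapping peaks (except
in an explicit stress mode via `peak_gap`), alignment errors, or sequence
content. Passing tests therefore demonstrate correctness of the statistics
and plumbing under the assumed generative structure, not robustness to every
artefact of real data.

## Problem sizes and numerical choices in the test suite

The suite validates the variance identity on 1,000 random matrices
($n \le 20$, $n_b \le 100$), runs the recovery scenario once (500 peaks ×
300 cells, 999 label permutations) and ten null replicates of the same
size — sizes chosen to give stable Monte-Carlo answers in seconds on a
laptop. Quantiles use R's default type-7 linear interpolation. All
stochastic routines take explicit seeds and restore the caller's RNG state;
`embed_cells()` pins UMAP to single-threaded execution so a fixed seed
reproduces coordinates exactly. Degenerate inputs never vanish silently:
zero-total peaks, zero-variance comparisons, all-zero cells, empty gene
sets and empty subsamples all either carry status/note columns or raise
typed errors.

## Known limitations

* No shrinkage or empirical-Bayes moderation of the per-peak variance; at
  very low depth the printed estimator is conservative (see above).
* Exactly two conditions; no covariates, no multi-factor designs.
* BAM parsing is out of scope — inputs are fragment TSVs and standard
  BED-family text formats.
* The embedding contract is determinism and interface only; coordinates are
  for visualisation, and no scientific claim rests on their geometry.
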