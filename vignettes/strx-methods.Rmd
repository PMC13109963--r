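---
title: "Methods and modeling choices in strx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in strx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strx is a pipeline for spatial transcriptomics samples that runs from raw
gene-by-capture-location counts to ranked drug repurposing candidates. This
vignette explains each stage's model and assumptions, the tunable parameters
and their defaults, what the synthetic-data generators emulate, the
numerical choices, and the known limitations.

## Quality control and normalization

Spatial platforms differ enough in resolution and depth that one QC recipe
does not fit all. strx keys the protocol on a technology class:

* **Multi-cell (spot) platforms** (`qc_multicell()`): capture locations with
  fewer than 500 UMIs, fewer than 500 detected genes, or a mitochondrial
  read fraction of 25% or more (boundary inclusive) are removed. A second,
  adaptive rule removes locations whose UMI total *or* detected-gene count
  falls more than three standard deviations below the respective median of
  the locations that survived the hard thresholds; because trimming tightens
  the survivor distribution, this rule is iterated to a fixed point, which
  makes the whole filter idempotent — re-running QC on its own output
  changes nothing. Finally, genes expressed (raw count > 0) in fewer than
  five surviving locations are dropped.
* **Single-cell (imaging) platforms** (`qc_singlecell()`): these measure
  fewer genes at lower depth, so only the 500-UMI and 25%-mitochondrial
  rules apply; there is no gene filter, detected-gene rule or outlier rule.
* **Bead platforms** (`qc_slideseq()`): genes with a sample-wide UMI total
  below 300 are removed first; then locations whose recomputed total is not
  strictly greater than 100, or whose mitochondrial fraction reaches 25%,
  are removed. The order of the two filters is switchable
  (`location_filter_first = TRUE`) for sensitivity analysis; with the
  default order, location totals are recomputed after gene removal.

The mitochondrial fraction is always the raw count of flagged genes
(symbols matching the configured prefix, default `MT-`) over the location
total. All cutoffs are exposed as arguments so retention monotonicity can
be probed, but the defaults above are the protocol.

Normalization (`normalize_sample()`) scales each location to the median
post-QC location total and applies `log(x + 1)`. Variance-stabilizing
transforms fit a per-gene noise model instead; we deliberately use the
simpler median-library-size scaling because every downstream statistic in
this pipeline — Moran's I, rank-sum tests, Kendall and Spearman
correlations, and the rank-based enrichment score — depends on the data
only through ranks or thresholded means, which are invariant to any
monotone per-gene transformation. One algebraic caveat is worth knowing:
multiplying all counts by a constant *c* rescales the median target by *c*
too, so (without the pseudo-count) normalized values shift by exactly
`log(c)` rather than staying fixed; rank-based statistics are unaffected.

## Pseudo-cells from deconvolution output

Deconvolution of multi-cell spots (performed upstream by a Bayesian
deconvolution tool; strx consumes its outputs) yields per-location cell-type
fractions, their posterior coefficients of variation, and cell-type-specific
expression. strx post-processes these into *pseudo-cells*:

1. `clip_fractions()` zeroes fractions whose CV exceeds 0.5 (strictly; a CV
   of exactly 0.5 is kept). No renormalization is performed afterwards, so
   clipped columns may sum below one.
2. `build_pseudocells()` emits, for every (cell type, location) pair with a
   positive clipped fraction, one pseudo-cell whose expression is the
   deconvolved expression divided by the fraction, carrying the origin
   location's coordinates. Division by a vanishing fraction explodes
   values, so fractions below `min_fraction = 0.01` are discarded as well;
   the count of such discards is recorded on the result.

The round trip `expression x fraction` reconstructs the deconvolved input
to floating-point accuracy, and the number of pseudo-cells equals the
number of positive retained fractions.

## Spatially variable genes

The spatial variability stage needs only to deliver a gene-to-q-value map
to its consumers (eligibility filtering and PPI module extraction), so strx
uses a transparent statistic: **Moran's I** on a symmetrized binary
k-nearest-neighbor graph (`k_neighbors = 6`),

$$I = \frac{n}{W}\,\frac{\sum_{ij} w_{ij}\,(x_i-\bar x)(x_j-\bar x)}
{\sum_i (x_i-\bar x)^2},$$

with $W$ the total weight. k-NN weights rather than a fixed radius keep the
graph meaningful across spot, bead and imaging geometries. Significance
comes from shuffling values across positions (`n_perm = 1000` by default)
with the add-one rule $p = (\#\{I_{perm} \ge I_{obs}\} + 1)/(B+1)$, upper
tail only — positive autocorrelation is what "spatially variable" means
here. One fresh permutation per iteration is shared across genes; this
leaves each gene's marginal null untouched and makes the stage linear
rather than quadratic in gene count. q-values are Benjamini–Hochberg within
scope (whole tissue, or within each cell type on pseudo-cells). Cell types
with fewer than `min_cells = 10` observations are skipped with a warning —
Gaussian-process models for spatial expression exist and are more powerful
per observation, but they add heavy inference for a stage whose consumers
only threshold q at 0.05; externally computed spatially-variable-gene
tables can be substituted wherever an `sv_result` is accepted. Constant
genes have an undefined statistic and are reported with `p = 1`.

Colocalization analyses use Kendall's tau-b between a gene's normalized
expression and a cell-type fraction (`colocalization_corr()`), and Spearman
correlations between a two-gene expression ratio and a marker panel
(`gene_ratio_corr()`, ratio pseudo-count 1, BH across the panel).

## Cell-type markers

`find_markers()` performs one-vs-rest Wilcoxon rank-sum tests per cell
type. Genes enter testing only if the absolute log2 fold change — defined
as `log2((mean_in + 1)/(mean_out + 1))` on normalized expression — is at
least 0.1 *and* the gene is detected in at least a fraction 0.1 of
observations in one of the groups. The pseudo-count-stabilized fold change
is one of several conventions in use; since every downstream consumer
thresholds the fold change rather than interpreting its exact value, the
choice is benign, and the natural-log variant is available via `lfc_base`.
BH adjustment is per cell type, because each cell type's DEG set feeds a
separate enrichment analysis. Types with fewer than three observations are
skipped.

## Cell-cell interaction

**Neighborhood-based** (`neighborhood_cci()`): pseudo-cells deconvolved
from the same capture location are neighbors (`same_location` adjacency);
for single-cell data, cells within `radius_um = 30` micrometers are (the
radius is a package choice — "adjacent" is not a measurable primitive on
segmented cells — and is exposed as a parameter). Query-type cells with at
least one interacting-type neighbor are compared against those with none,
gene by gene, with the same test and filters as marker detection. A
positive fold change reads as the interacting type promoting the gene in
the query type.

**Distance-based** (`distance_cci()`): for each (pathway, sender type,
receiver type, threshold *d*), each ligand–receptor pair scores the mean of
`ligand(a) x receptor(b)` over ordered cell pairs within *d* (500, 1000,
1500 micrometers by default), and the pathway sums its pairs. This
thresholded product is a deliberately simple stand-in for optimal-transport
signaling models and is tagged `method = "threshold_lr"` in every output.
Note that a *mean* over in-range pairs is not monotone in *d* (an extra
low-product pair can lower it); at `d = Inf` it equals the all-pairs mean
product. Significance comes from permuting cell-type labels with the
add-one rule, BH across rows.

## The drug repurposing engine

**Eligibility** (`eligible_deg_sets()`): per cell type, significant genes
(q < 0.05) split into up-regulated (log fold change > 0.5) and
down-regulated (< −0.5) sets; where a per-cell-type spatial variability
result exists, the significant set is first intersected with the spatially
variable genes. A query is eligible with at least 10 up- or 10
down-regulated genes and strictly fewer than 2000 significant genes in
total.

**Scoring** (`enrichment_score()`): each drug signature ranks its $r$ genes
by perturbation z-score, rank 1 = most down-regulated, ties broken
lexicographically for determinism. (The rank orientation is the only one
consistent with the convention that a *positive* score marks a reversal
compound: up-regulated disease genes must earn a positive sub-score when
the drug pushes them toward the bottom of its ranking. A `descending` flag
flips it for sensitivity checks.) For a sub-list of $s$ query genes with
profile ranks $V(j)$, sorted ascending,

$$a = \max_{1\le j\le s}\Bigl(\tfrac{j}{s} - \tfrac{V(j)}{r}\Bigr), \qquad
  b = \max_{1\le j\le s}\Bigl(\tfrac{V(j)}{r} - \tfrac{j-1}{s}\Bigr),$$

and the sub-score is $a$ if $a > b$, else $-b$; the measure-zero tie
$a = b$ resolves to $+a$, keeping the score continuous from the $a > b$
side. The combined score is $ES = ES_{up} - ES_{down}$ when the sub-score
signs differ and $0$ when they agree. A query with only one sub-list is
legitimate (the eligibility rule is an *or*): the missing sub-score is 0
and is treated as differing in sign from any nonzero value, so the
informative sub-list still scores.

**Permutation p-values** (`permutation_pvalue()`): random gene lists with
the query's `n_up` and `n_down` are drawn without replacement from the
profile's $r$-gene universe (up/down disjoint), rescored, and the
one-tailed add-one p-value taken on the right tail for $ES > 0$, the left
for $ES < 0$, with $p = 1$ at $ES = 0$. Because a ranked profile is a
permutation of $1..r$, the null law depends only on $(r, n_{up},
n_{down})$; `score_library()` therefore draws one seeded null per query and
reuses it across that query's signatures, which is statistically identical
to per-signature permutation and far faster. BH adjustment is across
signatures within each query. Signatures collapse to compounds by taking
the maximal-|ES| signature among a compound's significant ones (mean and
best-q collapses are available).

A statistical caveat follows directly from the tail rule: choosing the
tail *after* observing the sign, without doubling, makes the null p-value
distribution non-uniform — roughly uniform within each sign branch but
concentrated below ~0.5 overall, with an atom at 1 from zero scores. Null
p-values are therefore anti-conservative by about a factor of two near
zero, and BH on them inherits that optimism. We keep the rule because it
is the scheme this score is conventionally used with; treat the q-values
as a ranking device rather than a calibrated error rate.

**Networks and selection**: `extract_ppi_module()` takes up to 300 most
significant (optionally SV-filtered) DEGs of a cell type and induces the
protein-protein interaction subgraph on them, keeping isolated genes as
nodes. `build_perturbation_network()` overlays up to 500 significant
inversely related and 500 positively related compounds, drawing drug–gene
edges where the compound's summary signature perturbs a module gene with
|z| at or above 2 (a cutoff is needed for a finite, drawable network; it is
configurable). `select_candidates()` keeps compounds that (i) are
significantly inversely related to the target query, (ii) are not
significantly positively related to any protected query (a strict
point-estimate variant is available via `protected_rule`), and (iii)
perturb at least one module gene or a first neighbor of one in the
interactome; compounds unscored on a protected query pass it, with a log
message.

## Synthetic data: what it emulates and what it does not

`sim_config()` fixes the study conditions; every generator is a pure
function of the config, including its seed. The default sample is a
20 x 20 grid at 100 micrometer spacing (400 locations, Visium-like), 120
genes, 3 cell types arranged as vertical region bands. Counts are negative
binomial (`dispersion = 2`) around a mixture model: each location's
expected expression is the fraction-weighted sum of cell-type profiles,
with Dirichlet fractions concentrated (weight 8 vs 1) on the region's own
type — the same latent fractions that the fraction/deconvolution generator
reports, so the deconvolution inputs are consistent with the counts by
construction rather than fabricated independently. Each type carries 12
up-regulated markers (4-fold) and 12 down-regulated markers (1/4-fold);
markers additionally follow the spatial gradient
`exp(sv_effect * (x/x_max - 1/2))` (`sv_effect = 2`) within their own
type, and 5 planted SV genes follow it in every type. Gradient directions
alternate between graded genes and the graded block is rescaled per
location to constant mass, so expected library size is position-independent
and normalization cannot leak spatial structure into the null genes — that
choice is what makes the null-calibration checks meaningful. Five
mitochondrial genes are scaled to per-location fractions uniform in
2–10%. CV values are drawn so that 30% of fraction entries exceed the 0.5
clipping bound, and the enumerated entries are the clipping ground truth.
The perturbation library holds 200 compounds (one signature each); five
planted reversal compounds shift the target query's up-genes by −3 and
down-genes by +3 on top of the same standard-normal noise as the decoys,
so a zero magnitude reduces them to decoys exactly.

The generators emulate overdispersed UMI counts, soft regional cell-type
structure, noisy deconvolution, and a connectivity-style library. They do
not emulate segmentation errors, spatial transcript diffusion, batch
effects, gene-gene correlation beyond the type/region structure, or
realistic library-size gradients — so passing tests demonstrate the
pipeline's statistical machinery, not robustness to those artifacts.

At this desk scale (400 locations, ~800 pseudo-cells, 120 genes, 200
compounds, 500–1000 permutations per stage) the full pipeline runs in
seconds to a couple of minutes on one CPU; these sizes are the package's
chosen simulation conditions throughout the tests and examples.

## Numerical and engineering choices

* All permutation streams are seeded; stage outputs embed the seed and
  parameters in `#`-prefixed headers, and a fixed configuration reproduces
  every result table byte for byte.
* Rank ties (z-scores, ordering of equally significant DEGs) break
  lexicographically by gene symbol, never by memory order.
* Degenerate inputs are first-class: constant genes flag an undefined
  statistic with `p = 1`; empty samples pass QC as empty with zeroed
  reports; an all-adjacent or all-isolated neighborhood split returns an
  empty result with a warning rather than an error.
* Gene identity is the case-sensitive symbol string; no alias resolution.
* MatrixMarket indices are 1-based on disk per the standard; coordinates
  are real-valued micrometers with no grid assumption.

## Known limitations

* The sign-conditional permutation p-value is anti-conservative under the
  null (see above); compound *rankings* are unaffected.
* Moran's I detects smooth autocorrelation; spatially structured variance
  with zero autocorrelation (e.g. periodic patterns at the neighbor
  spacing) can escape it.
* The distance-based interaction score ignores ligand diffusion physics
  and directionality; it is a screening statistic.
* Pseudo-cell expression inherits deconvolution errors multiplicatively
  through the fraction division; the `min_fraction` guard bounds but does
  not remove this.
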