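---
title: "Methods: estimating and removing barcode swapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and removing barcode swapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapqc)
```

# The problem

Multiplexed libraries on patterned flow-cell sequencers exchange a small
fraction of reads: free sample-index primers anneal to foreign library
molecules and are extended, so the resulting read carries the wrong sample
index. The cDNA insert, and in droplet protocols the in-droplet cell barcode
and UMI, are untouched — only the *sample* assignment moves. Everything in
this package follows from that one mechanistic fact.

# Plate-based estimation

## Impossible-combination regression

In plate protocols a cell is identified by a (row barcode, column barcode)
pair. If two plates on the same lane use disjoint barcode sets, pairs that
mix plates are *impossible*: no library was prepared with them. A single
swap of either barcode moves a read from an expected combination to a
combination sharing exactly the other barcode, so the reads "available" to
land in impossible target $t$ are

$$A(t) = \sum_{y \,\in\, \text{expected},\; \text{share one}(t,y)} L_y ,$$

with $L_y$ the library size of $y$. Under per-read swapping at rate $f$ with
uniform destinations, the expected occupancy of $t$ is proportional to
$A(t)$, and we fit by ordinary least squares

$$\text{obs}(t) = \alpha + m\,A(t) + \varepsilon .$$

**Intercept.** The model is fitted *with* an intercept even though the
mechanism predicts $\alpha = 0$: a constant contamination or misassignment
floor would otherwise bias the slope, and with $\alpha$ present it is
absorbed and reported as a diagnostic instead. Combinations with zero
available reads stay in the fit — they are what identifies $\alpha$.

**From slope to fraction.** $m$ is the fraction of available reads captured
by *one* destination. A swapping read replaces one of its two barcodes, so
it has $D = (R - 1) + (C - 1)$ possible destinations ($R$, $C$ = total
row/column barcodes on the lane); double swaps are second order in $f$ and
neglected. The reported fraction is $\hat f = \hat m D$ and its standard
error is the slope's standard error times $D$. $D$ is recorded in the
diagnostics so any alternative destination convention can be audited. Under
the package's own generative model this convention is consistent: for two
8×12 plates with homogeneous library sizes the expectation of $\hat m D$
works out to $1.002\,f$.

## Cross-platform model

When the same plate is sequenced on a low-swapping reference machine and on
a patterned flow cell, we build three gene-length predictors per cell from
the reference counts: the cell itself ($x_i$), the sum of cells sharing
exactly one barcode ($s_i$), and the sum of cells sharing none ($n_i$). One
plate-level model

$$\text{swapped}(g, i) = a\,x_i(g) + b\,s_i(g) + c\,n_i(g)$$

is fitted pooled over all (gene, cell) pairs by non-negative least squares
(coefficients are contributions of read pools and cannot be negative; the
active-set solver in `pracma::lsqnonneg` handles the constraint exactly).
The swapped fraction is the share of the fit attributable to other cells,

$$\hat f = \frac{bS + cN}{aX + bS + cN},$$

with $X, S, N$ the grand totals of the three predictors over the fitted
cells. Before fitting, reference counts are rescaled so both platforms have
equal grand totals — otherwise sequencing-depth differences leak into $a$.
Uncertainty comes from a nonparametric pairs bootstrap over cells
(default 100 resamples, seedable): cells are resampled with replacement,
their existing predictor columns re-pooled, and the model refitted.

The single pooled $b$ deliberately averages over the two swap axes (row
swaps have $R-1$ destinations, column swaps $C-1$), which is an
approximation when the plate is not square; empirically, on the package's
simulator with 8×12 plates the induced bias is well inside the
between-plate spread (the recovery tests assert this).

## Gene-wise test

Per gene, the two-term model $y_g = a_g x_g + b_g s_g$ is fitted across
cells without intercept — the no-shared-barcode term is second order and
omitted — and $b_g = 0$ is tested two-sidedly with $n - 2$ degrees of
freedom, followed by Benjamini–Hochberg adjustment across tested genes. The
fits are computed from the closed-form 2×2 normal equations vectorised
across genes; a unit test pins them to `stats::lm` to eight decimals. Genes
with all-zero reference counts, collinear predictors
($\det < \sqrt{\epsilon}\, S_{xx} S_{ss}$), or fewer cells than parameters
are reported untested. A gene whose fit is numerically perfect (zero
residual variance) gets $p = 1$: exact reproduction of the reference is no
evidence of swapping.

## Free-barcode association

`free_barcode_association()` is plain OLS of per-plate fraction estimates on
per-plate free-barcode/cDNA concentration ratios (given numbers; trace
quantification is upstream of this package), with a two-sided $t$ test of
the slope and a 95% confidence band for plotting. At least three plates and
non-constant ratios are required.

# Droplet-based detection and correction

## Excess sharing

For samples $A$, $B$ with $n_A$, $n_B$ observed barcodes and overlap $k$
from a pool of $N$, the p-value is the hypergeometric upper tail
$P(X \ge k)$, computed as the survival function at $k - 1$, BH-adjusted
across pairs. The pool defaults to the standard 10x whitelist size
$N = 737{,}280$; passing `pool_size = NULL` conditions on the union of
observed barcodes instead, for data where the whitelist is unknown. The
explicit-$N$ default is the stricter, more interpretable choice: the union
option is there because the right conditioning is genuinely arguable.

## Exclusion cost

Dropping every shared barcode costs, in expectation,
$1 - (1 - c/N)^{S-1}$ of all cell libraries (each sample draws $c$ barcodes
without replacement; samples are independent). `simulate_cell_exclusion()`
verifies the closed form by direct simulation (default 10 repetitions with
an explicit seed, Monte-Carlo standard error reported so any comparison is
self-scaling). At $S = 30$, $c = 20{,}000$, $N = 737{,}280$ the expectation
is ≈ 0.55 — the motivation for molecule-level cleaning. The conclusion is
insensitive to the exact contemporary whitelist size within a factor of
about 1.2.

## Molecule removal

Records are grouped across samples by the key (cell barcode, UMI, gene).
Chance key collisions between samples require agreeing on all three labels
and are combinatorially rare; multi-sample keys are therefore treated as one
molecule spread by swapping. With read fractions $f_s$ per sample:

* single-sample keys are retained;
* if $\max_s f_s \ge$ `min_frac` (default 0.8), the argmax sample is the
  origin — the molecule is kept there and removed from all others;
* otherwise the origin is unresolvable and the molecule is removed from all
  samples.

`min_frac` must exceed 0.5: two samples with $f_s \ge$ `min_frac` $> 0.5$
would sum past 1, so the origin, when it exists, is unique and no
tie-breaking rule is needed. The boundary is inclusive (a sample holding
exactly 80% of reads is an origin). Values ≤ 0.5 are rejected rather than
tie-broken. Gene IDs are opaque and matched exactly; multi-mapping
resolution is assumed upstream. Cleaned output written by
`write_cleaned_counts()` counts distinct molecules (UMIs), not reads, per
(gene, barcode), matching standard droplet quantification.

The cleaner never alters a record's read count and never adds records, so
per sample `in = retained + removed_swapped + removed_unresolved`
(asserted on every run), and it is idempotent: its output contains no
multi-sample keys.

# The simulators

The simulators exist to give every estimator and the cleaner a ground
truth; they emulate the *swapping mechanism* faithfully and the *biology*
only as far as the methods care.

* **Mechanism.** Swapping is per read, independent, single-barcode (plate)
  or single-sample-label (droplet), with uniform destinations. Uniformity
  is an assumption, not an observation — nothing in the method requires it,
  but the simulator's destination law is the simplest consistent with
  proportional occupancy of impossible combinations. Read totals are
  conserved (swapping relabels, never creates).
* **Expression.** Gene structure is exchangeable negative-binomial over
  lognormal gene weights. The estimators use totals and linear pooling
  only, so realistic gene–gene covariance, cell types and trajectories are
  deliberately absent. Passing tests therefore show the statistical
  machinery is correct under the stated mechanism — not that real tissues
  look like this.
* **Not modelled.** Ambient RNA and empty droplets, UMI sequencing errors
  and collapsing, barcode sequence errors, free-barcode extension kinetics.
  UMI collisions *are* modelled (random 10-mers over ACGT, collisions
  allowed and truth-labelled) because the cleaner must tolerate them.

Key defaults, chosen once as a realistic well-sequenced experiment:

| parameter | default | rationale |
|---|---|---|
| plate `mean_reads` / combination | 5,000 | two 96-well plates ≈ 10⁶ mapped reads on a lane share |
| `dispersion` (NB size) | 5 (plate), 2 (cells) | moderate library-size variability |
| droplet `mean_molecules` / cell | 50 | modest cells; scaled up via `large_factor` for donors |
| `mean_reads` / molecule | 20 | deep 10x sequencing; at this depth a molecule essentially never transfers *all* its reads (which would hide it from the cleaner) and rarely drops below an 80% origin share |
| `swap_fraction` | 0.02 | the patterned-flow-cell regime; 0.002 mirrors non-patterned machines |
| `pool_size` | 737,280 | standard 10x cell-barcode whitelist |
| UMI length | 10 nt | 10x v2-style chemistry |

Truth labels mark, for each output droplet record, its origin sample
(majority-read contributor, relevant only for rare collisions) and whether
it is swapped-in; planted "donor-only large cells" get barcodes excluded
from other samples' draws, producing the artefactual-library scenario.

# Validation scale and numerical choices

The test suite validates at desk scale, sized as the smallest problems where
the asymptotics visibly hold: plate recovery on two 8×12 plates at ~10⁶
reads ($f \in \{0.002, 0.02\}$, within 3 SE); cross-platform recovery
exactly on model-generated data and across 16 independently simulated 96-cell
plates at $f = 0.0228$ (mean within 2 between-plate SDs); cleaning on
4 samples × 2,000 cells at $f = 0.02$ (precision and recall of swapped-record
removal ≥ 0.99 against truth labels); never-multiplexed controls bounded by
the analytic collision expectation $M_1 M_2 / (N \cdot 4^{10} \cdot G)$;
null calibration of the gene-wise $t$ test (KS uniformity at 1000 genes,
type-I error within binomial 99% bounds at 200 genes) and of the sharing
test on independent draws.

Numerical details worth knowing: estimated fractions are clamped to
$[0, 1]$ (the raw slope stays in the diagnostics); `estimate_swap_impossible`
refuses designs with fewer than 3 impossible combinations or constant
availability; the cross-platform bootstrap can be disabled (`n_boot = 0`,
`std_error = NA`) when only the point estimate is needed, as in the
16-plate recovery run; all simulator and bootstrap seeds are applied to a
local RNG scope and restore the caller's stream.

# Known limitations

The cross-platform fraction formula interprets *pooled* coefficient totals;
per-cell heterogeneity in swap rates is averaged over. The $D$ multiplier
assumes destination-uniform single swaps; lane compositions with very
unequal plate sizes would need a different convention (the diagnostics
expose $m$ and $D$ separately for exactly this reason). The cleaner cannot
recover a molecule whose reads all swapped away from their origin — it sees
a single-sample key and retains it in the wrong sample; at realistic read
depths this is vanishingly rare, but at one read per molecule it is not,
and the cleaner's guarantees weaken accordingly. Cell calling here is a
plain UMI threshold; ambient-aware callers are out of scope.
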