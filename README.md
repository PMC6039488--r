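# swapqc

Quantify, detect and remove **barcode swapping** (index hopping) in
multiplexed single-cell RNA-seq experiments.

On patterned flow-cell Illumina machines (HiSeq 4000/X, NovaSeq), free
sample-index primers can extend on foreign library molecules, so a few
percent of reads end up assigned to the wrong multiplexed library. For
plate-based scRNA-seq this mixes expression between cells; for droplet
(10x-style) experiments it can fabricate entire "artefactual" cell
libraries: molecules from a large cell in one sample reappear under the same
cell barcode in another sample and pass cell calling. `swapqc` is for
sequencing-facility QC and scRNA-seq analysts who multiplex libraries and
need to (a) measure how much swapping their run suffered and (b) clean
droplet data before analysis.

## What it computes

**Plate experiments — two independent estimators of the swapped-read
fraction.**

1. *Impossible-combination regression.* With two plates that share no
   barcodes, row/column combinations mixing plates are "impossible": any
   reads there came from swapping. For each impossible combination *t*, the
   observed library size is regressed on the reads available to swap into it
   (the summed library sizes *A(t)* of expected combinations sharing exactly
   one barcode with *t*):

   *obs(t) = α + m·A(t) + ε.*

   The slope *m* is the per-destination swap rate; a swapping read has
   *D = (R−1) + (C−1)* single-swap destinations (R rows, C columns in total),
   so the swapped-read fraction is *f = m·D*, with the standard error scaled
   the same way.

2. *Cross-platform linear model.* When the same plate is sequenced on a
   non-patterned (reference) and a patterned machine, each cell's affected
   profile is modelled as a non-negative linear combination of reference
   predictors — itself (*x*), cells sharing exactly one barcode (*s*), cells
   sharing none (*n*): `swapped = a·x + b·s + c·n`, fitted pooled over all
   (gene, cell) pairs by non-negative least squares. The swapped fraction is
   the relative contribution of other cells, *(bS + cN)/(aX + bS + cN)*, with
   a cell-resampling bootstrap for the standard error. A gene-wise variant
   (`genewise_swap_test()`) tests each gene's swapping term, and
   `free_barcode_association()` regresses per-plate fractions on
   free-barcode/cDNA concentration ratios.

**Droplet experiments.**

- `sharing_test()` — upper-tail hypergeometric test of excess cell-barcode
  sharing between every pair of samples (population = barcode whitelist,
  default 737,280), BH-adjusted.
- `expected_exclusion_fraction()` / `simulate_cell_exclusion()` — the cost of
  the naive fix (drop all shared barcodes): *1 − (1 − c/N)^(S−1)*, which
  already exceeds 50% at 30 samples of 20,000 cells.
- `remove_swapped_molecules()` — the molecule-level fix: molecules observed
  in several samples with the same (cell barcode, UMI, gene) key are almost
  surely one swapped molecule; if one sample holds ≥ 80% of the reads it
  keeps the molecule and all other samples lose it, otherwise it is removed
  everywhere.
- `call_cells_threshold()` — a minimal UMI-threshold cell caller to
  demonstrate artefact libraries appearing/disappearing around cleaning.

**Simulators** (`simulate_plate()`, `simulate_crossplatform()`,
`simulate_droplet()`) generate both experiment types with a known injected
swap fraction and per-record truth labels, so every estimator and the
cleaning rule are validated against ground truth.

## Worked example

```r
library(swapqc)

# two 96-well plates with disjoint barcode sets
design <- plate_design(
  row_barcodes = list(P1 = sprintf("R%02d", 1:8),  P2 = sprintf("R%02d", 9:16)),
  col_barcodes = list(P1 = sprintf("C%02d", 1:12), P2 = sprintf("C%02d", 13:24))
)
sim <- simulate_plate(design, mean_reads = 5000, swap_fraction = 0.02, seed = 1)
sim$counts
#> <combination_counts> 384 combinations (192 impossible), total reads 922,430
estimate_swap_impossible(sim$counts)
#> <swap_estimate> 1.717% ± 0.221%  (impossible_regression)
```

The injected 2% swap rate is recovered within 1.3 standard errors from under
a million reads; `tidy()` returns the same numbers as a one-row tibble and
`plot_impossible_regression(sim$counts)` draws the underlying regression.

```r
simd <- simulate_droplet(n_samples = 3, cells_per_sample = 500,
                         mean_molecules = 40, swap_fraction = 0.02, seed = 2)
sharing_test(simd$tables)
#>   sample_a sample_b   n_a   n_b overlap pool_size p_value adjusted_p
#> 1 S1       S2        1454  1449    1413    737280       0          0
#> ...
cleaned <- remove_swapped_molecules(simd$tables)
cleaned$report
#>   sample molecules_in retained removed_swapped removed_unresolved
#> 1 S1            28429    20965            7449                 15
#> ...
```

Every sample pair shares far more of the 737,280 possible barcodes than
chance allows (p ≈ 0): swapped-in molecules have carried donor barcodes into
the other samples. Cleaning removes those swapped-in records (about a quarter
of all records at this read depth) and almost nothing else; with truth labels
from the simulator, removal precision and recall both exceed 0.99.

A command-line interface wrapping the same functions ships in
`inst/cli/swapqc.R`:

```sh
Rscript inst/cli/swapqc.R exclusion-cost --samples 30 --cells 20000 --json out.json
Rscript inst/cli/swapqc.R droplet-clean --samples S1.tsv S2.tsv --out-dir cleaned/ --report report.json
```

## Limitations

The simulators use exchangeable negative-binomial expression and uniform
swap destinations; they validate the estimators' statistical machinery, not
biological realism (see the methods vignette, `vignettes/barcode-swapping.Rmd`).
Alignment, demultiplexing, barcode sequence correction and ambient-RNA-aware
cell calling are out of scope: counts and molecule tables are the input
boundary.
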