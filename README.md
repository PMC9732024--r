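# umiopt

Optimizing the minimum-UMI quality-control threshold for droplet scRNA-seq.

## What it is for

Standard scRNA-seq QC discards every cell below a fixed UMI floor before any
cell identities are known. Natively low-expression populations — T- and
B-lymphocytes above all — live exactly in that discarded range, so a
depth-blind floor distorts the measured composition of a tissue. `umiopt`
is for analysts who already have a stringently filtered, well-annotated
"gold standard" subset of their data and want to know: *how much lower
could the floor go while cells remain accurately classifiable?*

The framework:

1. computes per-cell QC statistics and partitions cells into
   high-quality / rescue-pool / excluded sets;
2. splits the gold standard per label (400 cells per label, 1:1
   train/test), finds one-vs-rest marker genes, and trains two multiclass
   classifiers — a Spearman-correlation reference classifier and a
   gene-pair random forest (1,000 trees over binary top-pair features);
3. downsamples the held-out cells with a per-gene multiplicative Poisson
   transform (each gene's count times an independent Poisson(λ) deviate,
   λ = target / total, so the expected cell total equals the target) to a
   grid of target depths from 0 to 4,000 UMIs;
4. computes a multiclass AUROC (pairwise-averaged one-vs-one, Hand & Till;
   scaled by 2/(c(c−1))) at every grid point and selects the smallest
   threshold whose AUROC reaches a cutoff (0.9 by default);
5. rescues the cells that only failed the original depth floor but clear
   the optimized one, classifies them, and reports per-class gains and
   per-sample composition shifts.

A negative-binomial simulator of multi-cell-type count data (type-specific
depth tiers, planted markers, mitochondrial genes, a low-quality tail)
makes every stage testable without any external download.

## Worked example

```r
library(umiopt)

sim   <- simulate_dataset(sim_config(seed = 1))
stats <- compute_cell_stats(sim$matrix) |> apply_qc()
table(stats$partition)
#> high_quality  rescue_pool     excluded
#>         1210          774           16

labs  <- sim_labels(sim$truth, "cell_type")
gold  <- labs[labs$cell_barcode %in%
              stats$cell_barcode[stats$partition == "high_quality"], ]
split <- stratified_split(gold, seed = 1)
model <- train_correlation(sim$matrix[, split$train],
                           gold[gold$cell_barcode %in% split$train, ])

sweep <- threshold_sweep(sim$matrix[, split$test], gold, list(model),
                         grid = c(0L, 50L, 450L, 1000L, 2000L, 4000L),
                         seed = 1)
tidy(sweep)[, c("threshold", "mean_umis", "mean_genes", "auroc")]
#>   threshold mean_umis mean_genes auroc
#> 1        NA    3425.       904.  1
#> 2         0       0          0   0.5
#> 3        50      50.3       14.7 0.522
#> 4       450     451.       124.  0.621
#> 5      1000    1001.       252.  0.720
#> 6      2000    1999.       422.  0.830
#> 7      4000    4022.       628.  0.950
```

The control row (`threshold = NA`) shows the untransformed test set is
perfectly classifiable; the realized mean UMIs track each target; AUROC
falls to chance (0.5) at target 0 and rises with depth. On this synthetic
fixture only 120 of 1,500 genes carry class signal, so accurate
classification needs more depth than on real data — see the vignette for
why, and for what the synthetic results do and do not show.

Applying a paper-style optimized threshold of 450 UMIs to the whole
dataset:

```r
report <- rescue_cells(sim$matrix, stats, list(model), 450, gold,
                       initial_threshold = 1500)
report
#> <rescue_report> threshold 1500 -> 450: 1210 initially retained,
#>   658 rescued (+54.4%), 116 still excluded
tidy(report)
#>   granularity label            initial_count rescued_count percent_gain
#> 1 cell_type   B-cells                    201           234        116.
#> 2 cell_type   T-cells                    236           218         92.4
#> 3 cell_type   epithelial cells           417            75         18.0
#> 4 cell_type   fibroblasts                356           131         36.8
```

The gain concentrates in the shallow lymphocyte-like types — the retention
asymmetry the framework exists to correct. `autoplot(sweep)` and
`autoplot(report)` draw the sweep curves and the gain bars;
`run_pipeline(pipeline_config(seed = 1), "out/")` runs every stage end to
end and writes checksummed artifacts plus a `manifest.json`.

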