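# mibench

Benchmarking discrete mutual-information estimators and discretization
methods for gene regulatory network inference with C3NET.

## What it is for

MI-based network inference estimates the dependence of every gene pair
from expression data and keeps the strongest links. The estimate depends
on two upstream choices that are easy to overlook: how the continuous
profiles are discretized, and which entropy estimator is plugged into
`I(X;Y) = H(X) + H(Y) − H(X,Y)`. mibench is a simulation benchmark that
measures how those choices propagate into the accuracy of the inferred
network, for the conservative causal core algorithm (C3NET: each gene
contributes at most its single most significant maximal-MI edge).

It implements, as plain R functions over tibbles and matrices:

* **Simulation** — sparse Erdős–Rényi reference networks; steady-state
  expression ensembles with Hill-type regulator→target coupling,
  activator/repressor signs, Uniform(0,1) root activities and Gaussian
  observation noise; unconnected genes kept as pure-noise genes.
* **Discretization** — equal frequency, equal width, global equal width;
  bin count `B = round(sqrt(N))`.
* **Estimators** — empirical, Miller–Madow, shrinkage (James–Stein
  toward uniform), Schürmann–Grassberger (Dirichlet pseudocounts), all in
  bits, marginals taken from the joint table's margins.
* **C3NET** — pooled permutation null, add-one p-values,
  Benjamini–Hochberg or Bonferroni correction, per-gene maximal
  significant edge.
* **Evaluation** — precision–recall curves over the all-pairs MI ranking
  and trapezoid AUC-PR; ensemble aggregation into per-edge true positive
  rates; chain-like (Class I, `deg(i)+deg(j) ≤ 4`) versus hub-attached
  (Class II) edge classes.
* **Heterogeneity audit** — per-gene Anderson–Darling normality tests,
  Stouffer-combined pair p-values, Kolmogorov–Smirnov pair-distribution
  tests, and the rank accumulation comparing where true-positive and
  false-positive edges sit among the pair p-values.

## A worked example

```r
library(mibench)
library(dplyr)

# one condition: 40 genes, 1% edge density, 10 datasets of 50 samples
cfg <- benchmark_config(n_genes = 40, edge_densities = 0.01,
                        sample_sizes = 50, n_datasets = 10,
                        estimators = c("miller_madow", "empirical"),
                        discretizations = c("equal_width", "equal_frequency"),
                        n_permutations = 2000, seed = 1)
res <- run_benchmark(cfg, verbose = FALSE)
summarize_benchmark(res$records)
#> # A tibble: 4 × 8
#>   density n_samples estimator    discretization  n_datasets auc_pr_median auc_pr_iqr n_edges_median
#>     <dbl>     <int> <chr>        <chr>                <int>         <dbl>      <dbl>          <dbl>
#> 1    0.01        50 empirical    equal_frequency         10         0.921     0.0885             12
#> 2    0.01        50 empirical    equal_width             10         0.959     0.0331             12
#> 3    0.01        50 miller_madow equal_frequency         10         0.929     0.0833             12
#> 4    0.01        50 miller_madow equal_width             10         0.962     0.0200             12
```

`auc_pr_median` is the ensemble median of the area under the
precision–recall curve of the all-pairs MI ranking against the true
network — 1.0 is perfect recovery, and a random ranking would sit near
the edge prevalence (≈ 0.015 here: 12 true edges among 780 pairs). The
equal-width rows above the equal-frequency rows, with Miller–Madow
slightly ahead of the plug-in estimator and markedly more stable (lower
IQR), is the benchmark's central finding at this condition; at larger
sample sizes every combination saturates toward 1. `summarize_class_tpr(res$class_tpr)` gives the analogous
medians of per-edge true positive rates split by edge class, and
`plot_auc_by_discretization()`, `plot_auc_by_sample_size()`,
`plot_class_tpr()` and `autoplot()` methods draw the standard figures.

Lower-level entry points mirror the pipeline stages: `sample_er_network()`
→ `orient_for_simulation()` → `simulate_expression()` /
`generate_ensemble()` → `mi_matrix()` → `permutation_null()` +
`edge_significance()` → `c3net_infer()` → `precision_recall_curve()` /
`ensemble_network()` / `classwise_tpr()`, plus
`heterogeneity_analysis()` for the data-heterogeneity audit. A thin CLI
wrapper ships at `inst/scripts/benchmark.R`.

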