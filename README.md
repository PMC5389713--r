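# mixbench

Benchmarking RNA-seq analysis methods with two-source mixture designs.

## The problem

Control experiments for transcriptomics need a ground truth, but spike-ins
cover few molecules and technical-replication designs produce unrealistically
low, purely technical noise. A **mixture design** solves both problems: RNA
from two reference sources (e.g. two related cancer cell lines) is profiled
pure and mixed at known proportions, with replicates grown independently and
some aliquots deliberately degraded. If gene *g* has concentration *X*<sub>g</sub>
in source A and *Y*<sub>g</sub> in source B, a sample mixed at proportion
*p*<sub>i</sub> must express it at *p*<sub>i</sub>*X*<sub>g</sub> + (1 −
*p*<sub>i</sub>)*Y*<sub>g</sub> — a predictable dose-response for every gene,
which serves as built-in truth for benchmarking.

`mixbench` is for method developers and analysts who want to run this style
of benchmark on simulated data with realistic gene-specific noise, or to
apply its scoring machinery to their own result tables.

## What it provides

* **Simulator** of the titration design: five proportions in triplicate plus
  degraded duplicates of one replicate; negative-binomial counts with
  gene-specific dispersions (low prior degrees of freedom) and a dispersion
  multiplier for degraded samples. Ground truth is returned with the counts.
* **Preprocessing**: CPM expression filter, TMM normalization factors
  (via edgeR), and offset log2-CPM.
* **Gene-wise non-linear mixture model**, fitted to log-CPM by a vectorized
  Gauss–Newton algorithm:

  logCPM<sub>gi</sub> = log2{ p<sub>i</sub>X<sub>g</sub> + (1−p<sub>i</sub>)Y<sub>g</sub> } + ε<sub>gi</sub>,  ε<sub>gi</sub> ~ (0, φ<sub>g</sub>²),

  returning per-gene estimates X̂, Ŷ, the log-ratio M = log2(X̂/Ŷ) and the
  residual standard deviation φ̂. Predicted log fold-changes between any two
  proportions, δ̂(p, q), and the RMSE of a method's estimated log-FCs against
  them (with leave-out refits to avoid data sharing).
* **Benchmark metrics**: sensitivity (detections at an FDR cutoff), recovery
  and inconsistency rates of subtler comparisons against the pure-vs-pure
  anchor, Venn-style overlap counts, plus a minimal moderated-t reference DE
  method and BH adjustment so the harness runs with no external tools.
* **Linear-mixture deconvolution**: informative-gene filter (fold-change > 2
  or < 0.5), closed-form proportion estimation under Y = (1−p)N + pT, profile
  deconvolution, and Table-style evaluation against the design truth.
* **5′-position read counting** over non-overlapping exon/intron/intergenic
  BED annotations, with conservative intron (gene body − exon) and intergenic
  (amalgamated − gene body) count arithmetic.
* **Pipeline driver** with YAML configuration and a checksummed JSON manifest.

## Worked example

```r
library(mixbench)

design <- make_default_design()                      # 15 good + 5 degraded samples
ref    <- simulate_reference_profiles(2000, de_fraction = 0.1, seed = 7)
counts <- simulate_mixture_counts(ref, design, lib_size_mean = 2e6, seed = 7)

norm <- log_cpm(filter_by_expression(counts))
fit  <- fit_mixture(norm, design[design$quality == "good", ])
head(fit[, c("gene_id", "Xhat", "Yhat", "M", "phi_hat")], 3)
#>               gene_id       Xhat       Yhat           M   phi_hat
#> gene_00001 gene_00001 4070.38781 4160.52361 -0.03159885 0.2954713
#> gene_00002 gene_00002   24.08143   25.02004 -0.05516316 0.2996007
#> gene_00003 gene_00003   46.17538   51.86580 -0.16765987 0.6950585

sqrt(mean((fit$M - log2(ref$R))^2))                  # log-ratio recovery error
#> [1] 0.2688727

report <- run_benchmark(counts, design, comparisons = list("100:000", "075:025"))
report$rates
#>       method  anchor comparison   recovery inconsistency
#>  moderated-t 100v000    100v000 1.00000000             0
#>  moderated-t 100v000    075v025 0.08695652             0
report$sensitivity
#>       method comparison sensitivity
#>  moderated-t    100v000         184
#>  moderated-t    075v025          16
```

Reading the output: `Xhat`/`Yhat` are the estimated per-gene concentrations
of the two sources on the CPM scale, `M` their log2 ratio (here recovered
with RMS error 0.27 under gene-specific noise), and `phi_hat` the residual
noise level. The benchmark report shows the anchor comparison (pure vs pure)
detecting 184 genes at FDR < 0.05, of which 8.7% are re-detected in the much
subtler 75:25-vs-25:75 comparison — with zero inconsistency, i.e. nothing is
called in the subtle comparison that the anchor missed.

End-to-end, with all outputs and a manifest written to disk:

```r
run_full_pipeline(default_run_config(), out_dir = "run1")
```

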