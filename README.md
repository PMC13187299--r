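# mitostab

Quantitative analysis of global mRNA stabilization in mitotically arrested
cells, for RNA biologists working with transcription-shutoff timecourses
and poly(A) tail-length profiling (PAL-seq / TAIL-seq style data).

Cells stuck in mitosis barely transcribe, yet survive for tens of hours.
`mitostab` implements the pipeline that quantifies how: per-gene mRNA
half-lives estimated from spike-normalized shutoff timecourses, with the
model

```
abundance(t) = a0 · exp(−kd · t),   t½ = ln(2)/kd
```

fit by nonlinear least squares on the linear abundance scale, half-lives
capped to [0.25, 200] h, genes filtered at ≥25 reads in every sample and
reference-condition fits at R² ≥ 0.8 (0.4 variant available); stabilization
ratios and covariate statistics (Spearman with tie correction, strict
FDR < 0.01 & log₂ > 2 style grouping rules, fold-change medians); poly(A)
tail-length distributions with weighted medians, window masses and a
calibrated detector for phased PABPC toeprints (~30-nt periodic bumps);
and a per-molecule stochastic deadenylation simulator in which a
deadenylase shortens free poly(A) quickly but stalls at PABPC-protected
boundaries, reproducing the mitotic toeprint phenotype mechanistically.
Synthetic count and tail generators with known truth make the entire
pipeline testable without any external download.

## Worked example

Simulate a shutoff timecourse with known decay truth, normalize to
spike-ins, fit half-lives; then contrast deadenylation regimes:

```r
library(mitostab)

truth <- generate_decay_truth(n_genes = 500, seed = 1, depth = 5e5)
sim <- simulate_counts(truth)
factors <- compute_size_factors(sim$matrix, "spike_in")
#> compute_size_factors: method=spike_in, 10 reference genes
filtered <- apply_expression_filter(sim$matrix)
#> apply_expression_filter: 442/510 genes retained at >=25 reads in each sample
norm <- normalize_and_average(filtered, factors)
fits <- fit_table(norm, "sim")
#> fit_table(sim): fitting 442/442 genes (0 all-zero excluded)
head(fits[, c("gene_id", "kd_per_h", "half_life_h", "capped", "r2")], 3)
#>      gene_id    kd_per_h half_life_h capped          r2
#> 1 gene_00001 0.251020212    2.761320  FALSE 0.980530834
#> 2 gene_00002 0.076096692    9.108769  FALSE 0.725491227
#> 3 gene_00004 0.006951658   99.709616  FALSE 0.006512548
median(fits$half_life_h)
#> [1] 5.75   # hours; the simulated truth had median 5.6 h
```

Gene 1 decays fast and fits cleanly (t½ 2.8 h, R² 0.98); gene 4 barely
decays over the 6-h window, so its rate is near zero and its R² near zero —
exactly the behavior the one-sided reference-condition R² filter exists to
handle.

```r
cfg_m  <- deadenylation_config(regime = "mitotic", seed = 1)
cfg_g2 <- deadenylation_config(regime = "interphase", seed = 1)
sim_m  <- simulate_tails(cfg_m,  c(0, 4))
sim_g2 <- simulate_tails(cfg_g2, c(0, 4))

median_tail(sim_g2$samples[[2]]); median_tail(sim_m$samples[[2]])
#> [1] 0    # interphase: tails collapse within 4 h of shutoff
#> [1] 60   # mitotic: shortening stalls at PABPC boundaries
sim_g2$degraded_fraction[2]; sim_m$degraded_fraction[2]
#> [1] 0.557
#> [1] 0.222  # boundary stalling shields mRNA from short-tail decay

set.seed(2)
detect_toeprints(tail_distribution(sim_m$samples[[2]]))
#> toeprint_report: period 30 nt (p = 0.001)
#>   peaks at: 30, 60, 90, 120, 150, 180 nt
set.seed(2)
detect_toeprints(tail_distribution(sim_g2$samples[[2]]))
#> toeprint_report: no significant period (p = 1)
```

The mitotic regime shows significant 30-nt-phased toeprints (the PABPC
packing period) while the matched interphase run shows none — the
package's statistical expression of perturbed mitotic deadenylation.

A command-line interface wraps the same functions
(`inst/cli/mitostab`, or `mitostab::run_cli()`): subcommands
`simulate-counts`, `simulate-tails`, `normalize`, `fit`, `compare`,
`tail-profile`, `toeprints`, all seed-deterministic with TSV input/output.

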