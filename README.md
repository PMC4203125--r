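# ripesync

Grape berries within one cluster enter ripening asynchronously — at
mid-véraison (V) a cluster holds green hard (GH), green soft (GS), pink soft
(PS) and red soft (RS) berries side by side — yet five weeks later (PostV)
they converge to a common state. `ripesync` is an R package for quantifying
that convergence from two-timepoint, multi-class designs, for researchers
working on fruit ripening kinetics and developmental synchronization in
transcriptome data.

## What it computes

**Reduction in variance (RV).** For gene *g*, with between-class variances
of class-mean log2 expression `Var_V(g)` and `Var_PostV(g)`,

    RV(g) = Var_V(g) / Var_PostV(g)

tested one-sided against F(k−1, k−1) (k = 3 classes) with Benjamini–Hochberg
FDR control at 0.2. Large RV flags genes whose between-class differences
collapse toward maturity — a ripening-relevance criterion distinct from
plain variance ranking (`rank_overlap()` compares the two).

**Transcriptional distances.** With véraison gaps `a = PS − GS`,
`b = RS − PS` (log2 class means) and within-class V→PostV changes `X, Y, Z`
(GS, PS, RS):

    X_calc = a + b + Z        Y_calc = b + Z

The identity `X_calc − X_obs = mean(RS@PostV) − mean(GS@PostV)` holds
exactly, so the observed-vs-calculated R² measures how completely the PostV
states converged.

**Differential expression and trends.** Moderated paired t-tests
(empirical-Bayes variance shrinkage, BH FDR 0.05) between class pairs define
the DE universe; a pooled contrast of PostV levels against véraison RS
labels each gene up / down / plateau.

**Ripening kinetics.** Reference stages R1–R4 are the RS Brix and
colour-index (`180·h/(L+C)`) values at 0/7/14/21 d. Per-class polynomial
ripening curves are inverted (`days_to_reference()`) to get each class's
days-to-reference, whole-day lag tables, and accumulation rates between
equivalent stages with Tukey HSD letters.

A synthetic-data generator (`simulate_expression()`,
`simulate_physiology()`) emulates the full design — 3 classes × 3 tissues ×
2 stages × 3 replicate plants for expression; 4 classes followed weekly with
7/10/13 d lags for physiology — with ground truth for recovery testing.

## Worked example

```r
library(ripesync)

cfg <- sim_config(seed = 1, n_genes = 2000, tissues = "pulp")
sim <- simulate_expression(cfg)

# DE universe at veraison (three class pairs, FDR < 0.05)
pairs <- list(c("GS","PS"), c("PS","RS"), c("GS","RS"))
res <- lapply(pairs, function(p)
  moderated_paired_ttest(sim$matrix, sim$meta, p, "pulp", "V"))
sapply(res, function(r) sum(r$q < 0.05))
#> 1359 1311 1493
universe <- degenes_union(res, 0.05)   # 1837 genes

# RV distribution over the DE universe
rv <- rv_records(sim$matrix, sim$meta, "pulp", genes = universe)
rv_distribution_summary(rv)$median_fold
#> 22.47514

# observed vs calculated transcriptional distances
d <- compute_distances(sim$matrix, sim$meta, "pulp", genes = universe)
linearity(d, "X")$r_squared
#> 0.9739288

# kinetics: reference stages and R1 lags
phys <- simulate_physiology(cfg)
st <- define_reference_stages(phys)
days <- do.call(rbind, lapply(c("PS","GS","GH"), function(cl) {
  fit <- fit_ripening_curve(phys, cl, "brix")
  data.frame(class = cl, stage = "R1",
             day = days_to_reference(fit, st$brix_ref[1]))
}))
lag_table(days, c(R1 = 0))
#>   class stage day_to_reference lag_vs_rs rounded_lag
#> 1    PS    R1         6.865028  6.865028           7
#> 2    GS    R1         9.899043  9.899043          10
#> 3    GH    R1        13.406672 13.406672          13
```

1837 of 2000 genes are differentially expressed between classes at
véraison; their between-class variance drops a median 22-fold by PostV; the
additive distance model explains 97% of the variance in observed V→PostV
changes; and the under-ripe classes' fitted Brix trajectories recover their
generating 7/10/13-day lags to the whole day.

`run_pipeline(pipeline_config(...))` chains all stages and writes each
stage's TSV/CSV plus a `summary.json`; every artifact is plain text, so a
real expression matrix and physiology table can replace the simulator
without code changes.

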