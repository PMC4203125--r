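---
title: "Methods: quantifying ripening synchronization in berry classes"
author: "ripesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ripening synchronization in berry classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripesync)
```

## The problem

At mid-véraison (V), a single grape cluster carries berries at visibly
different ripening states — green hard (GH), green soft (GS), pink soft (PS)
and red soft (RS) — yet five weeks later (PostV) the same berries have
converged to a narrow physiological and transcriptional window. `ripesync`
implements the statistics needed to quantify that convergence from a
two-timepoint, multi-class design:

* **Reduction in variance (RV)**: per gene, the ratio of the between-class
  variance of expression at V to that at PostV, with a one-sided F-test and
  Benjamini–Hochberg (BH) FDR control (threshold 0.2). Large RV marks genes
  whose between-class differences collapse, i.e. genes that synchronize.
* **Transcriptional distances**: an additive decomposition of each gene's
  V-to-PostV expression change. With véraison gaps `a = PS − GS` and
  `b = RS − PS` (log2 class means) and within-class changes `X`, `Y`, `Z`
  (GS, PS, RS), the model predicts `X_calc = a + b + Z` and
  `Y_calc = b + Z`: an under-ripe berry first traverses the véraison gaps to
  the RS state and then follows the RS programme.
* **Trend classification**: each gene's PostV level is compared against the
  véraison RS level (two-sided pooled-variance contrast, BH FDR 0.05) and
  labelled up, down, or plateau. Plateau genes completed their
  synchronization early post-véraison.
* **Ripening kinetics**: reference stages R1–R4 are the RS Brix/colour-index
  values at 0, 7, 14 and 21 d; per-class regression curves are inverted to
  find when under-ripe classes reach each reference, giving lag tables and
  accumulation rates between physiologically equivalent stages.

Every stage is driven either by user-supplied tables (expression TSV +
metadata TSV + physiology CSV) or by the package's synthetic-data generator,
which emulates the study design and carries ground truth for
parameter-recovery testing.

## The synthetic-data generator

### What it emulates

The expression design is 3 classes × 3 tissues × 2 stages × 3 replicate
plants (54 samples), paired by plant across classes and stages. Per gene and
tissue, on the log2 scale:

1. véraison class means are `μ`, `μ + a`, `μ + a + b` for GS/PS/RS, with
   `a, b ~ N(0, effect_sd_v²)` (default SD 1.0 log2, consistent with most
   differentially expressed genes showing at least 2-fold between-class
   differences);
2. a trend label (up/down/plateau, default mixture 1/3 each — the three
   trends were observed in similar proportions) shifts the common PostV
   target by `±trend_effect` (default 1.0 log2) relative to the véraison RS
   mean;
3. PostV class means scatter around the target with a synchronization
   residual (below);
4. replicates add `N(0, residual_sd²)` noise (default 0.25 log2: replicate
   coefficients of variation of ≤10% on intensity scale translate to
   roughly this order on log2 intensities).

The physiology design is 4 classes × 6 weekly timepoints (days 0, 7, 14,
21, 35, 42) × 6 plants × 5 clusters × 1 berry (30 berries per class per
week). All classes follow one logistic trajectory
`f(u) = asym / (1 + ((asym − start)/start) e^{−rate·u})` evaluated at
`u = day − lag(class)`, with default lags GH 13 d, GS 10 d, PS 7 d, RS 0 d.
The Brix curve (start 12.6, asymptote 24 °Brix, rate 0.0313/d) passes
through the reference values 12.6/13.9/15.3 °Brix at 0/7/14 d; the
colour-index curve (start 3.4, asymptote 7, rate 0.0833/d) does likewise
for 3.4/4.4/5.1.

### Design choices

**Lagged classes are not clipped to the curve start.** The logistic is
evaluated at `day − lag` directly, so under-ripe classes sit *below* the RS
level at day 0, as real green berries do. Clipping them at the curve's
start value would park every class exactly at the R1 reference from day 0,
making lag recovery ill-posed and the early class means flat (which a
strictly increasing fit must reject). Over the default fitting window the
logistic is nearly linear, so a degree-2 fit inverts it with negligible
bias (< 0.05 d noise-free).

**Synchronization residual scale.** The empirical between-class variance at
either stage is the sample variance of k = 3 class means, which includes a
replicate-noise floor `σ²/m` (m = 3 replicates) and has only 2 degrees of
freedom. The generator therefore sets the PostV residual variance to

`s² = max(0, (V + σ²/m)/fold − σ²/m)`,

where `V` is the gene's realized between-class variance of true means at V,
and *scales the drawn residuals to realized sample variance exactly `s²`*
(centred, unit-sample-variance direction times `s`). Without that scaling
the 2-df sampling fluctuation of the residuals themselves would dominate
the realized variance ratio: its median would sit ~40% above the target
(the median of a χ²₂-based variance estimate is ln 2 of its expectation)
and its mean would be tail-dominated. With it, the median realized RV
across genes centres on `rv_fold_target`. Genes whose véraison spread is
too small to exhibit the full fold are floored at `s² = 0` (their PostV
spread is pure replicate noise); consequently the *mean* RV over all genes
remains heavy-tailed — as any ratio of 2-df variance estimates must be —
and the package reports medians alongside means for this reason.

Crucially, the null configuration (`effect_sd_v = 0`, `rv_fold_target = 1`)
lands exactly at `s² = 0`, so both stages' class means are i.i.d. normal
and the variance ratio is exactly F(2, 2) — the F-test calibration tests
rely on this.

**Colour emission.** Only the composite colour index is analysed
downstream, so `L` and `C` are held near constants (32 and 5) with small
noise and the hue angle carries the signal: `h = CI·(L + C)/180`, making
`colour_index()` recover the intended index exactly.

**Physiology noise.** Default per-berry noise is 0.25 °Brix (refractometer
precision plus modest within-class spread — classes are phenotypically
selected, so berries within a class at a given week are homogeneous) and
0.1 colour-index units. At 30 berries per class per week this puts the
standard error of a weekly class mean at ~0.05 °Brix and the
time-to-reference estimates within a few tenths of a day.

**Randomness.** One seeded stream per generator call with a fixed,
vectorised draw order: identical configurations give byte-identical
outputs. (Per-gene sub-streams were considered and rejected: nothing
downstream needs to regenerate a single gene in isolation.)

### What it does not emulate

Real microarray features are out of scope: probe-level intensities,
normalization artefacts, expression-level-dependent variance, and the
nested plant/cluster variance structure (a single replicate-level noise
term is used). The published array-derived counts (1583/1126/491 DE genes
per tissue, mean RV of 24, 15% top-100 overlap) depend on those features
and are **not** reproduced by passing tests here; the pipeline computes
each of those summaries on any input, but their values on synthetic data
characterize the generator, not the biology.

## Statistical details

### Moderated paired differential expression

Paired log2 differences are taken across replicate plants within a
(tissue, stage) block. Per-gene variances `s²` (df = m − 1) are shrunk
toward a prior by empirical Bayes; the prior `(d0, s0²)` is estimated by
method of moments on log variances: if `s² ~ s0² F(d, d0)`, then
`Var[log s²] = trigamma(d/2) + trigamma(d0/2)`, so the excess spread of the
observed log variances over the sampling component determines `d0`
(trigamma inversion by Newton iteration); a non-positive excess means no
detectable heterogeneity (`d0 = ∞`, prior scale = mean variance). The
moderated statistic `t = mean difference / sqrt(var_post/m)` with
`var_post = (d0·s0² + d·s²)/(d0 + d)` is referred to t on `d0 + d` df,
two-sided. The implementation agrees with the independent limma
implementation to machine precision in the test suite, and `prior_df = 0`
reproduces the ordinary paired t exactly. A gene whose variance is zero in
every replicate pair falls back to the pooled mean variance rather than an
infinite statistic.

BH adjustment is applied within each (tissue, stage, pair) family — the
smallest self-contained family, and the default because the published
procedure does not state whether pairs were pooled. The DE universe of a
tissue is the union of genes significant in any of the three class pairs at
FDR 0.05, evaluated at V.

### RV and its F-test

"Between-class variance" is computed on the k = 3 class means (denominator
k − 1 = 2), not on the 9 pooled replicates: the quantity of interest is the
between-class spread, and replicate noise is a separate stratum. The
resulting default F-test df of (2, 2) is consistent with the lenient 0.2
FDR threshold the procedure uses (an F(2,2) test has little power). The
test is one-sided — RV is defined as a reduction. Infinite folds
(PostV variance exactly 0) and undefined 0/0 folds are flagged and excluded
from distribution means rather than silently averaged.

### Distances and linearity

The decomposition carries an algebraic identity,
`X_calc − X_obs = mean(RS@PostV) − mean(GS@PostV)` (and the Y analogue),
which holds to machine precision for every gene on every input. This is
the model's testable core: the calculated and observed distances coincide
exactly in proportion to how completely the PostV class means converge, so
the observed-vs-calculated R² is a direct measure of synchronization.
The regression is calculated-on-observed; R² is symmetric for OLS after
centring, so the headline metric does not depend on the axis choice (which
the source figure leaves ambiguous). Log2 is the working scale; fold-change
exports are `2^distance`.

### Trends

The contrast is a pooled two-group t of (all PostV samples) against
(véraison RS samples) — the simplest contrast consistent with "mean
expression level among berry classes at PostV" vs véraison RS. A per-class
mode is available (`mode = "per_class"`), where a gene is up/down if any
class's contrast is significant. Labels partition the universe exhaustively:
up ⟺ q < α and estimate > 0; down ⟺ q < α and estimate < 0; plateau
otherwise.

### Kinetics

* **Colour index**: the printed formula "180h/L+C" is ambiguous; the
  default is `180·h/(L + C)`, with `180·h/L + C` selectable
  (`formula = "sum"`). The generator is self-consistent under either.
* **Regression form**: degree-2 polynomial of the class-mean response
  against day over a default window of 0–21 d, both configurable. The exact
  published equations are not available; a quadratic accommodates the
  observed deceleration while remaining monotone and invertible over the
  window, and fits that are not strictly increasing are rejected.
* **Inversion**: earliest crossing within the window (extended above by a
  14 d margin, truncated where an extrapolated polynomial turns over),
  root-bracketed to 1e-6 d. On a monotone fit the crossing is unique and
  physically meaningful.
* **Lags** are reported from the Brix response by default: the published
  whole-day lags (7/10/13 at R1; 1/3/5 at R3) match the Brix rows of the
  reference-day table (6.5/9.9/13.0 and 15.4/17.0/19.1), under half-up
  rounding — which is why `lag_table()` rounds half-up rather than using
  R's round-half-even.
* **Rates** between consecutive reference stages are Δreference/Δdays; the
  class comparison fits per-plant curves, computes per-plant R1→R3 rates,
  and applies one-way ANOVA with Tukey's HSD at α = 0.05, summarised as a
  compact letter display. With zero within-group variance and unequal
  means the p-values are flagged degenerate and letters are assigned from
  distinct means.

## Numerical and scale choices

The default problem sizes — 2,000 genes, one tissue for expression tests,
30 berries per class per week for physiology — were chosen so that
Monte-Carlo properties (median RV within 25% of target, trend recovery
≥ 90%, lag recovery within 0.5 d, null Kolmogorov–Smirnov calibration)
are stable across seeds while a full test run completes in seconds.
Tolerances used in the tests: algebraic identities at 1e-12, curve
inversion at 1e-6 d against a 1e-4 d grid oracle, limma agreement at 1e-8,
Tukey-vs-permutation agreement at 0.05 with 10⁴ permutations.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1, n_genes = 2000,
                                        tissues = "pulp"))
bundle <- run_pipeline(cfg, outdir = "ripesync-run")
bundle$summary$linearity_r2$pulp      # observed-vs-calculated R^2
bundle$kinetics$lags                  # days-to-reference and rounded lags
```

Stage artifacts are plain TSV/CSV with stable headers, so any stage can be
re-run on user data (e.g. a real expression matrix) in place of the
simulator without code changes.

## Known limitations

* Two timepoints cannot resolve *when* synchronization happens between V
  and PostV; plateau genes bound it to the early post-véraison window, but
  phase-resolved timing is out of scope by design.
* The RV mean is a heavy-tailed statistic at df (2, 2); medians and the
  fold-bin table are the robust summaries.
* The generator's single noise stratum understates the plant/cluster
  nesting of real designs; recovery results should be read as
  best-case-under-the-stated-model, not as guarantees on real arrays.
* Elasticity is emitted for completeness but not used in staging.
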