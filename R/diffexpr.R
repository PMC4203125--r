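#' Moderated paired t-test between two berry classes
#'
#' Per gene, paired log2 differences between the two classes are taken across
#' replicate plants within one tissue and stage. Per-gene variances are
#' shrunk toward a pooled prior by empirical Bayes ([squeeze_variances()]),
#' and the moderated statistic `t = mean difference / sqrt(var_post / m)` is
#' referred to a t distribution on `d0 + (m - 1)` degrees of freedom
#' (two-sided). Benjamini-Hochberg adjusted q-values are computed within the
#' (tissue, stage, pair) family.
#'
#' `log2fc` is oriented as `pair[2] - pair[1]`; swapping the pair flips its
#' sign and the statistic's sign but leaves p-values unchanged.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param meta sample metadata (see [read_sample_metadata()]); replicates
#'   must pair the two classes.
#' @param pair character vector of two class labels.
#' @param tissue,stage block selectors.
#' @param prior_df optional override of the prior degrees of freedom; `0`
#'   disables moderation (ordinary paired t), `Inf` fully pools. `NULL`
#'   (default) estimates the prior from the data.
#' @return data.frame with one row per gene: `gene, pair, tissue, stage,
#'   log2fc, t_mod, df_total, p, q`.
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 50))
#' res <- moderated_paired_ttest(sim$matrix, sim$meta, c("GS", "RS"),
#'                               tissue = "pulp", stage = "V")
#' head(res)
#' @export
moderated_paired_ttest <- function(mat, meta, pair, tissue, stage,
                                   prior_df = NULL) {
  if (length(pair) != 2L) stop("'pair' must name exactly two classes")
  m1 <- select_samples(meta, tissue = tissue, stage = stage, class = pair[1L])
  m2 <- select_samples(meta, tissue = tissue, stage = stage, class = pair[2L])
  reps <- intersect(m1$replicate, m2$replicate)
  if (length(reps) < 2L) {
    stop("fewer than 2 complete replicate pairs: paired test undefined")
  }
  if (length(reps) < length(union(m1$replicate, m2$replicate))) {
    stop("unpaired samples: every replicate must be present in both classes")
  }
  s1 <- m1$sample_id[match(reps, m1$replicate)]
  s2 <- m2$sample_id[match(reps, m2$replicate)]

  d <- mat[, s2, drop = FALSE] - mat[, s1, drop = FALSE]
  m <- length(reps)
  df <- m - 1L
  mean_d <- rowMeans(d)
  s2g <- row_vars(d)

  if (is.null(prior_df)) {
    if (sum(is.finite(s2g) & s2g > 0) < 2L) {
      # degenerate (e.g. noise-free) data: no prior can be estimated
      df_prior <- 0
      var_post <- s2g
    } else {
      sq <- squeeze_variances(s2g, df)
      df_prior <- sq$df_prior
      var_post <- sq$var_post
    }
  } else {
    if (prior_df < 0) stop("'prior_df' must be >= 0")
    df_prior <- prior_df
    var_prior <- mean(s2g[s2g > 0])
    if (!is.finite(var_prior)) var_prior <- 0
    var_post <- if (df_prior == 0) s2g
                else posterior_variance(s2g, df, df_prior, var_prior)
  }
  # genes with zero variance everywhere: fall back to the pooled mean
  # variance so the statistic stays finite (0/0 -> t = 0, p = 1)
  zero <- var_post <= 0
  if (any(zero)) {
    pooled <- mean(s2g[s2g > 0])
    if (!is.finite(pooled) || pooled <= 0) pooled <- 1e-300
    var_post[zero] <- pooled
  }

  t_mod <- mean_d / sqrt(var_post / m)
  df_total <- df_prior + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  data.frame(
    gene = rownames(mat),
    pair = paste(pair, collapse = "-"),
    tissue = tissue,
    stage = stage,
    log2fc = mean_d,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    q = bh_fdr(p),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_i = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Union of differentially expressed genes across class pairs
#'
#' A gene is differentially expressed in a tissue-stage block if it passes
#' the FDR threshold in any of the class-pair comparisons.
#'
#' @param results list of data.frames from [moderated_paired_ttest()]
#'   (one per class pair).
#' @param alpha FDR threshold (default 0.05).
#' @return character vector of gene ids (sorted).
#' @export
degenes_union <- function(results, alpha = 0.05) {
  alpha <- assert_alpha(alpha, "alpha")
  genes <- unlist(lapply(results, function(r) r$gene[!is.na(r$q) & r$q < alpha]))
  sort(unique(genes))
}
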