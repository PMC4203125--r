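#' Classify V-to-PostV expression trends relative to veraison RS
#'
#' Per gene, tests the contrast (mean over all PostV samples) minus (mean of
#' veraison RS samples) with a pooled-variance two-sided t-test and BH FDR
#' within the tissue. Genes with a significant positive contrast are "up",
#' significant negative "down"; genes with no significant change have
#' plateaued (their synchronization completed early post-veraison).
#'
#' @param mat log2 expression matrix.
#' @param meta sample metadata.
#' @param tissue tissue label.
#' @param alpha FDR threshold (default 0.05).
#' @param rs_class reference class at veraison (default `"RS"`).
#' @param mode `"pooled"` (default: all PostV samples as one group) or
#'   `"per_class"` (each PostV class vs veraison RS; a gene is up/down if any
#'   class contrast is significant, with the sign of the largest significant
#'   contrast).
#' @return data.frame `gene, tissue, contrast_estimate, p, q, label`.
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 50))
#' table(trend_call(sim$matrix, sim$meta, "pulp")$label)
#' @export
trend_call <- function(mat, meta, tissue, alpha = 0.05, rs_class = "RS",
                       mode = c("pooled", "per_class")) {
  mode <- match.arg(mode)
  alpha <- assert_alpha(alpha, "alpha")
  ref <- select_samples(meta, tissue = tissue, stage = "V", class = rs_class)
  if (nrow(ref) == 0L) {
    stop(sprintf("no veraison '%s' samples in tissue '%s'", rs_class, tissue))
  }
  pv <- select_samples(meta, tissue = tissue, stage = "PostV")
  if (nrow(pv) == 0L) stop(sprintf("no PostV samples in tissue '%s'", tissue))

  groups <- if (mode == "pooled") {
    list(pv$sample_id)
  } else {
    split(pv$sample_id, pv$class)
  }

  est <- p <- matrix(NA_real_, nrow(mat), length(groups))
  for (j in seq_along(groups)) {
    tt <- pooled_t_rows(mat[, groups[[j]], drop = FALSE],
                        mat[, ref$sample_id, drop = FALSE])
    est[, j] <- tt$estimate
    p[, j] <- tt$p
  }

  if (mode == "pooled") {
    contrast <- est[, 1L]
    pval <- p[, 1L]
  } else {
    pick <- max.col(-p, ties.method = "first")
    idx <- cbind(seq_len(nrow(mat)), pick)
    contrast <- est[idx]
    pval <- p[idx] # smallest per-class p; BH below is then conservative-ish
  }
  q <- bh_fdr(pval)
  label <- ifelse(q < alpha & contrast > 0, "up",
                  ifelse(q < alpha & contrast < 0, "down", "plateau"))
  data.frame(
    gene = rownames(mat),
    tissue = tissue,
    contrast_estimate = contrast,
    p = pval,
    q = q,
    label = label,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Row-wise pooled-variance two-sample t-test
#' @noRd
pooled_t_rows <- function(x, y) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("need at least two samples per group")
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2)
  ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(estimate = m1 - m2, t = t, df = df, p = p)
}

#' Cross-tabulate expression trends against RV strata
#'
#' Proportions of up/down/plateau genes within the high-RV (fold above
#' `hi_threshold`) and low-RV (fold below `lo_threshold`) strata of the
#' shared gene universe.
#'
#' @param trends data.frame from [trend_call()].
#' @param rv data.frame from [rv_records()].
#' @param hi_threshold high-RV cut (default 20).
#' @param lo_threshold low-RV cut (default 10).
#' @return list with `proportions` (2 x 3 matrix, rows high/low), `counts`,
#'   and `empty_strata` (character vector naming any stratum with no genes,
#'   whose proportions are `NaN`).
#' @export
trend_by_rv_crosstab <- function(trends, rv, hi_threshold = 20,
                                 lo_threshold = 10) {
  shared <- intersect(trends$gene, rv$gene)
  if (length(shared) == 0L) stop("no shared genes between trends and RV records")
  tr <- trends$label[match(shared, trends$gene)]
  fold <- rv$rv_fold[match(shared, rv$gene)]
  labs <- c("up", "down", "plateau")
  strata <- list(
    high = tr[is.finite(fold) & fold > hi_threshold],
    low = tr[is.finite(fold) & fold < lo_threshold]
  )
  counts <- t(vapply(strata, function(s) {
    vapply(labs, function(l) sum(s == l), numeric(1L))
  }, numeric(3L)))
  props <- counts / rowSums(counts)
  empty <- rownames(counts)[rowSums(counts) == 0L]
  if (length(empty)) {
    warning("empty RV stratum: ", paste(empty, collapse = ", "),
            "; proportions undefined")
  }
  list(proportions = props, counts = counts, empty_strata = empty)
}
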