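#' Per-gene between-class variance of class-mean expression
#'
#' Sample variance (denominator k - 1) of the k class-mean log2 expressions
#' in one tissue at one stage. This targets the between-class spread; the
#' replicate stratum is averaged out first.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param meta sample metadata.
#' @param stage `"V"` or `"PostV"`.
#' @param tissue tissue label.
#' @param classes class labels (default: those present in the block, in
#'   metadata order).
#' @return named numeric vector, one variance per gene.
#' @export
between_class_variance <- function(mat, meta, stage, tissue, classes = NULL) {
  block <- select_samples(meta, tissue = tissue, stage = stage)
  classes <- classes %||% unique(block$class)
  if (length(classes) < 2L) stop("need at least two classes with samples")
  means <- class_stage_means(mat, meta, tissue, stage, classes)
  stats::setNames(row_vars(means), rownames(mat))
}

#' Reduction-in-variance (RV) fold
#'
#' Ratio of a gene's between-class variance at veraison to that at PostV;
#' large values indicate strong synchronization. A zero PostV variance with
#' positive veraison variance is reported as an infinite fold; 0/0 is
#' undefined (`NaN`). Both cases are flagged downstream rather than silently
#' averaged.
#'
#' @param var_v,var_postv non-negative variance vectors.
#' @return fold vector.
#' @examples
#' rv_score(4, 0.2) # 20
#' @export
rv_score <- function(var_v, var_postv) {
  if (any(var_v < 0, na.rm = TRUE) || any(var_postv < 0, na.rm = TRUE)) {
    stop("variances must be >= 0")
  }
  var_v / var_postv
}

#' Build the per-gene RV records for one tissue
#'
#' Combines [between_class_variance()] at both stages, [rv_score()] and
#' [rv_ftest()] into the per-gene record used by the reporting stages.
#'
#' @param mat,meta expression matrix and metadata.
#' @param tissue tissue label.
#' @param genes optional gene universe (default: all rows).
#' @param df1,df2 F-test degrees of freedom (default `k - 1` from the class
#'   count at each stage).
#' @param alpha FDR threshold for the significant set (default 0.2).
#' @return data.frame `gene, tissue, var_v, var_postv, rv_fold, f_stat, p, q,
#'   significant, flagged` (flagged = infinite or undefined fold).
#' @export
rv_records <- function(mat, meta, tissue, genes = NULL, df1 = NULL, df2 = NULL,
                       alpha = 0.2) {
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  classes_v <- unique(select_samples(meta, tissue = tissue, stage = "V")$class)
  classes_pv <- unique(select_samples(meta, tissue = tissue, stage = "PostV")$class)
  var_v <- between_class_variance(mat, meta, "V", tissue)
  var_postv <- between_class_variance(mat, meta, "PostV", tissue)
  fold <- rv_score(var_v, var_postv)
  ft <- rv_ftest(fold, df1 = df1 %||% (length(classes_v) - 1L),
                 df2 = df2 %||% (length(classes_pv) - 1L), alpha = alpha)
  data.frame(
    gene = rownames(mat),
    tissue = tissue,
    var_v = var_v,
    var_postv = var_postv,
    rv_fold = fold,
    f_stat = fold,
    p = ft$p,
    q = ft$q,
    significant = ft$significant,
    flagged = !is.finite(fold),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' One-sided F-test for reduction in variance
#'
#' The RV fold is itself the F statistic; under the null of equal
#' between-class variances at V and PostV, `fold ~ F(df1, df2)`. The test is
#' one-sided (variance reduction only): `p = P(F > fold)`. BH adjustment is
#' applied over the finite folds; infinite folds get p = 0 and undefined
#' (0/0) folds get `NA`, both flagged.
#'
#' @param rv_fold vector of RV folds (or a data.frame with an `rv_fold`
#'   column).
#' @param df1,df2 degrees of freedom (default 2 and 2: three classes at each
#'   stage).
#' @param alpha FDR threshold (default 0.2).
#' @return list with `p`, `q`, `significant` (logical), `alpha`.
#' @examples
#' rv_ftest(1)$p # 0.5 exactly: F(2,2) has median 1
#' @export
rv_ftest <- function(rv_fold, df1 = 2, df2 = 2, alpha = 0.2) {
  if (is.data.frame(rv_fold)) rv_fold <- rv_fold$rv_fold
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  alpha <- assert_alpha(alpha, "alpha")
  p <- ifelse(is.nan(rv_fold), NA_real_,
              stats::pf(rv_fold, df1, df2, lower.tail = FALSE))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  list(p = p, q = q, significant = !is.na(q) & q < alpha, alpha = alpha)
}

#' Distribution summary of RV folds
#'
#' Mean and quantiles over the finite folds, plus the fraction of genes in
#' the fold bins <=10, 10-20, >20 and <=100. Infinite and undefined folds are
#' counted separately, never averaged.
#'
#' @param rv data.frame with an `rv_fold` column (e.g. from [rv_records()]),
#'   or a numeric fold vector.
#' @return list with `n`, `n_infinite`, `n_undefined`, `mean_fold`,
#'   `median_fold`, `quantiles`, and `bins` (named fractions of the finite
#'   folds).
#' @export
rv_distribution_summary <- function(rv) {
  fold <- if (is.data.frame(rv)) rv$rv_fold else rv
  if (length(fold) == 0L) stop("no RV records")
  finite <- fold[is.finite(fold)]
  list(
    n = length(finite),
    n_infinite = sum(is.infinite(fold)),
    n_undefined = sum(is.nan(fold)),
    mean_fold = mean(finite),
    median_fold = stats::median(finite),
    quantiles = stats::quantile(finite, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    bins = c(
      le10 = mean(finite <= 10),
      `10to20` = mean(finite > 10 & finite <= 20),
      gt20 = mean(finite > 20),
      le100 = mean(finite <= 100)
    )
  )
}

#' Overlap fraction between the top-n genes of two rankings
#'
#' Compares two per-gene scores (e.g. RV fold vs plain between-class
#' variance) by the fraction of shared genes among their top `n`. Ties are
#' broken by gene id so the ranking is stable.
#'
#' @param score_a,score_b named numeric vectors over the same gene universe
#'   (larger = higher priority).
#' @param n top-list size.
#' @return overlap fraction in `[0, 1]`.
#' @examples
#' s <- c(a = 3, b = 2, c = 1)
#' rank_overlap(s, s, 2) # 1
#' @export
rank_overlap <- function(score_a, score_b, n) {
  if (is.null(names(score_a)) || is.null(names(score_b))) {
    stop("scores must be named by gene")
  }
  if (!setequal(names(score_a), names(score_b))) {
    stop("scores must cover the same gene universe")
  }
  n <- assert_count(n, "n")
  if (n > length(score_a)) stop("'n' exceeds the gene universe size")
  top <- function(s) {
    ord <- order(-s, names(s), method = "radix")
    names(s)[ord][seq_len(n)]
  }
  length(intersect(top(score_a), top(score_b))) / n
}
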