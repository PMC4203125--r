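#' Transcriptional distances between ripening stages
#'
#' Per gene, from class means over replicates on the log2 scale:
#' * `a = mean(PS) - mean(GS)` at veraison, `b = mean(RS) - mean(PS)` at
#'   veraison (the between-class gaps);
#' * `x_obs`, `y_obs`, `z` = V-to-PostV change within GS, PS, RS;
#' * `x_calc = a + b + z`, `y_calc = b + z` (the additive model: an
#'   under-ripe berry must first traverse the veraison gaps to the RS state,
#'   then the RS class's own V-to-PostV distance).
#'
#' The decomposition carries an exact identity:
#' `x_calc - x_obs = mean(RS at PostV) - mean(GS at PostV)` (and the y
#' analogue), so observed and calculated distances coincide exactly as the
#' PostV class means converge — the model's testable core.
#'
#' @param mat log2 expression matrix.
#' @param meta sample metadata.
#' @param tissue tissue label.
#' @param genes optional gene universe (e.g. the DGE union); default all
#'   rows.
#' @param classes ripening-ordered class labels (default GS, PS, RS).
#' @param scale `"log2"` (default) or `"fold"` (`2^distance` exports).
#' @return data.frame with `gene, tissue, a, b, x_obs, y_obs, z, x_calc,
#'   y_calc`.
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 20))
#' d <- compute_distances(sim$matrix, sim$meta, "pulp")
#' all.equal(d$x_calc, d$a + d$b + d$z)
#' @export
compute_distances <- function(mat, meta, tissue, genes = NULL,
                              classes = c("GS", "PS", "RS"),
                              scale = c("log2", "fold")) {
  scale <- match.arg(scale)
  if (length(classes) != 3L) stop("the distance model needs exactly 3 classes")
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  mv <- class_stage_means(mat, meta, tissue, "V", classes)
  mp <- class_stage_means(mat, meta, tissue, "PostV", classes)

  a <- mv[, 2L] - mv[, 1L]
  b <- mv[, 3L] - mv[, 2L]
  x_obs <- mp[, 1L] - mv[, 1L]
  y_obs <- mp[, 2L] - mv[, 2L]
  z <- mp[, 3L] - mv[, 3L]

  out <- data.frame(
    gene = rownames(mat),
    tissue = tissue,
    a = a,
    b = b,
    x_obs = x_obs,
    y_obs = y_obs,
    z = z,
    x_calc = a + b + z,
    y_calc = b + z,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (scale == "fold") {
    for (col in c("a", "b", "x_obs", "y_obs", "z", "x_calc", "y_calc")) {
      out[[col]] <- 2^out[[col]]
    }
  }
  out
}

#' Linearity of calculated vs observed transcriptional distances
#'
#' Ordinary least squares of the calculated distance on the observed distance
#' across genes. R^2 near 1 indicates that the additive distance model holds,
#' i.e. the PostV transcriptional states of the classes have converged.
#'
#' @param records data.frame from [compute_distances()] (log2 scale).
#' @param which `"X"` (GS distances, default) or `"Y"` (PS distances).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linearity <- function(records, which = c("X", "Y")) {
  which <- match.arg(which)
  obs <- if (which == "X") records$x_obs else records$y_obs
  calc <- if (which == "X") records$x_calc else records$y_calc
  if (length(obs) < 3L) stop("need at least 3 records")
  if (stats::var(obs) == 0) stop("degenerate observed distances (all equal)")
  fit <- stats::lm(calc ~ obs)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((calc - mean(calc))^2)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    n = length(obs)
  )
}
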