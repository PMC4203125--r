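#' Simulate a log2 expression matrix with PostV synchronization
#'
#' Generates genes x samples log2 intensities for the multi-class,
#' two-timepoint berry design, plus a ground-truth table for
#' parameter-recovery tests. Per gene and tissue:
#'
#' * veraison (V) class means are `mu`, `mu + a`, `mu + a + b` along the
#'   ripening order (GS, PS, RS), with gaps `a`, `b` drawn from
#'   `N(0, effect_sd_v^2)`;
#' * every class shares a common PostV target equal to the veraison RS mean
#'   shifted by `+trend_effect`, `-trend_effect` or 0 according to the gene's
#'   trend label (up/down/plateau, drawn from `trend_mix`);
#' * PostV class means scatter around the target with a synchronization
#'   residual whose scale is calibrated so the median realized
#'   variance-at-V / variance-at-PostV ratio across genes centres on the
#'   per-gene fold (`rv_fold_target`, optionally lognormal-spread); see the
#'   methods vignette for the 2-degree-of-freedom median calibration;
#' * replicate values add `N(0, residual_sd^2)` noise, paired by replicate
#'   (plant) id across classes and stages.
#'
#' With `exact_sync = TRUE` (or an infinite fold target) the PostV class
#' means are identical per gene.
#'
#' @param config a [sim_config()]; `n_replicates` must be >= 2 (paired tests
#'   are undefined otherwise).
#' @return a list with elements
#'   \describe{
#'     \item{matrix}{numeric matrix, genes x samples, log2 scale.}
#'     \item{meta}{sample metadata data.frame with columns
#'       `sample_id, class, tissue, stage, replicate`.}
#'     \item{truth}{per gene and tissue: true `a`, `b`, `z` (RS V-to-PostV
#'       change), trend label, per-gene fold and the PostV synchronization
#'       residual variance actually used.}
#'   }
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 50))
#' dim(sim$matrix)
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  if (config$n_replicates < 2L) {
    stop("'n_replicates' must be >= 2: paired tests are undefined with fewer")
  }
  set.seed(config$seed)

  G <- config$n_genes
  classes <- config$classes_expr
  K <- length(classes)
  m <- config$n_replicates
  genes <- sprintf("g%05d", seq_len(G))
  mean_noise_var <- config$residual_sd^2 / m
  exact <- config$exact_sync || is.infinite(config$rv_fold_target)

  mats <- list()
  metas <- list()
  truths <- list()

  for (tissue in config$tissues) {
    mu <- rnorm(G, config$baseline_mean, config$baseline_sd)
    gaps <- matrix(rnorm(G * (K - 1L), 0, config$effect_sd_v), G, K - 1L)
    offsets <- cbind(0, t(apply(gaps, 1L, cumsum)))
    v_means <- mu + offsets
    var_v_true <- row_vars(offsets)

    fold <- if (exact) {
      rep(Inf, G)
    } else if (config$rv_fold_spread > 0) {
      config$rv_fold_target * exp(rnorm(G, 0, config$rv_fold_spread))
    } else {
      rep(config$rv_fold_target, G)
    }

    trend <- draw_trends(G, config, fold)
    delta <- c(up = config$trend_effect, down = -config$trend_effect,
               plateau = 0)[trend]
    target <- v_means[, K] + delta

    if (exact) {
      sync_var <- rep(0, G)
      pv_means <- matrix(target, G, K)
    } else {
      # residual scale: the empirical between-class variance at V includes a
      # replicate-noise floor sigma^2/m, and the same floor bounds PostV from
      # below, so s^2 = (varV_true + sigma^2/m)/fold - sigma^2/m (>= 0)
      sync_var <- pmax(0, (var_v_true + mean_noise_var) / fold -
                         mean_noise_var)
      # residuals are centred and scaled so their realized sample variance
      # equals s^2 exactly: the 2-df sampling noise of a Gaussian draw would
      # otherwise dominate the realized variance ratio per gene
      e <- matrix(rnorm(G * K), G, K)
      e <- (e - rowMeans(e)) / sqrt(pmax(row_vars(e), 1e-300)) * sqrt(sync_var)
      pv_means <- target + e
    }

    blocks <- list(V = v_means, PostV = pv_means)
    for (stage in names(blocks)) {
      for (k in seq_len(K)) {
        for (r in seq_len(m)) {
          id <- paste(tissue, stage, classes[k], paste0("p", r), sep = "_")
          mats[[id]] <- blocks[[stage]][, k] +
            rnorm(G, 0, config$residual_sd)
          metas[[id]] <- data.frame(
            sample_id = id, class = classes[k], tissue = tissue,
            stage = stage, replicate = paste0("p", r),
            stringsAsFactors = FALSE
          )
        }
      }
    }

    truths[[tissue]] <- data.frame(
      gene = genes,
      tissue = tissue,
      a = if (K >= 2) gaps[, 1L] else NA_real_,
      b = if (K >= 3) gaps[, 2L] else NA_real_,
      z = pv_means[, K] - v_means[, K],
      trend = trend,
      fold = fold,
      sync_var = sync_var,
      stringsAsFactors = FALSE
    )
  }

  mat <- do.call(cbind, mats)
  rownames(mat) <- genes
  list(
    matrix = mat,
    meta = do.call(rbind, c(metas, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truths, list(make.row.names = FALSE)))
  )
}

#' Draw per-gene trend labels, optionally coupled to the RV fold
#' @noRd
draw_trends <- function(G, config, fold) {
  p <- matrix(config$trend_mix[c("up", "down", "plateau")], G, 3L,
              byrow = TRUE)
  if (config$trend_rv_coupling > 0) {
    hi <- is.finite(fold) & fold > config$rv_fold_target
    p[hi, 1L] <- p[hi, 1L] * (1 + config$trend_rv_coupling)
    p <- p / rowSums(p)
  }
  u <- runif(G)
  lab <- ifelse(u < p[, 1L], "up",
                ifelse(u < p[, 1L] + p[, 2L], "down", "plateau"))
  lab
}
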