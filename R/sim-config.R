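#' Configuration for the synthetic berry-ripening data generator
#'
#' Bundles every tunable of the simulator into a validated list. The defaults
#' emulate the study design the downstream statistics assume: three
#' transcriptome berry classes (GS, PS, RS) sampled in three tissues at
#' mid-veraison (V) and five weeks later (PostV) with three replicate plants,
#' and four physiology classes (GH, GS, PS, RS) followed weekly, with
#' under-ripe classes lagging the red-soft (RS) class by 13, 10 and 7 days
#' and converging on a common saturating trajectory.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration (including this seed).
#' @param n_genes number of genes to simulate.
#' @param classes_expr ordered ripening classes for the expression design,
#'   least to most ripe. The between-class veraison gaps are cumulative along
#'   this order.
#' @param classes_phys ripening classes for the physiology design.
#' @param tissues tissue labels; effects are drawn independently per tissue.
#' @param n_replicates replicate plants per class/stage/tissue block (the
#'   pairing unit for paired tests); must be >= 2.
#' @param class_lags_days named vector of per-class ripening lags in days
#'   relative to RS; the most-ripe class must have lag 0.
#' @param weeks sampling days post mid-veraison for physiology
#'   (default 0, 7, 14, 21, 35, 42 = weeks 0,1,2,3,5,6).
#' @param n_plants_phys,n_clusters plants and clusters per plant in the
#'   physiology design; one berry per class per cluster per week, so
#'   `n_plants_phys * n_clusters` berries per class per timepoint (30 by
#'   default).
#' @param brix_curve,colour_curve parameters of the common monotone
#'   saturating (logistic) trajectory: `list(start=, asym=, rate=)` with
#'   `0 < start < asym`, `rate > 0`; `start` is the RS value at day 0.
#' @param phys_noise_sd named per-measurement Gaussian noise SDs:
#'   `brix` (deg Brix), `colour` (colour-index units), `L`, `C`, `elasticity`.
#' @param baseline_mean,baseline_sd log2 baseline expression distribution.
#' @param effect_sd_v SD (log2) of the veraison between-class gaps a and b.
#' @param rv_fold_target target reduction-in-variance fold: the factor by
#'   which a gene's between-class variance shrinks from V to PostV
#'   (median-calibrated; see the methods vignette). `Inf` means exact
#'   synchronization.
#' @param rv_fold_spread SD of a lognormal spread on the per-gene fold
#'   (0 = every gene gets the target fold; the lognormal median stays at the
#'   target).
#' @param exact_sync if `TRUE`, PostV class means are identical per gene
#'   (equivalent to `rv_fold_target = Inf`).
#' @param trend_mix named proportions of up/down/plateau genes (must sum
#'   to 1).
#' @param trend_effect log2 shift of the common PostV target relative to the
#'   veraison RS mean for up/down genes.
#' @param trend_rv_coupling non-negative multiplier coupling "up" trends to
#'   genes whose fold exceeds the target (0 = no coupling).
#' @param residual_sd within-class replicate noise SD (log2).
#'
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 100)
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       classes_expr = c("GS", "PS", "RS"),
                       classes_phys = c("GH", "GS", "PS", "RS"),
                       tissues = c("pulp", "skin", "seed"),
                       n_replicates = 3L,
                       class_lags_days = c(GH = 13, GS = 10, PS = 7, RS = 0),
                       weeks = c(0, 7, 14, 21, 35, 42),
                       n_plants_phys = 6L,
                       n_clusters = 5L,
                       brix_curve = list(start = 12.6, asym = 24, rate = 0.0313),
                       colour_curve = list(start = 3.4, asym = 7, rate = 0.0833),
                       phys_noise_sd = c(brix = 0.25, colour = 0.1, L = 0.8,
                                         C = 0.3, elasticity = 0.03),
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       effect_sd_v = 1.0,
                       rv_fold_target = 24,
                       rv_fold_spread = 0,
                       exact_sync = FALSE,
                       trend_mix = c(up = 1 / 3, down = 1 / 3, plateau = 1 / 3),
                       trend_effect = 1.0,
                       trend_rv_coupling = 0,
                       residual_sd = 0.25) {
  cfg <- list(
    seed = assert_count(seed, "seed"),
    n_genes = assert_count(n_genes, "n_genes"),
    classes_expr = as.character(classes_expr),
    classes_phys = as.character(classes_phys),
    tissues = as.character(tissues),
    n_replicates = assert_count(n_replicates, "n_replicates"),
    class_lags_days = class_lags_days,
    weeks = sort(unique(as.numeric(weeks))),
    n_plants_phys = assert_count(n_plants_phys, "n_plants_phys"),
    n_clusters = assert_count(n_clusters, "n_clusters"),
    brix_curve = brix_curve,
    colour_curve = colour_curve,
    phys_noise_sd = phys_noise_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    effect_sd_v = effect_sd_v,
    rv_fold_target = rv_fold_target,
    rv_fold_spread = rv_fold_spread,
    exact_sync = isTRUE(exact_sync),
    trend_mix = trend_mix,
    trend_effect = trend_effect,
    trend_rv_coupling = trend_rv_coupling,
    residual_sd = residual_sd
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$classes_expr) < 2L) stop("need at least two expression classes")
  if (!(cfg$rv_fold_target > 0)) stop("'rv_fold_target' must be > 0")
  if (cfg$rv_fold_spread < 0) stop("'rv_fold_spread' must be >= 0")
  mix <- cfg$trend_mix
  if (!all(c("up", "down", "plateau") %in% names(mix))) {
    stop("'trend_mix' must have names up, down, plateau")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("'trend_mix' proportions must be non-negative and sum to 1")
  }
  missing_lag <- setdiff(cfg$classes_phys, names(cfg$class_lags_days))
  if (length(missing_lag)) {
    stop("missing 'class_lags_days' entries for: ",
         paste(missing_lag, collapse = ", "))
  }
  ripest <- cfg$classes_phys[length(cfg$classes_phys)]
  if (cfg$class_lags_days[[ripest]] != 0) {
    stop(sprintf("the reference class '%s' must have lag 0", ripest))
  }
  for (nm in c("brix_curve", "colour_curve")) validate_curve(cfg[[nm]], nm)
  noise_names <- c("brix", "colour", "L", "C", "elasticity")
  if (!all(noise_names %in% names(cfg$phys_noise_sd))) {
    stop("'phys_noise_sd' must have entries: ",
         paste(noise_names, collapse = ", "))
  }
  if (any(cfg$phys_noise_sd < 0) || cfg$residual_sd < 0 || cfg$effect_sd_v < 0) {
    stop("noise and effect standard deviations must be >= 0")
  }
  if (cfg$trend_rv_coupling < 0) stop("'trend_rv_coupling' must be >= 0")
  invisible(cfg)
}

validate_curve <- function(curve, name) {
  need <- c("start", "asym", "rate")
  if (!all(need %in% names(curve))) {
    stop(sprintf("'%s' must be list(start=, asym=, rate=)", name))
  }
  if (!(curve$start > 0 && curve$asym > curve$start && curve$rate > 0)) {
    stop(sprintf(
      "'%s' is not monotone increasing over the sampled range: need 0 < start < asym and rate > 0",
      name
    ))
  }
  invisible(curve)
}

#' Logistic saturating trajectory used by the physiology generator
#'
#' `f(u) = asym / (1 + ((asym - start)/start) * exp(-rate * u))`, so that
#' `f(0) = start` and `f(u) -> asym`. Strictly increasing for
#' `0 < start < asym`, `rate > 0`.
#'
#' @param u time in days (may be negative for lagged classes).
#' @param curve `list(start=, asym=, rate=)`.
#' @return trajectory values.
#' @export
logistic_curve <- function(u, curve) {
  validate_curve(curve, "curve")
  curve$asym / (1 + ((curve$asym - curve$start) / curve$start) *
                  exp(-curve$rate * u))
}
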