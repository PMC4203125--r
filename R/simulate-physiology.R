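#' Simulate a per-berry physiology table
#'
#' Generates weekly Brix, colorimeter (L, h, C) and elasticity measurements
#' for individual berries of each ripening class. Every class follows the
#' same saturating logistic trajectory, evaluated at `day - lag(class)`, so
#' under-ripe classes trace the identical curve shifted later in time and
#' converge toward the common asymptote. Hue angle `h` is emitted so that
#' [colour_index()] recovers the intended colour-index value exactly
#' (`h = CI * (L + C) / 180`); L and C are held near constants with small
#' noise, since only the composite index is analysed downstream.
#'
#' @param config a [sim_config()].
#' @return a data.frame with one row per berry per sampling day and columns
#'   `berry_id, plant, cluster, class, day, brix, L, h, C, elasticity`.
#'   Deterministic given the config (including its seed).
#' @examples
#' phys <- simulate_physiology(sim_config(seed = 1))
#' head(phys)
#' @export
simulate_physiology <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  grid <- expand.grid(
    cluster = seq_len(config$n_clusters),
    plant = seq_len(config$n_plants_phys),
    class = config$classes_phys,
    day = config$weeks,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  lag <- config$class_lags_days[grid$class]
  u <- grid$day - lag
  sd <- config$phys_noise_sd

  brix_true <- logistic_curve(u, config$brix_curve)
  ci_true <- logistic_curve(u, config$colour_curve)

  brix <- brix_true + rnorm(n, 0, sd[["brix"]])
  ci <- ci_true + rnorm(n, 0, sd[["colour"]])
  L <- 32 + rnorm(n, 0, sd[["L"]])
  C <- 5 + rnorm(n, 0, sd[["C"]])
  # berries soften with ripening progress; not analysed downstream
  elasticity <- 0.25 + 1.25 / (1 + exp(0.15 * u)) + rnorm(n, 0, sd[["elasticity"]])

  data.frame(
    berry_id = sprintf("%s_d%02d_p%d_c%d", grid$class, grid$day, grid$plant,
                       grid$cluster),
    plant = paste0("p", grid$plant),
    cluster = paste0("c", grid$cluster),
    class = grid$class,
    day = grid$day,
    brix = brix,
    L = L,
    h = ci * (L + C) / 180,
    C = C,
    elasticity = elasticity,
    stringsAsFactors = FALSE
  )
}
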