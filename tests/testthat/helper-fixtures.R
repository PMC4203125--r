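# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default-condition expression simulation, one tissue, 2000 genes
sim_default <- function() {
  get_fixture("sim_default", function() {
    simulate_expression(sim_config(seed = 1, n_genes = 2000, tissues = "pulp"))
  })
}

# null expression simulation: no veraison effects, no synchronization,
# all genes plateau
sim_null <- function() {
  get_fixture("sim_null", function() {
    simulate_expression(sim_config(
      seed = 7, n_genes = 2000, tissues = "pulp", effect_sd_v = 0,
      rv_fold_target = 1, trend_mix = c(up = 0, down = 0, plateau = 1)
    ))
  })
}

# default-condition physiology table
phys_default <- function() {
  get_fixture("phys_default", function() {
    simulate_physiology(sim_config(seed = 1))
  })
}

# a minimal physiology table with prescribed per-class trajectories
# values: function(day, class) -> brix; colour index held proportional
make_phys <- function(days, classes, brix_fn, n_plants = 2) {
  grid <- expand.grid(plant = seq_len(n_plants), class = classes, day = days,
                      stringsAsFactors = FALSE)
  brix <- mapply(brix_fn, grid$day, grid$class)
  ci <- brix / 3
  L <- rep(32, nrow(grid))
  C <- rep(5, nrow(grid))
  data.frame(
    berry_id = paste0("b", seq_len(nrow(grid))),
    plant = paste0("p", grid$plant),
    cluster = "c1",
    class = grid$class,
    day = grid$day,
    brix = brix,
    L = L,
    h = ci * (L + C) / 180,
    C = C,
    elasticity = 1,
    stringsAsFactors = FALSE
  )
}

poly_eval_test <- function(coefs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

# a toy expression matrix with exact class/stage means (one replicate each)
make_mean_matrix <- function(v_means, pv_means, classes = c("GS", "PS", "RS")) {
  G <- nrow(v_means)
  cols <- list()
  meta <- list()
  for (st in c("V", "PostV")) {
    mm <- if (st == "V") v_means else pv_means
    for (k in seq_along(classes)) {
      id <- paste("pulp", st, classes[k], "p1", sep = "_")
      cols[[id]] <- mm[, k]
      meta[[id]] <- data.frame(sample_id = id, class = classes[k],
                               tissue = "pulp", stage = st, replicate = "p1",
                               stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- sprintf("g%03d", seq_len(G))
  list(matrix = mat, meta = do.call(rbind, meta))
}
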