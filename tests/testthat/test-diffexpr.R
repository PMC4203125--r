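test_that("moderated paired t handles degenerate and limiting cases", {
  sim <- simulate_expression(sim_config(seed = 5, n_genes = 60,
                                        tissues = "pulp"))
  mat <- sim$matrix
  meta <- sim$meta
  # force one gene's GS and RS veraison samples to be identical
  gs <- meta$sample_id[meta$class == "GS" & meta$stage == "V"]
  rs <- meta$sample_id[meta$class == "RS" & meta$stage == "V"]
  mat[1, rs] <- mat[1, gs]
  res <- moderated_paired_ttest(mat, meta, c("GS", "RS"), "pulp", "V")
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)

  # prior df 0 reproduces the ordinary paired t exactly
  res0 <- moderated_paired_ttest(mat, meta, c("GS", "RS"), "pulp", "V",
                                 prior_df = 0)
  for (g in c(2, 10, 33)) {
    tt <- t.test(mat[g, rs], mat[g, gs], paired = TRUE)
    expect_equal(res0$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res0$p[g], tt$p.value, tolerance = 1e-12)
  }

  # swapping the pair flips signs, p unchanged
  rev <- moderated_paired_ttest(mat, meta, c("RS", "GS"), "pulp", "V")
  expect_equal(rev$log2fc, -res$log2fc)
  expect_equal(rev$p, res$p)
})

test_that("pairing requirements are enforced", {
  sim <- simulate_expression(sim_config(seed = 5, n_genes = 10,
                                        tissues = "pulp"))
  meta <- sim$meta
  broken <- meta[!(meta$class == "RS" & meta$replicate == "p1" &
                     meta$stage == "V"), ]
  expect_error(
    moderated_paired_ttest(sim$matrix, broken, c("GS", "RS"), "pulp", "V"),
    "unpaired"
  )
  one <- meta[meta$replicate == "p1" | meta$class != "RS", ]
  expect_error(
    moderated_paired_ttest(sim$matrix, one, c("GS", "RS"), "pulp", "V"),
    "fewer than 2"
  )
})

test_that("unmoderated p-values agree with the exhaustive sign-flip oracle", {
  set.seed(7)
  m <- 3
  d <- matrix(rnorm(30 * m), 30, m)
  tstat <- rowMeans(d) / sqrt(apply(d, 1, var) / m)
  p_t <- 2 * pt(-abs(tstat), m - 1)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  p_perm <- vapply(seq_len(nrow(d)), function(g) {
    ts <- apply(flips, 1, function(s) {
      x <- d[g, ] * s
      mean(x) / sqrt(var(x) / m)
    })
    mean(abs(ts) >= abs(tstat[g]) - 1e-12)
  }, numeric(1))
  # sign flips come in +/- pairs, so the oracle's granularity is 2/2^m
  expect_true(all(abs(p_t - p_perm) <= 2 / 2^m + 0.15))
  expect_gt(cor(p_t, p_perm, method = "spearman"), 0.9)
})

test_that("variance shrinkage matches the independent limma implementation", {
  skip_if_not_installed("limma")
  check_against_limma <- function(d) {
    s2 <- apply(d, 1, var)
    sq <- squeeze_variances(s2, ncol(d) - 1)
    fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1)))
    expect_equal(sq$df_prior, fit$df.prior, tolerance = 1e-6)
    expect_equal(sq$var_prior, fit$s2.prior, tolerance = 1e-8)
    expect_equal(unname(sq$var_post), unname(fit$s2.post), tolerance = 1e-8)
  }
  sim <- simulate_expression(sim_config(seed = 3, n_genes = 500,
                                        tissues = "pulp"))
  meta <- sim$meta
  gs <- meta$sample_id[meta$class == "GS" & meta$stage == "V"]
  rs <- meta$sample_id[meta$class == "RS" & meta$stage == "V"]
  check_against_limma(sim$matrix[, rs] - sim$matrix[, gs])
  # heterogeneous per-gene variances exercise the finite-prior branch
  set.seed(42)
  v <- 0.04 * rf(800, 6, 6)
  check_against_limma(matrix(rnorm(800 * 4, 0, sqrt(v)), 800, 4))
})

test_that("posterior variances are convex combinations of prior and sample", {
  sim <- sim_default()
  meta <- sim$meta
  gs <- meta$sample_id[meta$class == "GS" & meta$stage == "V"]
  ps <- meta$sample_id[meta$class == "PS" & meta$stage == "V"]
  s2 <- apply(sim$matrix[, ps] - sim$matrix[, gs], 1, var)
  sq <- squeeze_variances(s2, 2)
  lo <- pmin(s2, sq$var_prior)
  hi <- pmax(s2, sq$var_prior)
  expect_true(all(sq$var_post >= lo - 1e-12 & sq$var_post <= hi + 1e-12))
})

test_that("bh_fdr implements the step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.7, 0.04)
  # independent step-up definition: q_i = min over j >= i of p_(j) m / j
  o <- order(p)
  m <- length(p)
  q_oracle <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(o)]
  expect_equal(bh_fdr(p), pmin(q_oracle, 1))
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_true(all(bh_fdr(p) >= p))
})

test_that("the DE universe is the union over class pairs", {
  mk <- function(genes, q) data.frame(gene = genes, q = q,
                                      stringsAsFactors = FALSE)
  res <- list(
    mk(c("g1", "g2", "g3"), c(0.01, 0.5, 0.9)),
    mk(c("g1", "g2", "g3"), c(0.7, 0.02, 0.9)),
    mk(c("g1", "g2", "g3"), c(0.8, 0.9, 0.99))
  )
  expect_equal(degenes_union(res, 0.05), c("g1", "g2"))
  expect_equal(degenes_union(lapply(res, function(r) mk(r$gene, rep(1, 3))),
                             0.05), character(0))
  per_pair <- vapply(res, function(r) sum(r$q < 0.05), numeric(1))
  expect_gte(length(degenes_union(res, 0.05)), max(per_pair))
})
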