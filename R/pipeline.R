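#' Pipeline configuration
#'
#' Either a [sim_config()] (synthetic mode) or paths to an expression matrix
#' TSV, sample-metadata TSV and physiology CSV (input mode), plus the
#' per-stage thresholds.
#'
#' @param sim a [sim_config()] for synthetic mode, or `NULL` in input mode.
#' @param expression,metadata,physiology file paths for input mode (ignored
#'   when `sim` is given).
#' @param alpha_dge FDR threshold for differential expression (default 0.05).
#' @param alpha_rv FDR threshold for the RV F-test (default 0.2).
#' @param alpha_trend FDR threshold for trend calls (default 0.05).
#' @param rv_hi,rv_lo RV-fold bin edges for the trend crosstab (20 / 10).
#' @param top_n top-list size for the ranking comparison (default 100).
#' @param degree,fit_window,margin kinetics regression settings.
#' @param ci_formula colour-index interpretation (see [colour_index()]).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            expression = NULL, metadata = NULL,
                            physiology = NULL,
                            alpha_dge = 0.05, alpha_rv = 0.2,
                            alpha_trend = 0.05,
                            rv_hi = 20, rv_lo = 10, top_n = 100,
                            degree = 2, fit_window = c(0, 21), margin = 14,
                            ci_formula = "ratio") {
  for (nm in c("alpha_dge", "alpha_rv", "alpha_trend")) {
    assert_alpha(get(nm), nm)
  }
  if (is.null(sim)) {
    paths <- c(expression = expression, metadata = metadata,
               physiology = physiology)
    if (length(paths) != 3L) {
      stop("input mode needs 'expression', 'metadata' and 'physiology' paths")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(
      sim = sim, expression = expression, metadata = metadata,
      physiology = physiology,
      alpha_dge = alpha_dge, alpha_rv = alpha_rv, alpha_trend = alpha_trend,
      rv_hi = rv_hi, rv_lo = rv_lo, top_n = assert_count(top_n, "top_n"),
      degree = degree, fit_window = fit_window, margin = margin,
      ci_formula = ci_formula
    ),
    class = "pipeline_config"
  )
}

#' Run the full synchronization analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load) -> paired
#' differential expression -> reduction-in-variance -> transcriptional
#' distances -> trends -> physiology kinetics -> summary — writing each
#' stage's artifact under `outdir` (TSV/CSV; summary as JSON) and logging one
#' line per stage. Fully deterministic given the configuration seed; a stage
#' failure aborts with the failing stage named, retaining earlier outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress stage log lines.
#' @return (invisibly) the report bundle: a list with every stage's tables
#'   and the summary.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(seed = 1, n_genes = 200))
#' bundle <- run_pipeline(cfg, outdir = tempfile("ripesync"))
#' names(bundle)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("ripesync"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(outdir = outdir)
  log_line <- function(stage, t0) {
    if (!quiet) {
      message(sprintf("[ripesync] stage %-10s %6.2fs", stage,
                      as.numeric(proc.time()[3L]) - t0))
    }
  }
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(proc.time()[3L])
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_line(stage, t0)
    out
  }

  # -- stage 1: simulate or load ------------------------------------------
  inputs <- run_stage("simulate", function() {
    if (!is.null(config$sim)) {
      sim <- simulate_expression(config$sim)
      phys <- simulate_physiology(config$sim)
      write_expression_matrix(sim$matrix, file.path(outdir, "expression.tsv"))
      write_sample_metadata(sim$meta, file.path(outdir, "sample_meta.tsv"))
      write_physiology(phys, file.path(outdir, "physiology.csv"))
      write_stage_tsv(sim$truth, file.path(outdir, "truth.tsv"))
      list(mat = sim$matrix, meta = sim$meta, phys = phys, truth = sim$truth)
    } else {
      list(
        mat = read_expression_matrix(config$expression),
        meta = read_sample_metadata(config$metadata),
        phys = read_physiology(config$physiology),
        truth = NULL
      )
    }
  })
  mat <- inputs$mat
  meta <- inputs$meta
  tissues <- unique(meta$tissue)
  classes <- unique(meta$class)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)

  # -- stage 2: paired differential expression ----------------------------
  dge <- run_stage("dge", function() {
    res <- list()
    for (tissue in tissues) {
      for (stage in unique(meta$stage)) {
        tab <- do.call(rbind, lapply(pairs, function(pr) {
          moderated_paired_ttest(mat, meta, pr, tissue, stage)
        }))
        write_stage_tsv(tab, file.path(
          outdir, sprintf("dge_%s_%s.tsv", tissue, stage)))
        res[[paste(tissue, stage, sep = ".")]] <- tab
      }
    }
    res
  })
  de_universe <- lapply(stats::setNames(tissues, tissues), function(tissue) {
    tab <- dge[[paste(tissue, "V", sep = ".")]]
    degenes_union(split(tab, tab$pair), config$alpha_dge)
  })
  de_counts <- lapply(dge, function(tab) {
    vapply(split(tab, tab$pair), function(x) sum(x$q < config$alpha_dge),
           numeric(1L))
  })

  # -- stage 3: reduction in variance -------------------------------------
  rv <- run_stage("rv", function() {
    res <- list()
    for (tissue in tissues) {
      genes <- de_universe[[tissue]]
      if (length(genes) < 2L) genes <- rownames(mat)
      rec <- rv_records(mat, meta, tissue, genes = genes,
                        alpha = config$alpha_rv)
      write_stage_tsv(rec, file.path(outdir, sprintf("rv_%s.tsv", tissue)))
      res[[tissue]] <- rec
    }
    res
  })
  rv_summary <- lapply(rv, rv_distribution_summary)
  overlap <- lapply(rv, function(rec) {
    n <- min(config$top_n, nrow(rec))
    rank_overlap(stats::setNames(rec$rv_fold, rec$gene),
                 stats::setNames(rec$var_v, rec$gene), n)
  })

  # -- stage 4: transcriptional distances ---------------------------------
  distances <- run_stage("distances", function() {
    res <- list()
    for (tissue in tissues) {
      genes <- de_universe[[tissue]]
      if (length(genes) < 3L) genes <- rownames(mat)
      rec <- compute_distances(mat, meta, tissue, genes = genes,
                               classes = classes)
      write_stage_tsv(rec, file.path(outdir, sprintf("distances_%s.tsv", tissue)))
      res[[tissue]] <- rec
    }
    res
  })
  lin <- lapply(distances, function(rec) {
    list(X = linearity(rec, "X"), Y = linearity(rec, "Y"))
  })

  # -- stage 5: trends -----------------------------------------------------
  trends <- run_stage("trends", function() {
    res <- list()
    for (tissue in tissues) {
      tab <- trend_call(mat, meta, tissue, alpha = config$alpha_trend)
      write_stage_tsv(tab, file.path(outdir, sprintf("trends_%s.tsv", tissue)))
      res[[tissue]] <- tab
    }
    res
  })
  crosstab <- lapply(tissues, function(tissue) {
    tryCatch(
      suppressWarnings(trend_by_rv_crosstab(trends[[tissue]], rv[[tissue]],
                                            config$rv_hi, config$rv_lo)),
      error = function(e) NULL
    )
  })
  names(crosstab) <- tissues

  # -- stage 6: physiology kinetics ---------------------------------------
  kinetics <- run_stage("kinetics", function() {
    run_kinetics_stage(inputs$phys, config, outdir)
  })

  # -- stage 7: consolidated summary --------------------------------------
  summary <- run_stage("summary", function() {
    s <- list(
      de_counts = de_counts,
      de_universe_size = vapply(de_universe, length, numeric(1L)),
      rv = lapply(rv_summary, function(x) x[c("n", "n_infinite", "n_undefined",
                                              "mean_fold", "median_fold",
                                              "bins")]),
      rank_overlap_top_n = overlap,
      linearity_r2 = lapply(lin, function(l) {
        c(X = l$X$r_squared, Y = l$Y$r_squared)
      }),
      trend_proportions = lapply(trends, function(t) {
        as.list(prop.table(table(t$label)))
      }),
      lags = kinetics$lags,
      rates = kinetics$rate_comparison
    )
    jsonlite::write_json(s, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    s
  })

  bundle$inputs <- inputs
  bundle$dge <- dge
  bundle$de_universe <- de_universe
  bundle$rv <- rv
  bundle$rv_summary <- rv_summary
  bundle$distances <- distances
  bundle$linearity <- lin
  bundle$trends <- trends
  bundle$crosstab <- crosstab
  bundle$kinetics <- kinetics
  bundle$summary <- summary
  invisible(bundle)
}

#' Kinetics stage: references, fits, inversions, lags and rates
#' @noRd
run_kinetics_stage <- function(phys, config, outdir) {
  stages <- define_reference_stages(phys, ci_formula = config$ci_formula)
  write_stage_tsv(stages, file.path(outdir, "reference_stages.tsv"))
  classes <- unique(phys$class)
  rs_class <- "RS"
  ref_ids <- stages$id[stages$id %in% c("R1", "R2", "R3")]
  rs_days <- stats::setNames(stages$rs_day[match(ref_ids, stages$id)], ref_ids)

  day_rows <- list()
  fits <- list()
  for (cl in classes) {
    fit <- fit_ripening_curve(phys, cl, "brix", window = config$fit_window,
                              degree = config$degree,
                              ci_formula = config$ci_formula)
    fits[[cl]] <- fit
    for (id in ref_ids) {
      ref <- stages$brix_ref[stages$id == id]
      day_rows[[paste(cl, id)]] <- data.frame(
        class = cl, stage = id,
        day = days_to_reference(fit, ref, margin = config$margin),
        stringsAsFactors = FALSE
      )
    }
  }
  days <- do.call(rbind, c(day_rows, list(make.row.names = FALSE)))
  lags <- lag_table(days, rs_days)
  write_stage_tsv(lags, file.path(outdir, "lag_table.tsv"))
  rates <- accumulation_rates(stages, days, "brix")
  write_stage_tsv(rates, file.path(outdir, "rate_table.tsv"))

  # per-plant rates over the full R1 -> R3 span for the class comparison;
  # plants whose per-plant fit is non-monotone under noise are dropped
  plant_rates <- list()
  for (cl in classes) {
    for (pl in unique(phys$plant)) {
      rate <- tryCatch({
        fit <- fit_ripening_curve(phys, cl, "brix", window = config$fit_window,
                                  degree = config$degree,
                                  ci_formula = config$ci_formula, plant = pl)
        d1 <- days_to_reference(fit, stages$brix_ref[stages$id == "R1"],
                                margin = config$margin)
        d3 <- days_to_reference(fit, stages$brix_ref[stages$id == "R3"],
                                margin = config$margin)
        (stages$brix_ref[stages$id == "R3"] -
           stages$brix_ref[stages$id == "R1"]) / (d3 - d1)
      }, error = function(e) NA_real_)
      plant_rates[[paste(cl, pl)]] <- data.frame(
        class = cl, plant = pl, rate = rate, stringsAsFactors = FALSE
      )
    }
  }
  plant_rates <- do.call(rbind, c(plant_rates, list(make.row.names = FALSE)))
  plant_rates <- plant_rates[is.finite(plant_rates$rate), , drop = FALSE]
  write_stage_tsv(plant_rates, file.path(outdir, "plant_rates.tsv"))

  comparison <- tryCatch(compare_rates(plant_rates), error = function(e) NULL)
  list(
    reference_stages = stages,
    fits = fits,
    days = days,
    lags = lags,
    rates = rates,
    plant_rates = plant_rates,
    rate_comparison = if (is.null(comparison)) NULL else {
      list(means = as.list(comparison$means),
           anova_p = comparison$anova_p,
           letters = as.list(comparison$letters),
           degenerate = comparison$degenerate)
    }
  )
}
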