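#' Composite berry colour index from colorimeter readings
#'
#' The printed formula "180h/L+C" is ambiguous; the default interpretation is
#' `180 * h / (L + C)`. The alternative reading `180 * h / L + C` is
#' selectable. The synthetic generator is self-consistent under whichever
#' interpretation is configured.
#'
#' @param L lightness.
#' @param h hue angle (degrees).
#' @param C chroma.
#' @param formula `"ratio"` for `180 h / (L + C)` (default) or `"sum"` for
#'   `180 h / L + C`.
#' @return colour-index values.
#' @examples
#' colour_index(L = 40, h = 1, C = 5) # 4
#' @export
colour_index <- function(L, h, C, formula = c("ratio", "sum")) {
  formula <- match.arg(formula)
  if (formula == "ratio") {
    if (any(L + C <= 0)) stop("colour index undefined: L + C must be > 0")
    180 * h / (L + C)
  } else {
    if (any(L <= 0)) stop("colour index undefined: L must be > 0")
    180 * h / L + C
  }
}

#' Extract the response values used by the kinetics functions
#' @noRd
phys_response <- function(table, response, ci_formula = "ratio") {
  switch(response,
    brix = table$brix,
    colour_index = colour_index(table$L, table$h, table$C, ci_formula),
    stop(sprintf("unknown response '%s'", response))
  )
}

#' Per-day class means of a physiology response
#' @noRd
class_day_means <- function(table, class, response, ci_formula = "ratio",
                            plant = NULL) {
  sub <- table[table$class == class, , drop = FALSE]
  if (!is.null(plant)) sub <- sub[sub$plant == plant, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no rows for class '%s'", class))
  y <- phys_response(sub, response, ci_formula)
  means <- tapply(y, sub$day, mean)
  data.frame(day = as.numeric(names(means)), mean = as.numeric(means))
}

#' Fit a per-class ripening curve (polynomial of class-mean response vs day)
#'
#' Least-squares polynomial of the class-mean response against day over a
#' window of sampled days. Fits that are not strictly increasing on the
#' window are rejected: ripening responses (Brix, colour index) rise
#' monotonically over the observed period and the fit must be invertible for
#' time-to-reference estimation.
#'
#' @param table physiology data.frame (see [simulate_physiology()]).
#' @param class berry class label to fit.
#' @param response `"brix"` or `"colour_index"`.
#' @param window `c(day_min, day_max)`; defaults to `c(0, 21)`.
#' @param degree polynomial degree (default 2).
#' @param ci_formula passed to [colour_index()].
#' @param plant optional plant id to fit per-plant means (used for
#'   plant-level rate comparisons).
#' @return an object of class `kinetics_fit`: list with `class`, `response`,
#'   `coefficients` (increasing powers), `window`, `r_squared`, `n_points`.
#' @examples
#' phys <- simulate_physiology(sim_config(seed = 1))
#' fit <- fit_ripening_curve(phys, "RS", "brix")
#' fit$r_squared
#' @export
fit_ripening_curve <- function(table, class, response = c("brix", "colour_index"),
                               window = c(0, 21), degree = 2,
                               ci_formula = "ratio", plant = NULL) {
  response <- match.arg(response)
  degree <- assert_count(degree, "degree")
  means <- class_day_means(table, class, response, ci_formula, plant)
  means <- means[means$day >= window[1] & means$day <= window[2], , drop = FALSE]
  if (nrow(means) < degree + 2L) {
    stop(sprintf(
      "insufficient timepoints: degree %d needs >= %d distinct days in window, got %d",
      degree, degree + 2L, nrow(means)
    ))
  }
  fit <- stats::lm(mean ~ stats::poly(day, degree, raw = TRUE), data = means)
  coefs <- unname(stats::coef(fit))
  grid <- seq(window[1], window[2], length.out = 201L)
  if (any(poly_eval(poly_deriv(coefs), grid) <= 0)) {
    stop(sprintf(
      "fitted curve for class '%s' (%s) is not strictly increasing on [%g, %g]",
      class, response, window[1], window[2]
    ))
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((means$mean - mean(means$mean))^2)
  structure(
    list(
      class = class,
      response = response,
      coefficients = coefs,
      window = as.numeric(window),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
      n_points = nrow(means)
    ),
    class = "kinetics_fit"
  )
}

#' Evaluate a fitted ripening curve at given days
#'
#' @param object a `kinetics_fit`.
#' @param newdata days at which to evaluate (numeric vector).
#' @param ... unused.
#' @return fitted response values.
#' @export
predict.kinetics_fit <- function(object, newdata, ...) {
  poly_eval(object$coefficients, newdata)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "Ripening curve: class %s, %s, degree %d over [%g, %g] d (R^2 = %.3f, %d day means)\n",
    x$class, x$response, length(x$coefficients) - 1L,
    x$window[1], x$window[2], x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Define red-berry reference ripening stages from RS trajectories
#'
#' The Brix and colour-index values of the ripest (RS) class at fixed days
#' past mid-veraison (0, 7, 14, 21 d) define the reference stages R1-R4 on a
#' common physiological axis; under-ripe classes reach them later.
#'
#' @param table physiology data.frame.
#' @param rs_class label of the reference class (default `"RS"`).
#' @param days reference days (default `c(0, 7, 14, 21)`).
#' @param ci_formula passed to [colour_index()].
#' @return data.frame with columns `id` (R1..), `rs_day`, `brix_ref`,
#'   `ci_ref`; both reference series must be strictly increasing.
#' @examples
#' phys <- simulate_physiology(sim_config(seed = 1))
#' define_reference_stages(phys)
#' @export
define_reference_stages <- function(table, rs_class = "RS",
                                    days = c(0, 7, 14, 21),
                                    ci_formula = "ratio") {
  brix <- class_day_means(table, rs_class, "brix")
  ci <- class_day_means(table, rs_class, "colour_index", ci_formula)
  missing <- setdiff(days, brix$day)
  if (length(missing)) {
    stop(sprintf("class '%s' not sampled at day(s): %s", rs_class,
                 paste(missing, collapse = ", ")))
  }
  brix_ref <- brix$mean[match(days, brix$day)]
  ci_ref <- ci$mean[match(days, ci$day)]
  if (any(diff(brix_ref) <= 0) || any(diff(ci_ref) <= 0)) {
    stop("degenerate reference trajectory: reference values must be strictly increasing")
  }
  data.frame(
    id = paste0("R", seq_along(days)),
    rs_day = days,
    brix_ref = brix_ref,
    ci_ref = ci_ref,
    stringsAsFactors = FALSE
  )
}

#' Invert a fitted ripening curve: days to reach a reference value
#'
#' Finds the earliest day at which the fitted curve equals `ref_value`, by
#' monotone root bracketing to 1e-6 d. The search window is the fit window,
#' optionally extended above by `margin` days (extrapolation), truncated
#' where the extrapolated polynomial stops increasing.
#'
#' @param fit a `kinetics_fit`.
#' @param ref_value target response value.
#' @param margin days of permitted extrapolation beyond the window
#'   (default 14).
#' @return day (numeric scalar).
#' @examples
#' phys <- simulate_physiology(sim_config(seed = 1))
#' fit <- fit_ripening_curve(phys, "GS", "brix")
#' days_to_reference(fit, 12.6) # ~10 d: GS lags RS by 10 d
#' @export
days_to_reference <- function(fit, ref_value, margin = 14) {
  stopifnot(inherits(fit, "kinetics_fit"))
  lo <- fit$window[1]
  hi <- fit$window[2] + margin
  # truncate the extension where the polynomial turns over
  grid <- seq(fit$window[2], hi, by = 0.01)
  dgrid <- poly_eval(poly_deriv(fit$coefficients), grid)
  if (any(dgrid <= 0)) hi <- grid[which(dgrid <= 0)[1L]]
  f <- function(t) poly_eval(fit$coefficients, t) - ref_value
  if (f(lo) > 1e-12) {
    stop(sprintf(
      "reference %.4g lies below the fitted range: fitted(%g) = %.4g",
      ref_value, lo, poly_eval(fit$coefficients, lo)
    ))
  }
  if (f(lo) >= -1e-12) return(lo)
  if (f(hi) < 0) {
    stop(sprintf(
      "reference %.4g unreachable within window + margin (fitted(%g) = %.4g)",
      ref_value, hi, poly_eval(fit$coefficients, hi)
    ))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Lag table: days each class trails the reference class at each stage
#'
#' @param days data.frame with columns `class`, `stage`, `day` giving each
#'   class's estimated day of reaching each reference stage.
#' @param rs_days named vector mapping stage id to the reference (RS) day,
#'   e.g. `c(R1 = 0, R2 = 7, R3 = 14)`.
#' @return data.frame with `class, stage, day_to_reference, lag_vs_rs,
#'   rounded_lag` (half-up rounding to whole days).
#' @examples
#' d <- data.frame(class = c("PS", "GS", "GH"), stage = "R1",
#'                 day = c(6.5, 9.9, 13.0))
#' lag_table(d, c(R1 = 0))
#' @export
lag_table <- function(days, rs_days) {
  need <- c("class", "stage", "day")
  if (!all(need %in% names(days))) {
    stop("'days' must have columns class, stage, day")
  }
  missing <- setdiff(unique(days$stage), names(rs_days))
  if (length(missing)) {
    stop("missing reference day for stage(s): ", paste(missing, collapse = ", "))
  }
  lag <- days$day - rs_days[days$stage]
  data.frame(
    class = days$class,
    stage = days$stage,
    day_to_reference = days$day,
    lag_vs_rs = unname(lag),
    rounded_lag = unname(round_half_up(lag)),
    stringsAsFactors = FALSE
  )
}

#' Accumulation rates between consecutive reference stages
#'
#' Per class and consecutive stage pair, `rate = (ref_j - ref_i) /
#' (day_j - day_i)` in response units per day.
#'
#' @param stages reference-stage data.frame from [define_reference_stages()].
#' @param days data.frame with columns `class`, `stage`, `day` (days to reach
#'   each stage, per class); must be strictly increasing across stages within
#'   each class.
#' @param response `"brix"` or `"colour_index"` (selects `brix_ref` or
#'   `ci_ref`).
#' @return data.frame with `class, interval, rate`.
#' @examples
#' stages <- data.frame(id = c("R1", "R2"), rs_day = c(0, 7),
#'                      brix_ref = c(12.6, 13.9), ci_ref = c(3.4, 4.4))
#' days <- data.frame(class = "RS", stage = c("R1", "R2"), day = c(0, 7))
#' accumulation_rates(stages, days, "brix") # 1.3 / 7
#' @export
accumulation_rates <- function(stages, days, response = c("brix", "colour_index")) {
  response <- match.arg(response)
  ref <- if (response == "brix") stages$brix_ref else stages$ci_ref
  names(ref) <- stages$id
  out <- list()
  for (cl in unique(days$class)) {
    sub <- days[days$class == cl, , drop = FALSE]
    sub <- sub[match(stages$id[stages$id %in% sub$stage], sub$stage), , drop = FALSE]
    if (nrow(sub) < 2L) next
    if (any(diff(sub$day) <= 0)) {
      stop(sprintf("days to reference for class '%s' are not strictly increasing", cl))
    }
    i <- seq_len(nrow(sub) - 1L)
    out[[cl]] <- data.frame(
      class = cl,
      interval = paste(sub$stage[i], sub$stage[i + 1L], sep = "->"),
      rate = (ref[sub$stage[i + 1L]] - ref[sub$stage[i]]) / diff(sub$day),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Compare per-plant accumulation rates between classes
#'
#' One-way ANOVA on the class factor followed by Tukey's HSD at `alpha`,
#' summarised as a compact letter display: classes sharing no letter differ
#' significantly.
#'
#' @param rates data.frame with columns `class`, `plant`, `rate` (one rate
#'   per plant per class).
#' @param alpha significance level (default 0.05).
#' @return list with `means` (named class means), `anova_f`, `anova_p`,
#'   `tukey` (data.frame: pair, diff, p_adj), `letters` (named character),
#'   and `degenerate` (TRUE when within-group variance is zero while means
#'   differ, in which case p-values are unreliable and letters are assigned
#'   from distinct means).
#' @export
compare_rates <- function(rates, alpha = 0.05) {
  need <- c("class", "plant", "rate")
  if (!all(need %in% names(rates))) {
    stop("'rates' must have columns class, plant, rate")
  }
  alpha <- assert_alpha(alpha, "alpha")
  classes <- unique(rates$class)
  if (length(classes) < 2L) stop("need at least two classes")
  if (any(table(rates$class) < 2L)) stop("need at least two plants per class")
  rates$class <- factor(rates$class, levels = classes)

  group_means <- tapply(rates$rate, rates$class, mean)
  within_ss <- sum(tapply(rates$rate, rates$class,
                          function(x) sum((x - mean(x))^2)))
  degenerate <- within_ss < 1e-12 && stats::var(group_means) > 1e-12

  fit <- stats::aov(rate ~ class, data = rates)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$class
  tukey <- data.frame(
    pair = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  if (degenerate) {
    # zero residual variance: studentized range is undefined; distinct means
    # get distinct letters and p-values are flagged unreliable
    sig <- outer(group_means, group_means,
                 function(a, b) abs(a - b) > 1e-12)
  } else {
    sig <- matrix(FALSE, length(classes), length(classes),
                  dimnames = list(classes, classes))
    for (i in seq_len(nrow(tukey))) {
      pr <- strsplit(tukey$pair[i], "-", fixed = TRUE)[[1L]]
      s <- is.finite(tukey$p_adj[i]) && tukey$p_adj[i] < alpha
      sig[pr[1L], pr[2L]] <- s
      sig[pr[2L], pr[1L]] <- s
    }
  }

  list(
    means = group_means,
    anova_f = an[["F value"]][1L],
    anova_p = an[["Pr(>F)"]][1L],
    tukey = tukey,
    letters = compact_letters(sig, order(-group_means)),
    degenerate = degenerate
  )
}

#' Compact letter display from a logical "significantly different" matrix
#'
#' Assigns one letter per maximal clique of the complement (non-significance)
#' graph: every non-different pair shares a letter and every different pair
#' shares none. Group counts here are small (<= 8), so cliques are
#' enumerated by exhaustive subset search.
#' @noRd
compact_letters <- function(sig, ord = seq_len(nrow(sig))) {
  k <- nrow(sig)
  groups <- rownames(sig) %||% as.character(seq_len(k))
  if (k > 12L) stop("compact letter display supports up to 12 groups")
  adj <- !sig
  diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^k - 1L), function(bits) {
    which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0L)
  })
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1L))
  cliques <- subsets[is_clique]
  sizes <- lengths(cliques)
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > sizes[i] && all(cliques[[i]] %in% o)
    }, logical(1L)))
  }, logical(1L))
  cliques <- cliques[maximal]
  # order cliques by their best-ranked (e.g. largest-mean) member
  rank_of <- order(ord)
  cliques <- cliques[order(vapply(cliques, function(s) min(rank_of[s]), numeric(1L)))]
  out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' Ratio of analyte levels between classes at equivalent ripening stages
#'
#' Element-wise GS/RS ratio of levels measured at the same reference stages
#' (e.g. hormone concentrations at R1-R3).
#'
#' @param values_gs,values_rs numeric vectors of equal length;
#'   `values_rs` must be strictly positive.
#' @return named ratio vector.
#' @examples
#' equivalent_stage_ratio(c(R1 = 0.7), c(R1 = 1)) # 0.7, i.e. 30% lower
#' @export
equivalent_stage_ratio <- function(values_gs, values_rs) {
  if (length(values_gs) != length(values_rs)) {
    stop("'values_gs' and 'values_rs' must have the same length")
  }
  if (any(values_rs <= 0)) stop("denominator values must be > 0")
  values_gs / values_rs
}

#' Between-class spread of a physiology response at one day
#'
#' Max minus min of the class means at the given day; the headline
#' convergence summary (e.g. Brix spread shrinking from veraison to
#' maturity).
#'
#' @param table physiology data.frame.
#' @param day sampling day.
#' @param response `"brix"` or `"colour_index"`.
#' @param ci_formula passed to [colour_index()].
#' @return numeric scalar.
#' @export
between_class_spread <- function(table, day, response = c("brix", "colour_index"),
                                 ci_formula = "ratio") {
  response <- match.arg(response)
  sub <- table[table$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no measurements at day %g", day))
  if (length(unique(sub$class)) < 2L) {
    stop(sprintf("need at least two classes at day %g", day))
  }
  y <- phys_response(sub, response, ci_formula)
  means <- tapply(y, sub$class, mean)
  max(means) - min(means)
}
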