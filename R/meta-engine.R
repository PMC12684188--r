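#' Meta-analysis method configuration
#'
#' A fully resolved set of methods under which a meta-analysis is (re)run:
#' the model, the pooling method, the between-study variance estimator, the
#' interval method, the continuity rule for sparse binary data, and the
#' confidence level. [resolve_methods()] builds one of these from partially
#' reported details; here every field must be concrete.
#'
#' @param model `"fixed"` or `"random"`.
#' @param pooling `"inverse_variance"` or `"mantel_haenszel"`.
#'   Mantel-Haenszel is a fixed-effect method for binary 2x2 data only.
#' @param tau2_estimator `"DL"`, `"REML"`, `"PM"`, or `"none"` (fixed effect).
#' @param ci_method `"wald_z"` or `"hartung_knapp"`.
#' @param continuity Continuity rule for zero cells: `"add_half"` or `"none"`.
#' @param level Confidence level.
#' @return An object of class `meta_config`.
#' @export
meta_config <- function(model = c("random", "fixed"),
                        pooling = c("inverse_variance", "mantel_haenszel"),
                        tau2_estimator = c("REML", "DL", "PM", "none"),
                        ci_method = c("wald_z", "hartung_knapp"),
                        continuity = c("add_half", "none"),
                        level = 0.95) {
  model <- match.arg(model)
  pooling <- match.arg(pooling)
  tau2_estimator <- match.arg(tau2_estimator)
  ci_method <- match.arg(ci_method)
  continuity <- match.arg(continuity)
  stopifnot(level > 0, level < 1)
  if (pooling == "mantel_haenszel" && model != "fixed")
    stop("inconsistent methods: Mantel-Haenszel pooling is a fixed-effect method",
         call. = FALSE)
  if (model == "fixed") tau2_estimator <- "none"
  if (model == "random" && tau2_estimator == "none")
    stop("inconsistent methods: random-effects model requires a tau2 estimator",
         call. = FALSE)
  structure(list(model = model, pooling = pooling,
                 tau2_estimator = tau2_estimator, ci_method = ci_method,
                 continuity = continuity, level = level),
            class = "meta_config")
}

#' @export
print.meta_config <- function(x, ...) {
  cat(sprintf("<meta_config> %s / %s, tau2 = %s, CI = %s, continuity = %s, level = %g\n",
              x$model, x$pooling, x$tau2_estimator, x$ci_method, x$continuity,
              x$level))
  invisible(x)
}

## Cochran's Q about the fixed-effect weighted mean.
.q_statistic <- function(yi, vi) {
  wi <- 1 / vi
  yw <- sum(wi * yi) / sum(wi)
  sum(wi * (yi - yw)^2)
}

## Restricted log-likelihood of tau2 (constants dropped).
.reml_ll <- function(tau2, yi, vi) {
  wi <- 1 / (vi + tau2)
  mu <- sum(wi * yi) / sum(wi)
  -0.5 * (sum(log(vi + tau2)) + log(sum(wi)) + sum(wi * (yi - mu)^2))
}

#' Between-study variance estimators
#'
#' Estimates the heterogeneity variance tau^2 from study-level effects and
#' within-study variances, by DerSimonian-Laird (method-of-moments on
#' Cochran's Q), restricted maximum likelihood, or Paule-Mandel (root of the
#' generalised-Q estimating equation). All estimates are truncated at zero.
#'
#' REML maximisation uses Fisher scoring (tolerance 1e-10, at most 100
#' iterations) with a bracketed grid + golden-section fallback if the
#' iteration leaves the feasible range or fails to converge.
#'
#' @param yi,vi Numeric vectors of effects and within-study variances
#'   (`vi > 0`, at least two studies).
#' @param estimator `"DL"`, `"REML"`, or `"PM"`.
#' @return A list with `tau2`, `Q` (about the fixed-effect mean), and `df`.
#' @examples
#' estimate_tau2(c(0.1, 0.5), c(0.04, 0.04), "DL")  # tau2 = 0.04
#' @export
estimate_tau2 <- function(yi, vi, estimator = c("DL", "REML", "PM")) {
  estimator <- match.arg(estimator)
  k <- length(yi)
  if (k < 2)
    stop("insufficient studies for heterogeneity estimation (k < 2)",
         call. = FALSE)
  stopifnot(length(vi) == k, all(vi > 0))
  wi <- 1 / vi
  Q <- .q_statistic(yi, vi)
  df <- k - 1

  tau2 <- switch(estimator,
    DL = {
      C <- sum(wi) - sum(wi^2) / sum(wi)
      max(0, (Q - df) / C)
    },
    PM = {
      f <- function(t) {
        w <- 1 / (vi + t)
        mu <- sum(w * yi) / sum(w)
        sum(w * (yi - mu)^2) - df
      }
      if (f(0) <= 0) 0 else {
        upper <- max(vi)
        while (f(upper) > 0) upper <- upper * 2
        stats::uniroot(f, c(0, upper), tol = 1e-12)$root
      }
    },
    REML = .reml_tau2(yi, vi)
  )
  list(tau2 = tau2, Q = Q, df = df)
}

## Fisher scoring for REML tau2; falls back to grid + golden section.
.reml_tau2 <- function(yi, vi, tol = 1e-10, maxit = 100) {
  t2 <- max(0, stats::var(yi) - mean(vi))  # moment start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- 1 / (vi + t2)
    sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
    mu <- sum(w * yi) / sw
    r2 <- (yi - mu)^2
    score <- -0.5 * (sw - sw2 / sw - sum(w^2 * r2))
    info <- 0.5 * (sw2 - 2 * sw3 / sw + (sw2 / sw)^2)
    if (!is.finite(score) || !is.finite(info) || info <= 0) break
    step <- score / info
    t2_new <- t2 + step
    if (t2_new < 0) t2_new <- 0
    if (abs(t2_new - t2) < tol) { t2 <- t2_new; converged <- TRUE; break }
    t2 <- t2_new
  }
  if (converged && .reml_ll(t2, yi, vi) >= .reml_ll(0, yi, vi)) return(t2)
  ## fallback: coarse grid to bracket, then golden-section refinement
  upper <- max(stats::var(yi) * 10, max(vi) * 10, 1e-6)
  grid <- seq(0, upper, length.out = 201)
  ll <- vapply(grid, .reml_ll, numeric(1), yi = yi, vi = vi)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(.reml_ll, c(lo, hi), yi = yi, vi = vi,
                         maximum = TRUE, tol = 1e-12)
  t2 <- max(0, opt$maximum)
  if (.reml_ll(0, yi, vi) >= opt$objective) 0 else t2
}

#' Heterogeneity summaries from Q
#'
#' `I2 = max(0, (Q - df)/Q) * 100` and `H2 = Q/df`. Undefined (returned as
#' `NA`) when `df = 0`.
#'
#' @param Q Cochran's Q statistic.
#' @param df Its degrees of freedom (`k - 1`).
#' @return List with `i2` (percent) and `h2`.
#' @export
heterogeneity_stats <- function(Q, df) {
  if (df < 1) return(list(i2 = NA_real_, h2 = NA_real_))
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(i2 = i2, h2 = Q / df)
}

new_meta_result <- function(k, measure, y, se, ci_low, ci_high, p, Q, df,
                            tau2, weights, config, notes = character()) {
  het <- heterogeneity_stats(Q, df)
  structure(
    list(k = k, measure = measure, y_pooled = y, se_pooled = se,
         ci_low = ci_low, ci_high = ci_high, p_value = p,
         Q = Q, df = df, tau2 = tau2, i2 = het$i2, h2 = het$h2,
         weights = weights / sum(weights), config = config, notes = notes),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  ratio <- is_ratio_measure(x$measure)
  cat(sprintf("<meta_result> %s, k = %d (%s/%s)\n", x$measure, x$k,
              x$config$model, x$config$pooling))
  cat(sprintf("  pooled: %.4f [%.4f, %.4f], p = %.4g\n",
              x$y_pooled, x$ci_low, x$ci_high, x$p_value))
  if (ratio)
    cat(sprintf("  ratio scale: %.4f [%.4f, %.4f]\n",
                exp(x$y_pooled), exp(x$ci_low), exp(x$ci_high)))
  cat(sprintf("  Q = %.3f (df = %d), tau2 = %.4g, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$i2))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Inverse-variance pooling
#'
#' Pools study-level effects with weights `1/(vi + tau2)` (tau2 = 0 under a
#' fixed-effect model). The Wald interval uses the exact normal quantile;
#' the Hartung-Knapp method replaces the Wald variance with the
#' weighted residual variance `sum(wi (yi - y)^2) / ((k-1) sum(wi))` and a
#' t interval on `k - 1` degrees of freedom. P values are two-sided. A
#' single-study "meta-analysis" under a random-effects model falls back to
#' fixed effect, with a note recorded on the result.
#'
#' @param yi,vi Effects and variances on the analysis scale.
#' @param config A [meta_config()]; `pooling` must be `"inverse_variance"`.
#' @param measure Effect measure label carried on the result.
#' @return A `meta_result`.
#' @examples
#' pool_inverse_variance(c(0.1, 0.5), c(0.04, 0.04),
#'                       meta_config("random", tau2_estimator = "DL"))
#' @export
pool_inverse_variance <- function(yi, vi, config = meta_config(),
                                  measure = "MD") {
  k <- length(yi)
  if (k == 0) stop("no estimable studies to pool", call. = FALSE)
  stopifnot(length(vi) == k, all(vi > 0))
  notes <- character()

  model <- config$model
  if (model == "random" && k == 1) {
    model <- "fixed"
    notes <- c(notes, "single study: random-effects model fell back to fixed effect")
  }

  if (k >= 2) {
    Q <- .q_statistic(yi, vi)
    df <- k - 1L
  } else {
    Q <- 0; df <- 0L
  }
  tau2 <- 0
  if (model == "random")
    tau2 <- estimate_tau2(yi, vi, config$tau2_estimator)$tau2

  wi <- 1 / (vi + tau2)
  y <- sum(wi * yi) / sum(wi)
  se <- sqrt(1 / sum(wi))
  level <- config$level

  if (config$ci_method == "hartung_knapp" && k >= 2) {
    se_hk <- sqrt(sum(wi * (yi - y)^2) / ((k - 1) * sum(wi)))
    tcrit <- stats::qt(1 - (1 - level) / 2, df = k - 1)
    ci_low <- y - tcrit * se_hk
    ci_high <- y + tcrit * se_hk
    p <- 2 * stats::pt(abs(y) / se_hk, df = k - 1, lower.tail = FALSE)
    se_out <- se_hk
  } else {
    if (config$ci_method == "hartung_knapp")
      notes <- c(notes, "Hartung-Knapp needs k >= 2: Wald interval used")
    z <- .z(level)
    ci_low <- y - z * se
    ci_high <- y + z * se
    p <- 2 * stats::pnorm(abs(y) / se, lower.tail = FALSE)
    se_out <- se
  }

  cfg <- config; cfg$model <- model
  if (model == "fixed") cfg$tau2_estimator <- "none"
  new_meta_result(k, measure, y, se_out, ci_low, ci_high, p, Q, df, tau2,
                  wi, cfg, notes)
}

#' Mantel-Haenszel pooling of 2x2 tables
#'
#' Fixed-effect stratified pooling for binary data, robust to sparse cells:
#' no continuity correction is applied inside the Mantel-Haenszel estimator.
#' The variance of the log pooled odds ratio uses the
#' Robins-Breslow-Greenland formula; the log pooled risk ratio uses the
#' Greenland-Robins formula. Strata with zero events in both arms contribute
#' nothing and are dropped with a note. Heterogeneity (Q, I^2) is reported
#' from the per-study inverse-variance effects of the estimable strata,
#' continuity-corrected where needed for that purpose only.
#'
#' @param tables Data frame with columns `e1`, `n1`, `e2`, `n2`, one row per
#'   stratum (study).
#' @param measure `"logOR"` or `"logRR"`.
#' @param level Confidence level.
#' @return A `meta_result` on the log scale.
#' @examples
#' pool_mantel_haenszel(data.frame(e1 = 10, n1 = 100, e2 = 5, n2 = 100), "logOR")
#' @export
pool_mantel_haenszel <- function(tables, measure = c("logOR", "logRR"),
                                 level = 0.95) {
  measure <- match.arg(measure)
  stopifnot(all(c("e1", "n1", "e2", "n2") %in% names(tables)))
  notes <- character()

  keep <- (tables$e1 + tables$e2) > 0 &
    !(tables$e1 == tables$n1 & tables$e2 == tables$n2)
  if (!all(keep))
    notes <- c(notes, sprintf("%d non-estimable strata excluded", sum(!keep)))
  tab <- tables[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("all strata non-estimable", call. = FALSE)

  a <- tab$e1; b <- tab$n1 - tab$e1
  c <- tab$e2; d <- tab$n2 - tab$e2
  n1 <- tab$n1; n2 <- tab$n2; N <- n1 + n2

  if (measure == "logOR") {
    R <- a * d / N; S <- b * c / N
    P <- (a + d) / N; Qq <- (b + c) / N
    y <- log(sum(R) / sum(S))
    v <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Qq * R) / (2 * sum(R) * sum(S)) +
      sum(Qq * S) / (2 * sum(S)^2)
  } else {
    R <- a * n2 / N; S <- c * n1 / N
    y <- log(sum(R) / sum(S))
    v <- sum((n1 * n2 * (a + c) - a * c * N) / N^2) / (sum(R) * sum(S))
  }
  se <- sqrt(v)
  z <- .z(level)
  p <- 2 * stats::pnorm(abs(y) / se, lower.tail = FALSE)

  ## Q from per-study IV effects, for the heterogeneity report only.
  effs <- lapply(seq_len(nrow(tab)), function(i)
    effect_binary(tab$e1[i], tab$n1[i], tab$e2[i], tab$n2[i], measure))
  est <- vapply(effs, is_estimable, logical(1))
  if (sum(est) >= 2) {
    yi <- vapply(effs[est], `[[`, numeric(1), "y")
    vi <- vapply(effs[est], `[[`, numeric(1), "v")
    Q <- .q_statistic(yi, vi); df <- as.integer(sum(est) - 1)
  } else {
    Q <- 0; df <- 0L
  }

  cfg <- meta_config(model = "fixed", pooling = "mantel_haenszel",
                     tau2_estimator = "none", level = level)
  new_meta_result(nrow(tab), measure, y, se, y - z * se, y + z * se, p,
                  Q, df, 0, rep(1, nrow(tab)), cfg, notes)
}

#' Run a meta-analysis under a resolved configuration
#'
#' Dispatches a review's study table to the configured pooling route:
#' Mantel-Haenszel works from the 2x2 tables directly; inverse variance
#' first computes per-study effects via [compute_study_effects()] and pools
#' the estimable ones. Excluded studies are recorded in the result notes.
#'
#' @param studies Study table for one review (studies-CSV layout).
#' @param measure Effect measure of the review.
#' @param config A [meta_config()].
#' @return A `meta_result`.
#' @export
run_meta_analysis <- function(studies, measure, config = meta_config()) {
  measure <- match.arg(measure, .measures)
  if (config$pooling == "mantel_haenszel") {
    if (!measure %in% c("logOR", "logRR"))
      stop("inconsistent methods: Mantel-Haenszel requires a binary ratio measure",
           call. = FALSE)
    if (any(is.na(studies$e1)))
      stop("Mantel-Haenszel requires summary statistics (2x2 tables), ",
           "which are unavailable for at least one study", call. = FALSE)
    return(pool_mantel_haenszel(studies, measure, level = config$level))
  }
  eff <- compute_study_effects(studies, measure,
                               correction = config$continuity)
  excl <- !eff$estimable
  res <- pool_inverse_variance(eff$yi[!excl], eff$vi[!excl], config, measure)
  if (any(excl))
    res$notes <- c(res$notes,
                   sprintf("excluded %s: %s",
                           eff$study_id[excl], eff$reason[excl]))
  res
}
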