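## Run code under a local RNG state so corpus generation is reproducible
## without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-review seed from a master seed
#'
#' One RNG stream per review, derived from (master seed, review index), so a
#' corpus is reproducible regardless of generation order or parallelism.
#'
#' @param master_seed Integer master seed.
#' @param index Review index (1-based).
#' @return An integer seed.
#' @export
seed_for_review <- function(master_seed, index) {
  s <- (as.numeric(master_seed) + index * 1000003) %% 2147483629
  as.integer(max(1, s))
}

#' Configuration of one synthetic review
#'
#' Describes the "true" review the generator emulates: how many studies its
#' index meta-analysis has, the effect measure, the true pooled effect and
#' between-study variance, per-study sample sizes, the outcome model, the
#' methods the original authors "really" used, and which
#' information-loss profile the published report suffers from.
#'
#' When `k_studies` is `NULL` the study count is drawn from a log-normal
#' distribution with median 6 rounded and truncated to `[2, 30]`, matching
#' the typical size of an index meta-analysis in published intervention
#' reviews (median 6, interquartile range about 4 to 11).
#'
#' @param seed Integer seed for this review's RNG stream.
#' @param measure Effect measure.
#' @param k_studies Number of studies, or `NULL` to draw one.
#' @param true_effect True pooled effect on the analysis scale.
#' @param tau2_true True between-study variance (>= 0).
#' @param n_range Per-arm sample-size range (uniform integer draw).
#' @param baseline_risk Control-arm event risk for binary outcomes.
#' @param outcome_sd Outcome standard deviation for continuous outcomes.
#' @param method_config True analysis methods (a [meta_config()]).
#' @param info_loss Character vector of information-loss profiles applied to
#'   the published report, from `"none"`, `"estimates_only"`,
#'   `"no_methods"`, `"rounded_2dp"`, `"missing_all"`, `"typo_injection"`.
#'   Profiles compose (e.g. `c("estimates_only", "rounded_2dp")`).
#' @param report_p Whether the report prints a P value for the summary
#'   effect (just over half of published reviews do).
#' @param author_involved Label carried through to grouped tabulations.
#' @return An object of class `review_sim_config`.
#' @export
review_sim_config <- function(seed, measure = "SMD", k_studies = NULL,
                              true_effect = 0.3, tau2_true = 0.04,
                              n_range = c(20, 200), baseline_risk = 0.2,
                              outcome_sd = 1,
                              method_config = meta_config(tau2_estimator = "DL"),
                              info_loss = "none", report_p = TRUE,
                              author_involved = FALSE) {
  measure <- match.arg(measure, .measures)
  stopifnot(tau2_true >= 0, n_range[1] >= 2, n_range[2] >= n_range[1],
            baseline_risk > 0, baseline_risk < 1, outcome_sd > 0)
  ok <- c("none", "estimates_only", "no_methods", "rounded_2dp",
          "missing_all", "typo_injection")
  bad <- setdiff(info_loss, ok)
  if (length(bad)) stop("unknown info-loss profile: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(k_studies)) stopifnot(k_studies >= 1)
  structure(list(seed = as.integer(seed), measure = measure,
                 k_studies = k_studies, true_effect = true_effect,
                 tau2_true = tau2_true, n_range = n_range,
                 baseline_risk = baseline_risk, outcome_sd = outcome_sd,
                 method_config = method_config, info_loss = info_loss,
                 report_p = report_p, author_involved = author_involved),
            class = "review_sim_config")
}

.draw_k <- function() {
  k <- round(exp(stats::rnorm(1, log(6), 0.75)))
  min(30, max(2, k))
}

## Arm-level data for one review; returns a studies data.frame in the
## studies-CSV column layout.
.simulate_studies <- function(config, review_id) {
  k <- if (is.null(config$k_studies)) .draw_k() else config$k_studies
  theta <- config$true_effect +
    stats::rnorm(k, 0, sqrt(config$tau2_true))
  n1 <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
  n2 <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)

  empty <- rep(NA_real_, k)
  df <- data.frame(review_id = review_id,
                   study_id = sprintf("%s_s%02d", review_id, seq_len(k)),
                   measure = config$measure,
                   e1 = empty, n1 = empty, e2 = empty, n2 = empty,
                   m1 = empty, sd1 = empty, m2 = empty, sd2 = empty,
                   yi = empty, ci_low = empty, ci_high = empty,
                   prepost_r = empty, stringsAsFactors = FALSE)

  if (config$measure %in% c("logOR", "logRR")) {
    p2 <- rep(config$baseline_risk, k)
    p1 <- if (config$measure == "logOR") {
      odds <- p2 / (1 - p2) * exp(theta)
      odds / (1 + odds)
    } else {
      pmin(0.99, p2 * exp(theta))
    }
    df$e1 <- stats::rbinom(k, n1, p1)
    df$e2 <- stats::rbinom(k, n2, p2)
    df$n1 <- n1; df$n2 <- n2
  } else if (config$measure %in% c("MD", "SMD")) {
    sdv <- config$outcome_sd
    mu1 <- if (config$measure == "SMD") theta * sdv else theta
    df$m1 <- stats::rnorm(k, mu1, sdv / sqrt(n1))
    df$m2 <- stats::rnorm(k, 0, sdv / sqrt(n2))
    df$sd1 <- sdv * sqrt(stats::rchisq(k, n1 - 1) / (n1 - 1))
    df$sd2 <- sdv * sqrt(stats::rchisq(k, n2 - 1) / (n2 - 1))
    df$n1 <- n1; df$n2 <- n2
  } else {
    ## Hazard ratios enter only as reported per-study estimates: their
    ## variance is driven by the event count, not the arm sizes.
    events <- sample(20:200, k, replace = TRUE)
    vi <- 4 / events
    yi <- stats::rnorm(k, theta, sqrt(vi))
    z <- .z()
    df$yi <- exp(yi)
    df$ci_low <- exp(yi - z * sqrt(vi))
    df$ci_high <- exp(yi + z * sqrt(vi))
  }
  df
}

#' Simulate one synthetic review
#'
#' Draws study-level data at the arm level (binomial event counts for
#' binary outcomes, normal summary statistics for continuous ones; hazard
#' ratios as reported per-study estimates), runs the "original" analysis
#' under the review's true method configuration, and assembles the
#' published report — then applies the configured information-loss
#' profiles via [degrade_report()].
#'
#' The same seed always yields the identical review.
#'
#' @param config A [review_sim_config()].
#' @return An object of class `synthetic_review` with elements `truth`
#'   (true effect, tau2, methods, and any injected typo), `studies`,
#'   `original_result` (the true `meta_result`), `report` (the possibly
#'   degraded [original_report()]), `profile`, `expected_verdict`.
#' @export
simulate_review <- function(config) {
  stopifnot(inherits(config, "review_sim_config"))
  with_seed(config$seed, {
    review_id <- sprintf("rev%09.0f", as.numeric(config$seed) %% 1e9)
    studies <- .simulate_studies(config, review_id)

    ## Mantel-Haenszel needs 2x2 tables; hazard ratios never have them.
    cfg <- config$method_config
    if (config$measure == "logHR" && cfg$pooling == "mantel_haenszel")
      stop("degenerate config: Mantel-Haenszel with hazard ratios",
           call. = FALSE)

    original_result <- run_meta_analysis(studies, config$measure, cfg)

    ratio <- is_ratio_measure(config$measure)
    bt <- function(x) if (ratio) exp(x) else x
    reported <- reported_methods(
      software = "r", package_or_command = "meta",
      model = original_result$config$model,
      pooling = original_result$config$pooling,
      tau2_estimator = original_result$config$tau2_estimator,
      ci_method = original_result$config$ci_method,
      continuity = original_result$config$continuity,
      level = original_result$config$level)

    report <- original_report(
      review_id = review_id, measure = config$measure,
      pooled_estimate = bt(original_result$y_pooled),
      ci_low = bt(original_result$ci_low),
      ci_high = bt(original_result$ci_high),
      p_value = if (config$report_p) original_result$p_value else NA_real_,
      data_available = if (config$measure == "logHR") "estimates_only"
                       else "summary_stats",
      revman_forest_plot = FALSE, methods = reported,
      author_involved = config$author_involved)

    review <- structure(
      list(truth = list(true_effect = config$true_effect,
                        tau2_true = config$tau2_true,
                        method_config = cfg, typo = NULL),
           studies = studies, original_result = original_result,
           report = report, profile = "none",
           expected_verdict = "fully_reproducible"),
      class = "synthetic_review")

    profiles <- setdiff(config$info_loss, "none")
    for (p in profiles) review <- degrade_report(review, p)
    review
  })
}

#' @export
print.synthetic_review <- function(x, ...) {
  cat(sprintf("<synthetic_review> %s (%s), k = %d, profile: %s\n",
              x$report$review_id, x$report$measure, x$original_result$k,
              paste(x$profile, collapse = "+")))
  cat(sprintf("  truth: effect = %.3g, tau2 = %.3g (%s/%s)\n",
              x$truth$true_effect, x$truth$tau2_true,
              x$truth$method_config$model, x$truth$method_config$pooling))
  print(x$report)
  invisible(x)
}

## Replace one decimal digit of a positive reported value with a different
## digit — the forest-plot typo failure mode.
.inject_typo <- function(value) {
  s <- sprintf("%.2f", value)
  digits <- gregexpr("[0-9]", s)[[1]]
  pos <- digits[sample(length(digits), 1)]
  old <- substr(s, pos, pos)
  new <- sample(setdiff(as.character(0:9), old), 1)
  substr(s, pos, pos) <- new
  out <- as.numeric(s)
  if (out <= 0) out <- value + 0.1  # keep ratio-scale values positive
  list(value = out, original = value)
}

#' Degrade a synthetic review's report by an information-loss profile
#'
#' Applies one reporting failure mode to a complete synthetic review,
#' mimicking how published reviews lose information:
#' \describe{
#'   \item{`estimates_only`}{arm-level summary statistics are dropped; each
#'     study keeps only its effect estimate and 95% CI (on the reported
#'     scale).}
#'   \item{`no_methods`}{all reported method details are blanked, forcing
#'     downstream method resolution onto the rule table.}
#'   \item{`rounded_2dp`}{every reported number (pooled and per-study
#'     estimates, CIs, means, SDs, P value) is rounded to two decimals, as
#'     printed tables do.}
#'   \item{`missing_all`}{no usable study-level data remain; downstream
#'     classification must be `cannot_reproduce`.}
#'   \item{`typo_injection`}{one digit of the printed pooled estimate is
#'     replaced by a different digit; the true value is recorded in
#'     `truth$typo`.}
#' }
#' Profiles compose by repeated application.
#'
#' @param review A `synthetic_review`.
#' @param profile One profile name (see above; `"none"` is a no-op).
#' @return The modified `synthetic_review`.
#' @export
degrade_report <- function(review, profile) {
  stopifnot(inherits(review, "synthetic_review"))
  profile <- match.arg(profile, c("none", "estimates_only", "no_methods",
                                  "rounded_2dp", "missing_all",
                                  "typo_injection"))
  if (profile == "none") return(review)
  studies <- review$studies
  report <- review$report
  expected <- review$expected_verdict

  if (profile == "estimates_only") {
    if (report$data_available != "estimates_only") {
      eff <- compute_study_effects(studies, report$measure,
                                   correction = review$truth$method_config$continuity)
      ratio <- is_ratio_measure(report$measure)
      z <- .z(report$level)
      bt <- function(x) if (ratio) exp(x) else x
      studies$yi <- bt(eff$yi)
      studies$ci_low <- bt(eff$yi - z * sqrt(eff$vi))
      studies$ci_high <- bt(eff$yi + z * sqrt(eff$vi))
      studies[c("e1", "n1", "e2", "n2", "m1", "sd1", "m2", "sd2")] <- NA_real_
      report$data_available <- "estimates_only"
    }
  } else if (profile == "no_methods") {
    report$methods <- reported_methods()
  } else if (profile == "rounded_2dp") {
    num_cols <- c("m1", "sd1", "m2", "sd2", "yi", "ci_low", "ci_high")
    studies[num_cols] <- lapply(studies[num_cols], round, digits = 2)
    report$pooled_estimate <- round(report$pooled_estimate, 2)
    report$ci_low <- round(report$ci_low, 2)
    report$ci_high <- round(report$ci_high, 2)
    report$p_value <- round(report$p_value, 2)
  } else if (profile == "missing_all") {
    studies[c("e1", "n1", "e2", "n2", "m1", "sd1", "m2", "sd2",
              "yi", "ci_low", "ci_high")] <- NA_real_
    report$data_available <- "none"
    expected <- "cannot_reproduce"
  } else if (profile == "typo_injection") {
    typo <- .inject_typo(report$pooled_estimate)
    report$pooled_estimate <- typo$value
    ## keep the report internally consistent (CI must bracket the estimate)
    report$ci_low <- min(report$ci_low, typo$value - abs(typo$value) * 1e-3)
    report$ci_high <- max(report$ci_high, typo$value + abs(typo$value) * 1e-3)
    review$truth$typo <- typo
  }

  if (!identical(expected, "cannot_reproduce") && profile != "none" &&
      review$expected_verdict == "fully_reproducible" &&
      profile %in% c("rounded_2dp", "typo_injection", "no_methods"))
    expected <- NA_character_  # outcome depends on magnitudes, not fixed

  review$studies <- studies
  review$report <- report
  review$profile <- unique(c(setdiff(review$profile, "none"), profile))
  review$expected_verdict <- expected
  review
}

#' Reproduce one review from its (possibly degraded) report
#'
#' The reproduction step of the pipeline: resolve the analysis methods from
#' whatever the report states (via the rule table), then reanalyse with the
#' best available data route — arm-level summary statistics when available,
#' otherwise per-study estimates and CIs through the inverse-variance
#' method. If the resolved methods call for Mantel-Haenszel pooling but
#' only estimates are available, the analysis falls back to inverse
#' variance with a note (a summary-statistics requirement that cannot be
#' met is a classic reproduction obstacle).
#'
#' @param studies The review's studies table (may be all-`NA` when no data
#'   are available).
#' @param report An [original_report()].
#' @param rules Method-resolution rule table.
#' @return A list with `result` (a `meta_result`, or `NULL` when no
#'   reanalysis was possible), `config`, `provenance`, `notes`.
#' @export
reproduce_review <- function(studies, report, rules = default_rule_table()) {
  resolved <- resolve_methods(report$methods, rules, measure = report$measure)
  config <- resolved$config
  notes <- character()

  if (report$data_available == "none")
    return(list(result = NULL, config = config,
                provenance = resolved$provenance,
                notes = "no study-level data available"))

  if (report$data_available == "estimates_only" &&
      config$pooling == "mantel_haenszel") {
    config$pooling <- "inverse_variance"
    notes <- c(notes, paste("summary statistics required for Mantel-Haenszel",
                            "were unavailable; inverse variance used"))
  }

  result <- tryCatch(
    run_meta_analysis(studies, report$measure, config),
    error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
  list(result = result, config = config, provenance = resolved$provenance,
       notes = notes)
}

## Default corpus composition for the end-to-end experiment; chosen to
## mirror the usability mix observed in published intervention reviews
## (about a third with full summary statistics, half with per-study
## estimates only, and a small unusable remainder).
.default_profile_mix <- c("none" = 0.33,
                          "estimates_only" = 0.59,
                          "missing_all" = 0.08)
.default_measure_mix <- c(MD = 0.22, SMD = 0.27, logOR = 0.28,
                          logRR = 0.20, logHR = 0.03)

.draw_true_config <- function(measure) {
  u <- stats::runif(1)
  if (u < 0.5) meta_config("random", tau2_estimator = "DL")
  else if (u < 0.8) meta_config("random", tau2_estimator = "REML")
  else if (u < 0.9 || !measure %in% c("logOR", "logRR"))
    meta_config("fixed")
  else meta_config("fixed", pooling = "mantel_haenszel")
}

#' Run a full synthetic reproduction experiment
#'
#' The end-to-end harness: simulate a corpus of reviews, degrade each
#' published report by a profile drawn from `profile_mix`, resolve methods,
#' reproduce, classify at the main and sensitivity thresholds, and
#' tabulate — the whole pipeline a reproducibility study runs on a real
#' corpus, here with ground truth attached.
#'
#' Profile-mix names may compose profiles with `"+"` (e.g.
#' `"estimates_only+rounded_2dp"`). Each review draws its own effect
#' measure, true effect, heterogeneity, and true method configuration, and
#' uses an RNG stream derived from the master seed and its index.
#'
#' @param n_reviews Number of reviews (default 121, a realistic
#'   reproduction-sample size).
#' @param profile_mix Named probability vector over information-loss
#'   profiles; must sum to 1.
#' @param seed Master seed.
#' @param threshold,sensitivity_threshold Classification thresholds
#'   (default 0.10 and 0.05).
#' @param scale Comparison scale for ratio measures.
#' @param rules Method-resolution rule table.
#' @param measure_mix Named probability vector over measures.
#' @return A list of class `repro_experiment`: `reviews`, `verdicts` (data
#'   frame, one row per review, with ground truth attached),
#'   `verdicts_sensitivity`, `table`, `table_sensitivity`, `agreement`
#'   (per-measure [bland_altman()] summaries), `seed`.
#' @export
run_reproduction_experiment <- function(n_reviews = 121,
                                        profile_mix = .default_profile_mix,
                                        seed = 1,
                                        threshold = 0.10,
                                        sensitivity_threshold = 0.05,
                                        scale = "reported",
                                        rules = default_rule_table(),
                                        measure_mix = .default_measure_mix) {
  stopifnot(abs(sum(profile_mix) - 1) < 1e-8,
            abs(sum(measure_mix) - 1) < 1e-8)

  reviews <- vector("list", n_reviews)
  verdicts <- vector("list", n_reviews)
  verdicts5 <- vector("list", n_reviews)
  extra <- vector("list", n_reviews)
  pairs <- vector("list", n_reviews)

  for (i in seq_len(n_reviews)) {
    si <- seed_for_review(seed, i)
    draw <- with_seed(si + 7, {
      measure <- sample(names(measure_mix), 1, prob = measure_mix)
      profile <- sample(names(profile_mix), 1, prob = profile_mix)
      ratio <- is_ratio_measure(measure)
      list(measure = measure,
           profile = strsplit(profile, "+", fixed = TRUE)[[1]],
           true_effect = if (ratio) stats::rnorm(1, -0.4, 0.3)
                         else stats::rnorm(1, 0.3, 0.25),
           tau2 = if (stats::runif(1) < 0.25) 0
                  else stats::rexp(1, rate = 20),
           config = .draw_true_config(measure),
           report_p = stats::runif(1) < 0.54,
           author = stats::runif(1) < 0.18)
    })
    cfg <- review_sim_config(
      seed = si, measure = draw$measure, true_effect = draw$true_effect,
      tau2_true = draw$tau2, method_config = draw$config,
      info_loss = draw$profile, report_p = draw$report_p,
      author_involved = draw$author)
    rev <- simulate_review(cfg)
    rep_out <- reproduce_review(rev$studies, rev$report, rules)
    v10 <- classify_reproducibility(rev$report, rep_out$result,
                                    threshold = threshold, scale = scale)
    v05 <- classify_reproducibility(rev$report, rep_out$result,
                                    threshold = sensitivity_threshold,
                                    scale = scale)
    reviews[[i]] <- rev
    verdicts[[i]] <- v10
    verdicts5[[i]] <- v05
    extra[[i]] <- data.frame(
      measure = rev$report$measure,
      profile = paste(rev$profile, collapse = "+"),
      author_involved = rev$report$author_involved,
      expected_verdict = rev$expected_verdict,
      true_effect = rev$truth$true_effect,
      tau2_true = rev$truth$tau2_true,
      stringsAsFactors = FALSE)
    ratio <- is_ratio_measure(rev$report$measure)
    pairs[[i]] <- data.frame(
      measure = rev$report$measure,
      original = if (ratio) log(rev$report$pooled_estimate)
                 else rev$report$pooled_estimate,
      reproduced = if (is.null(rep_out$result)) NA_real_
                   else rep_out$result$y_pooled)
  }

  extra_df <- do.call(rbind, extra)
  vdf <- verdicts_to_df(verdicts, extra_df)
  vdf5 <- verdicts_to_df(verdicts5, extra_df)
  structure(
    list(reviews = reviews, verdicts = vdf, verdicts_sensitivity = vdf5,
         table = tabulate_verdicts(vdf, "by_author_involvement"),
         table_sensitivity = tabulate_verdicts(vdf5),
         agreement = agreement_by_measure(do.call(rbind, pairs)),
         seed = seed),
    class = "repro_experiment")
}

#' @export
print.repro_experiment <- function(x, ...) {
  n <- nrow(x$verdicts)
  cat(sprintf("<repro_experiment> %d synthetic reviews (seed %d)\n", n,
              x$seed))
  overall <- x$table[x$table$group == "overall", ]
  for (i in seq_len(nrow(overall)))
    cat(sprintf("  %-24s %3d/%d  %s\n", overall$item[i],
                overall$successes[i], overall$trials[i],
                format_proportion_ci(exact_binomial_ci(overall$successes[i],
                                                       overall$trials[i]))))
  invisible(x)
}
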