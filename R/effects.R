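#' @keywords internal
"_PACKAGE"

## Measures handled throughout the package. Ratio measures are carried on the
## natural-log scale internally ("analysis scale") and back-transformed only
## for reporting and comparison against printed results.
.measures <- c("MD", "SMD", "logOR", "logRR", "logHR")
.ratio_measures <- c("logOR", "logRR", "logHR")

#' Is a measure a ratio measure?
#'
#' Ratio measures (odds, risk, and hazard ratios) are analysed on the
#' natural-log scale and reported on the ratio scale; difference measures
#' (MD, SMD) use the same scale for both.
#'
#' @param measure One of `"MD"`, `"SMD"`, `"logOR"`, `"logRR"`, `"logHR"`.
#' @return Logical.
#' @export
is_ratio_measure <- function(measure) {
  measure <- match.arg(measure, .measures)
  measure %in% .ratio_measures
}

## Exact normal quantile used everywhere a "1.96" would appear, so that CI
## round-trips are bit-faithful to what statistical software prints.
.z <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)

new_effect_estimate <- function(y, v, measure, source) {
  stopifnot(is.finite(y), is.finite(v), v > 0)
  structure(
    list(y = y, v = v, measure = measure, source = source),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s  y = %.6g  v = %.6g  se = %.6g  [%s]\n",
              x$measure, x$y, x$v, sqrt(x$v), x$source))
  invisible(x)
}

## A non-estimable study (double-zero or all-events 2x2 table) is flagged
## rather than silently dropped; downstream pooling excludes it and records
## the reason in the run log.
non_estimable_effect <- function(measure, reason) {
  structure(
    list(y = NA_real_, v = NA_real_, measure = measure,
         source = "from_summary_stats", estimable = FALSE, reason = reason),
    class = c("non_estimable_effect", "effect_estimate")
  )
}

#' Test whether an effect estimate is usable for pooling
#' @param x An object returned by [effect_binary()], [effect_continuous()] or
#'   [effect_from_reported()].
#' @return Logical.
#' @export
is_estimable <- function(x) !inherits(x, "non_estimable_effect")

#' Log odds ratio or log risk ratio from a 2x2 table
#'
#' Computes the study-level effect and its delta-method variance from arm
#' counts. When any cell of the 2x2 table is zero, the continuity rule is
#' applied (by default 0.5 added to all four cells, the common software
#' convention). Tables with zero events in both arms, or events equal to the
#' sample size in both arms, carry no information about a ratio effect and
#' are returned as non-estimable.
#'
#' @param events1,n1 Events and sample size in the first arm.
#' @param events2,n2 Events and sample size in the second arm.
#' @param measure `"logOR"` or `"logRR"`.
#' @param correction Continuity rule: `"add_half"` (default) adds `cc_value`
#'   to every cell of a table containing any zero cell; `"none"` applies no
#'   correction (zero cells then make the effect non-estimable).
#' @param cc_value Constant added under `"add_half"`; default 0.5.
#' @return An `effect_estimate` (log scale), or a `non_estimable_effect`
#'   carrying the reason.
#' @examples
#' effect_binary(10, 100, 5, 100, "logRR")   # y = log 2, v = 0.28
#' effect_binary(0, 10, 5, 10, "logOR")      # continuity-corrected
#' @export
effect_binary <- function(events1, n1, events2, n2,
                          measure = c("logOR", "logRR"),
                          correction = c("add_half", "none"),
                          cc_value = 0.5) {
  measure <- match.arg(measure)
  correction <- match.arg(correction)
  stopifnot(n1 >= 1, n2 >= 1,
            events1 >= 0, events2 >= 0, events1 <= n1, events2 <= n2)

  if (events1 + events2 == 0)
    return(non_estimable_effect(measure, "zero events in both arms"))
  if (events1 == n1 && events2 == n2)
    return(non_estimable_effect(measure, "all events in both arms"))

  a <- events1; b <- n1 - events1
  c <- events2; d <- n2 - events2
  if (any(c(a, b, c, d) == 0)) {
    if (correction == "none")
      return(non_estimable_effect(measure, "zero cell and no continuity correction"))
    a <- a + cc_value; b <- b + cc_value
    c <- c + cc_value; d <- d + cc_value
  }
  m1 <- a + b; m2 <- c + d

  if (measure == "logOR") {
    y <- log((a * d) / (b * c))
    v <- 1 / a + 1 / b + 1 / c + 1 / d
  } else {
    y <- log((a / m1) / (c / m2))
    v <- 1 / a - 1 / m1 + 1 / c - 1 / m2
  }
  new_effect_estimate(y, v, measure, "from_summary_stats")
}

#' Mean difference or standardised mean difference from arm summaries
#'
#' For `measure = "MD"` the effect is `mean1 - mean2` with variance
#' `sd1^2/n1 + sd2^2/n2`. For `measure = "SMD"` the pooled standard deviation
#' standardises the difference; the default `"hedges_g"` variant applies the
#' small-sample correction `J = 1 - 3/(4(n1 + n2 - 2) - 1)` to both the
#' estimate and (squared) to the large-sample variance.
#'
#' For a before-after (change-score) design set `design = "prepost"` and pass
#' the pre/post correlation `r`; arm 1 is then the follow-up and arm 2 the
#' baseline measurement of the same group, and the change-score SD
#' `sqrt(sd1^2 + sd2^2 - 2 r sd1 sd2)` replaces the pooled SD. Omitting `r`
#' for such a design is an error, because the effect is not computable
#' without it.
#'
#' @param mean1,sd1,n1 Summary statistics of the first arm (`sd1 > 0`,
#'   `n1 >= 2`).
#' @param mean2,sd2,n2 Summary statistics of the second arm.
#' @param measure `"MD"` or `"SMD"`.
#' @param smd_variant `"hedges_g"` (default) or `"cohen_d"`.
#' @param design `"parallel"` (two independent groups, default) or
#'   `"prepost"` (one group measured before and after).
#' @param prepost_correlation Correlation between before and after
#'   measurements, in `[-1, 1]`; required when `design = "prepost"`.
#' @return An `effect_estimate`.
#' @examples
#' effect_continuous(1, 1, 20, 0, 1, 20, "MD")    # y = 1, v = 0.1
#' effect_continuous(1, 1, 20, 0, 1, 20, "SMD")   # Hedges g ~ 0.9801
#' @export
effect_continuous <- function(mean1, sd1, n1, mean2, sd2, n2,
                              measure = c("MD", "SMD"),
                              smd_variant = c("hedges_g", "cohen_d"),
                              design = c("parallel", "prepost"),
                              prepost_correlation = NULL) {
  measure <- match.arg(measure)
  smd_variant <- match.arg(smd_variant)
  design <- match.arg(design)
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)

  if (design == "prepost") {
    if (is.null(prepost_correlation) || is.na(prepost_correlation))
      stop("before-after design requires the missing input 'prepost_correlation' ",
           "(correlation between before and after measurements)", call. = FALSE)
    r <- prepost_correlation
    stopifnot(r >= -1, r <= 1, n1 == n2)
    n <- n1
    sd_change <- sqrt(sd1^2 + sd2^2 - 2 * r * sd1 * sd2)
    delta <- mean1 - mean2
    if (measure == "MD")
      return(new_effect_estimate(delta, sd_change^2 / n, measure,
                                 "from_summary_stats"))
    if (sd_change <= 0) stop("degenerate dispersion", call. = FALSE)
    d <- delta / sd_change
    v <- 1 / n + d^2 / (2 * n)
    if (smd_variant == "hedges_g") {
      J <- 1 - 3 / (4 * (n - 1) - 1)
      d <- J * d; v <- J^2 * v
    }
    return(new_effect_estimate(d, v, measure, "from_summary_stats"))
  }

  if (measure == "MD") {
    y <- mean1 - mean2
    v <- sd1^2 / n1 + sd2^2 / n2
    return(new_effect_estimate(y, v, measure, "from_summary_stats"))
  }

  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (s_pooled <= 0) stop("degenerate dispersion", call. = FALSE)
  d <- (mean1 - mean2) / s_pooled
  v <- 1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2))
  if (smd_variant == "hedges_g") {
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    d <- J * d
    v <- J^2 * v
  }
  new_effect_estimate(d, v, measure, "from_summary_stats")
}

#' Recover an effect estimate from a reported point estimate and CI
#'
#' When only study-level effect estimates and confidence intervals are
#' available in a report, the analysis-scale estimate and its variance are
#' recovered by inverting the Wald interval: ratio measures are mapped to the
#' natural-log scale first, and `SE = (hi - lo) / (2 z)` with the exact
#' normal quantile for the stated level.
#'
#' @param estimate,ci_low,ci_high The reported point estimate and CI bounds,
#'   on the reported scale (`ci_low < estimate < ci_high`; for ratio measures
#'   all three must be positive).
#' @param measure Effect measure.
#' @param level Confidence level of the reported interval (default 0.95).
#' @return An `effect_estimate` with `source = "from_reported"`.
#' @examples
#' effect_from_reported(2, 1, 4, "logOR")   # y = log 2, se ~ 0.3537
#' @export
effect_from_reported <- function(estimate, ci_low, ci_high,
                                 measure = c("MD", "SMD", "logOR", "logRR", "logHR"),
                                 level = 0.95) {
  measure <- match.arg(measure)
  stopifnot(level > 0, level < 1)
  if (!(ci_low < estimate && estimate < ci_high))
    stop("inconsistent report: CI [", ci_low, ", ", ci_high,
         "] does not bracket the estimate ", estimate,
         " (candidate typographical error)", call. = FALSE)
  if (is_ratio_measure(measure)) {
    if (!(estimate > 0 && ci_low > 0 && ci_high > 0))
      stop("inconsistent report: ratio-measure values must be positive",
           call. = FALSE)
    y <- log(estimate); lo <- log(ci_low); hi <- log(ci_high)
  } else {
    y <- estimate; lo <- ci_low; hi <- ci_high
  }
  se <- (hi - lo) / (2 * .z(level))
  new_effect_estimate(y, se^2, measure, "from_reported")
}

#' Per-study effects for one review's study table
#'
#' Applies the appropriate effect computation to every row of a studies table
#' (see [read_studies_table()] for the column layout): arm-level binary or
#' continuous summaries when present, otherwise the reported estimate/CI
#' route. Non-estimable studies are retained with `estimable = FALSE` and a
#' reason, so exclusions are auditable.
#'
#' @param studies A data frame with one row per study, using the studies-CSV
#'   column layout.
#' @param measure Effect measure shared by the review.
#' @param correction,cc_value Continuity rule for binary data, as in
#'   [effect_binary()].
#' @param smd_variant SMD variant, as in [effect_continuous()].
#' @return A data frame with columns `study_id`, `yi`, `vi`, `source`,
#'   `estimable`, `reason`.
#' @export
compute_study_effects <- function(studies, measure,
                                  correction = "add_half", cc_value = 0.5,
                                  smd_variant = "hedges_g") {
  measure <- match.arg(measure, .measures)
  out <- lapply(seq_len(nrow(studies)), function(i) {
    row <- studies[i, ]
    eff <- tryCatch({
      if (!is.na(row$e1) && !is.na(row$n1) && measure %in% c("logOR", "logRR")) {
        effect_binary(row$e1, row$n1, row$e2, row$n2, measure,
                      correction = correction, cc_value = cc_value)
      } else if (!is.na(row$m1) && !is.na(row$sd1) && measure %in% c("MD", "SMD")) {
        pr <- if ("prepost_r" %in% names(row)) row$prepost_r else NA_real_
        effect_continuous(row$m1, row$sd1, row$n1, row$m2, row$sd2, row$n2,
                          measure, smd_variant = smd_variant,
                          design = if (!is.na(pr)) "prepost" else "parallel",
                          prepost_correlation = if (!is.na(pr)) pr else NULL)
      } else if (!is.na(row$yi)) {
        effect_from_reported(row$yi, row$ci_low, row$ci_high, measure)
      } else {
        non_estimable_effect(measure, "no usable data in row")
      }
    }, error = function(e) non_estimable_effect(measure, conditionMessage(e)))
    data.frame(study_id = as.character(row$study_id),
               yi = eff$y, vi = eff$v,
               source = eff$source,
               estimable = is_estimable(eff),
               reason = if (is_estimable(eff)) NA_character_ else eff$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
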