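#' An original review's printed results
#'
#' The unit of comparison: what the review actually printed for its index
#' meta-analysis (pooled estimate and CI on the reported scale, optionally a
#' P value), together with the availability of its underlying data and the
#' reported method details.
#'
#' @param review_id Identifier of the review.
#' @param measure Effect measure of the index meta-analysis.
#' @param pooled_estimate,ci_low,ci_high Printed pooled estimate and 95% CI,
#'   on the reported scale (ratio scale for OR/RR/HR).
#' @param p_value Printed P value of the summary-effect test, or `NA` if not
#'   reported.
#' @param data_available `"summary_stats"` (arm-level summaries available),
#'   `"estimates_only"` (per-study estimates and CIs only), or `"none"`.
#' @param revman_forest_plot Logical; reviews presenting a RevMan forest
#'   plot display their data and methods and are treated as inherently
#'   reproducible, so they fall outside the reproduction sample.
#' @param methods A [reported_methods()] (possibly all-missing).
#' @param author_involved Logical; whether the original authors supplied
#'   data or code. Used only for grouped tabulations.
#' @param level Confidence level of the printed interval.
#' @return An object of class `original_report`.
#' @export
original_report <- function(review_id, measure, pooled_estimate, ci_low,
                            ci_high, p_value = NA_real_,
                            data_available = c("summary_stats",
                                               "estimates_only", "none"),
                            revman_forest_plot = FALSE,
                            methods = reported_methods(),
                            author_involved = FALSE, level = 0.95) {
  measure <- match.arg(measure, .measures)
  data_available <- match.arg(data_available)
  if (data_available != "none") {
    stopifnot(ci_low < ci_high)
    if (is_ratio_measure(measure))
      stopifnot(pooled_estimate > 0, ci_low > 0, ci_high > 0)
  }
  structure(list(review_id = review_id, measure = measure,
                 pooled_estimate = pooled_estimate, ci_low = ci_low,
                 ci_high = ci_high, p_value = p_value,
                 data_available = data_available,
                 revman_forest_plot = revman_forest_plot,
                 methods = methods, author_involved = author_involved,
                 level = level),
            class = "original_report")
}

#' @export
print.original_report <- function(x, ...) {
  cat(sprintf("<original_report> %s (%s): %.4g [%.4g, %.4g]",
              x$review_id, x$measure, x$pooled_estimate, x$ci_low, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat(sprintf("  data: %s\n", x$data_available))
  invisible(x)
}

## Map a meta_result to the scale the original report printed.
.reproduced_on_scale <- function(reproduced, ratio, scale) {
  if (ratio && scale == "reported")
    c(est = exp(reproduced$y_pooled), lo = exp(reproduced$ci_low),
      hi = exp(reproduced$ci_high))
  else
    c(est = reproduced$y_pooled, lo = reproduced$ci_low,
      hi = reproduced$ci_high)
}

.original_on_scale <- function(original, ratio, scale) {
  if (ratio && scale == "log")
    c(est = log(original$pooled_estimate), lo = log(original$ci_low),
      hi = log(original$ci_high))
  else
    c(est = original$pooled_estimate, lo = original$ci_low,
      hi = original$ci_high)
}

#' Significance band of a P value
#'
#' Categorises a P value into the commonly used significance bands
#' `P < 0.01`, `0.01 <= P < 0.05`, `0.05 <= P < 0.1`, `P >= 0.1`.
#' Boundaries belong to the upper band, so `p = 0.05` falls in
#' `0.05 <= P < 0.1`.
#'
#' @param p A probability in `[0, 1]` (vectorised).
#' @return A factor with levels `"<0.01"`, `"0.01-<0.05"`, `"0.05-<0.1"`,
#'   `">=0.1"`.
#' @export
p_category <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  cut(p, breaks = c(-Inf, 0.01, 0.05, 0.1, Inf),
      labels = c("<0.01", "0.01-<0.05", "0.05-<0.1", ">=0.1"),
      right = FALSE)
}

#' Concordance of two P values by significance band
#'
#' @param p_orig,p_repro P values from the original and reproduced analyses.
#' @return `TRUE` if both fall in the same band of [p_category()], `NA` if
#'   either is missing.
#' @export
p_concordance <- function(p_orig, p_repro) {
  if (is.na(p_orig) || is.na(p_repro)) return(NA)
  as.character(p_category(p_orig)) == as.character(p_category(p_repro))
}

#' Detect a meaningful difference between original and reproduced results
#'
#' A difference is meaningful if it could change the interpretation of the
#' review: the original and reproduced summary estimates lie on opposite
#' sides of the null effect (one for ratio measures, zero for difference
#' measures), or one of the two 95% CIs includes the null while the other
#' excludes it. An estimate lying exactly on the null has no direction and
#' can never produce a direction flip.
#'
#' @param original An [original_report()].
#' @param reproduced A `meta_result`, or `NULL` when reanalysis was not
#'   possible.
#' @param scale `"reported"` or `"log"`; both give identical answers for
#'   these rules, the option exists for symmetry with
#'   [classify_reproducibility()].
#' @return A list with `meaningful` (logical) and `reasons` (character
#'   subset of `"direction_flip"`, `"null_crossing_change"`).
#' @export
detect_meaningful_difference <- function(original, reproduced,
                                         scale = c("reported", "log")) {
  scale <- match.arg(scale)
  if (is.null(reproduced))
    return(list(meaningful = FALSE, reasons = character()))
  ratio <- is_ratio_measure(original$measure)
  null_value <- if (ratio && scale == "reported") 1 else 0
  o <- .original_on_scale(original, ratio, scale)
  r <- .reproduced_on_scale(reproduced, ratio, scale)

  reasons <- character()
  dir_o <- sign(o["est"] - null_value)
  dir_r <- sign(r["est"] - null_value)
  if (dir_o != 0 && dir_r != 0 && dir_o != dir_r)
    reasons <- c(reasons, "direction_flip")
  includes_o <- o["lo"] <= null_value && null_value <= o["hi"]
  includes_r <- r["lo"] <= null_value && null_value <= r["hi"]
  if (xor(includes_o, includes_r))
    reasons <- c(reasons, "null_crossing_change")
  list(meaningful = length(reasons) > 0, reasons = reasons)
}

#' Classify a reproduction attempt against the original report
#'
#' Implements the quantified reproducibility criteria: the attempt is
#' `fully_reproducible` when the relative difference between the reproduced
#' and originally reported summary estimate, and between the two 95% CI
#' widths, are both below the threshold (default 10%; 5% as a sensitivity
#' analysis); `not_fully_reproducible` when either reaches the threshold;
#' and `cannot_reproduce` when no reanalysis was possible
#' (`data_available = "none"` or `reproduced = NULL`).
#'
#' Ratio measures are compared on the reported (ratio) scale by default,
#' since the printed review results live on that scale; `scale = "log"`
#' compares on the analysis scale instead, and the choice is recorded in
#' the verdict. If the original estimate is numerically zero on a
#' difference scale, the relative difference is undefined; the estimate
#' difference is then taken relative to the original CI width instead, and
#' the fallback is recorded in the verdict notes.
#'
#' @param original An [original_report()].
#' @param reproduced A `meta_result` on the analysis scale, or `NULL`.
#' @param threshold Relative-difference threshold (default 0.10).
#' @param scale Comparison scale for ratio measures, `"reported"` (default)
#'   or `"log"`.
#' @return An object of class `repro_verdict` with fields `category`,
#'   `rel_diff_estimate`, `rel_diff_ci_width`, `threshold`, `meaningful`,
#'   `meaningful_reasons`, `p_concordant`, `scale`, `notes`.
#' @examples
#' orig <- original_report("r1", "MD", 0.5, 0.3, 0.7)
#' rep1 <- pool_inverse_variance(0.5, 0.0104, meta_config("fixed"), "MD")
#' classify_reproducibility(orig, rep1)
#' @export
classify_reproducibility <- function(original, reproduced, threshold = 0.10,
                                     scale = c("reported", "log")) {
  scale <- match.arg(scale)
  stopifnot(threshold > 0, threshold < 1)

  if (original$data_available == "none" || is.null(reproduced)) {
    return(structure(
      list(review_id = original$review_id, category = "cannot_reproduce",
           rel_diff_estimate = NA_real_, rel_diff_ci_width = NA_real_,
           threshold = threshold, meaningful = NA,
           meaningful_reasons = character(), p_concordant = NA,
           scale = scale, notes = "no reanalysis possible"),
      class = "repro_verdict"))
  }

  ratio <- is_ratio_measure(original$measure)
  o <- .original_on_scale(original, ratio, scale)
  r <- .reproduced_on_scale(reproduced, ratio, scale)
  notes <- character()

  if (abs(o["est"]) < 1e-8 && !(ratio && scale == "reported")) {
    rel_est <- abs(r["est"] - o["est"]) / (o["hi"] - o["lo"])
    notes <- c(notes,
               "original estimate at zero: difference taken relative to original CI width")
  } else {
    rel_est <- abs(r["est"] - o["est"]) / abs(o["est"])
  }
  width_o <- o["hi"] - o["lo"]
  width_r <- r["hi"] - r["lo"]
  rel_width <- abs(width_r - width_o) / width_o

  category <- if (rel_est < threshold && rel_width < threshold)
    "fully_reproducible" else "not_fully_reproducible"
  md <- detect_meaningful_difference(original, reproduced, scale)

  structure(
    list(review_id = original$review_id, category = category,
         rel_diff_estimate = unname(rel_est),
         rel_diff_ci_width = unname(rel_width),
         threshold = threshold, meaningful = md$meaningful,
         meaningful_reasons = md$reasons,
         p_concordant = p_concordance(original$p_value, reproduced$p_value),
         scale = scale, notes = notes),
    class = "repro_verdict")
}

#' @export
print.repro_verdict <- function(x, ...) {
  cat(sprintf("<repro_verdict> %s: %s (threshold %g%%)\n",
              x$review_id, x$category, 100 * x$threshold))
  if (!is.na(x$rel_diff_estimate))
    cat(sprintf("  rel diff estimate = %.4g, CI width = %.4g; meaningful = %s\n",
                x$rel_diff_estimate, x$rel_diff_ci_width, x$meaningful))
  if (length(x$meaningful_reasons))
    cat("  reasons:", paste(x$meaningful_reasons, collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Collect verdicts into a tidy data frame
#'
#' @param verdicts A list of `repro_verdict` objects.
#' @param extra Optional data frame of per-review columns (same order) to
#'   bind on, e.g. measure or ground-truth labels.
#' @return A data frame with one row per verdict.
#' @export
verdicts_to_df <- function(verdicts, extra = NULL) {
  df <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(review_id = v$review_id, category = v$category,
               rel_diff_estimate = v$rel_diff_estimate,
               rel_diff_ci_width = v$rel_diff_ci_width,
               threshold = v$threshold,
               meaningful = v$meaningful,
               reasons = paste(v$meaningful_reasons, collapse = ";"),
               p_concordant = v$p_concordant,
               scale = v$scale,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}
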