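## Studies-CSV column layout shared by readers, writers, and the generator.
.studies_cols <- c("review_id", "study_id", "measure", "e1", "n1", "e2",
                   "n2", "m1", "sd1", "m2", "sd2", "yi", "ci_low",
                   "ci_high", "prepost_r")

#' Read a studies table
#'
#' Reads the study-level input CSV (UTF-8, comma-separated, header row,
#' empty cells for missing values) with columns `review_id`, `study_id`,
#' `measure`, `e1`, `n1`, `e2`, `n2`, `m1`, `sd1`, `m2`, `sd2`, `yi`,
#' `ci_low`, `ci_high`, `prepost_r`. Binary rows fill `e*`/`n*`, continuous
#' rows fill `m*`/`sd*`/`n*`, estimate-only rows fill `yi`/`ci_*` (on the
#' reported scale).
#'
#' Rows failing validation (events exceeding the sample size, non-positive
#' SDs, CI not bracketing the estimate) are rejected individually with the
#' offending line number and reason; a review mixing different effect
#' measures is a fatal error, as its rows cannot form one meta-analysis.
#'
#' @param path CSV file path.
#' @return A list with `studies` (validated data frame) and `rejected`
#'   (data frame of line numbers and reasons; zero rows when clean).
#' @export
read_studies_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.studies_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[.studies_cols]
  num_cols <- setdiff(.studies_cols, c("review_id", "study_id", "measure"))
  df[num_cols] <- lapply(df[num_cols], as.numeric)

  mixed <- tapply(df$measure, df$review_id,
                  function(m) length(unique(m)) > 1)
  if (any(mixed))
    stop("mixed measures within index meta-analysis: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)

  reason <- rep(NA_character_, nrow(df))
  has_binary <- !is.na(df$e1) | !is.na(df$e2)
  has_cont <- !is.na(df$m1) | !is.na(df$m2)
  has_est <- !is.na(df$yi)
  bad <- function(cond, msg) {
    sel <- which(cond & is.na(reason))
    reason[sel] <<- msg
  }
  bad(!has_binary & !has_cont & !has_est, "no usable data in row")
  bad(has_binary & (is.na(df$e1) | is.na(df$n1) | is.na(df$e2) | is.na(df$n2)),
      "incomplete binary arms")
  bad(has_binary & (df$e1 > df$n1 | df$e2 > df$n2),
      "events exceed sample size")
  bad(has_binary & (df$e1 < 0 | df$e2 < 0 | df$n1 < 1 | df$n2 < 1),
      "negative counts")
  bad(has_cont & (is.na(df$sd1) | is.na(df$sd2) | is.na(df$n1) | is.na(df$n2)),
      "incomplete continuous arms")
  bad(has_cont & (df$sd1 <= 0 | df$sd2 <= 0), "non-positive SD")
  bad(has_est & (is.na(df$ci_low) | is.na(df$ci_high)),
      "estimate without CI")
  bad(has_est & !is.na(df$ci_low) & !is.na(df$ci_high) &
        !(df$ci_low < df$yi & df$yi < df$ci_high),
      "CI does not bracket estimate")

  rejected <- data.frame(line = which(!is.na(reason)) + 1L,
                         study_id = df$study_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(studies = df[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Write a studies table
#' @param studies Data frame in the studies-CSV layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies_table <- function(studies, path) {
  utils::write.csv(studies[.studies_cols], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.reports_cols <- c("review_id", "measure", "pooled_estimate", "ci_low",
                   "ci_high", "p_value", "data_available",
                   "revman_forest_plot", "author_involved", "level",
                   "software", "package_or_command", "model", "pooling",
                   "tau2_estimator", "ci_method", "continuity",
                   "methods_level")

#' Write original-report records
#' @param reports A list of [original_report()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports_table <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    m <- r$methods
    chr <- function(x) if (.is_missing_field(x)) NA_character_ else as.character(x)
    data.frame(review_id = r$review_id, measure = r$measure,
               pooled_estimate = r$pooled_estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value,
               data_available = r$data_available,
               revman_forest_plot = r$revman_forest_plot,
               author_involved = r$author_involved, level = r$level,
               software = chr(m$software),
               package_or_command = chr(m$package_or_command),
               model = chr(m$model), pooling = chr(m$pooling),
               tau2_estimator = chr(m$tau2_estimator),
               ci_method = chr(m$ci_method), continuity = chr(m$continuity),
               methods_level = if (.is_missing_field(m$level)) NA_real_
                               else as.numeric(m$level),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read original-report records
#' @param path CSV written by [write_reports_table()].
#' @return A list of [original_report()] objects.
#' @export
read_reports_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.reports_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    original_report(
      review_id = r$review_id, measure = r$measure,
      pooled_estimate = r$pooled_estimate, ci_low = r$ci_low,
      ci_high = r$ci_high,
      p_value = if (is.na(r$p_value)) NA_real_ else r$p_value,
      data_available = r$data_available,
      revman_forest_plot = isTRUE(r$revman_forest_plot),
      methods = reported_methods(
        software = r$software, package_or_command = r$package_or_command,
        model = r$model, pooling = r$pooling,
        tau2_estimator = r$tau2_estimator, ci_method = r$ci_method,
        continuity = r$continuity, level = r$methods_level),
      author_involved = isTRUE(r$author_involved),
      level = r$level)
  })
}

#' Write a synthetic corpus to CSV files
#'
#' Emits the three files the pipeline consumes: the studies table, the
#' reports table, and a ground-truth table (true effects, heterogeneity,
#' methods, profiles) kept separate so a blinded reproduction run never
#' sees it.
#'
#' @param reviews List of `synthetic_review` objects.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_corpus <- function(reviews, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  studies <- do.call(rbind, lapply(reviews, `[[`, "studies"))
  reports <- lapply(reviews, `[[`, "report")
  truth <- do.call(rbind, lapply(reviews, function(r)
    data.frame(review_id = r$report$review_id,
               true_effect = r$truth$true_effect,
               tau2_true = r$truth$tau2_true,
               model = r$truth$method_config$model,
               pooling = r$truth$method_config$pooling,
               tau2_estimator = r$truth$method_config$tau2_estimator,
               profile = paste(r$profile, collapse = "+"),
               expected_verdict = r$expected_verdict,
               stringsAsFactors = FALSE)))
  paths <- c(studies = file.path(dir, "studies.csv"),
             reports = file.path(dir, "reports.csv"),
             truth = file.path(dir, "truth.csv"))
  write_studies_table(studies, paths["studies"])
  write_reports_table(reports, paths["reports"])
  utils::write.csv(truth, paths["truth"], row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Write pooled results
#'
#' One row per review, with the analysis-scale estimate and, for ratio
#' measures, the back-transformed ratio-scale estimate and CI alongside.
#'
#' @param results Named list of `meta_result` objects (names = review ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pooled_table <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(id) {
    x <- results[[id]]
    ratio <- is_ratio_measure(x$measure)
    data.frame(review_id = id, k = x$k, measure = x$measure,
               model = x$config$model, pooling = x$config$pooling,
               tau2_estimator = x$config$tau2_estimator,
               y_pooled = x$y_pooled, ci_low = x$ci_low,
               ci_high = x$ci_high, p_value = x$p_value, Q = x$Q,
               tau2 = x$tau2, i2 = x$i2,
               estimate_ratio = if (ratio) exp(x$y_pooled) else NA_real_,
               ci_low_ratio = if (ratio) exp(x$ci_low) else NA_real_,
               ci_high_ratio = if (ratio) exp(x$ci_high) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write verdicts
#' @param verdicts Data frame from [verdicts_to_df()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts_table <- function(verdicts, path) {
  utils::write.csv(verdicts, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pool every review in a studies table
#'
#' @param studies Data frame in the studies-CSV layout (possibly several
#'   reviews).
#' @param config A [meta_config()] applied to every review, or a named list
#'   of per-review configurations.
#' @return Named list of `meta_result` objects.
#' @export
pool_reviews <- function(studies, config = meta_config()) {
  ids <- unique(studies$review_id)
  out <- lapply(ids, function(id) {
    sub <- studies[studies$review_id == id, , drop = FALSE]
    cfg <- if (inherits(config, "meta_config")) config else config[[id]]
    run_meta_analysis(sub, sub$measure[1], cfg)
  })
  stats::setNames(out, ids)
}
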