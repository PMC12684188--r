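#' Bland-Altman agreement between original and reproduced estimates
#'
#' Computes paired-differences agreement statistics for one effect measure:
#' differences `reproduced - original` on the analysis scale (natural log
#' for ratio measures), their mean, sample standard deviation (n - 1), and
#' the 95% limits of agreement `mean +/- 1.959964 sd`. For ratio measures
#' the mean difference and limits are also back-transformed by
#' exponentiation, giving a ratio of ratios (e.g. a ratio of odds ratios)
#' with its limits.
#'
#' With a single pair the mean difference is returned but the limits are
#' absent. The two vectors must be on the same (analysis) scale; pass
#' `log = TRUE` to log-transform ratio-scale inputs first.
#'
#' @param original,reproduced Numeric vectors of paired summary estimates
#'   on the analysis scale.
#' @param measure The common effect measure of all pairs.
#' @param log If `TRUE`, log-transform both inputs first (they are then
#'   expected on the ratio scale; only valid for ratio measures).
#' @param level Nominal level of the limits of agreement.
#' @return An object of class `agreement_summary` with fields `measure`,
#'   `n_pairs`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `back_transformed` (ratio measures only), `diffs`, `means`.
#' @examples
#' bland_altman(c(0.2, 0.5), c(0.1, 0.6), "MD")  # diffs -0.1, +0.1
#' @export
bland_altman <- function(original, reproduced, measure, log = FALSE,
                         level = 0.95) {
  measure <- match.arg(measure, .measures)
  stopifnot(length(original) == length(reproduced), length(original) >= 1)
  ratio <- is_ratio_measure(measure)
  if (log) {
    if (!ratio) stop("log transform only applies to ratio measures",
                     call. = FALSE)
    stopifnot(all(original > 0), all(reproduced > 0))
    original <- base::log(original); reproduced <- base::log(reproduced)
  }
  diffs <- reproduced - original
  n <- length(diffs)
  mean_diff <- mean(diffs)
  if (n >= 2) {
    sd_diff <- stats::sd(diffs)
    z <- .z(level)
    loa_low <- mean_diff - z * sd_diff
    loa_high <- mean_diff + z * sd_diff
  } else {
    sd_diff <- NA_real_; loa_low <- NA_real_; loa_high <- NA_real_
  }
  bt <- NULL
  if (ratio)
    bt <- list(mean_ratio = exp(mean_diff),
               loa_low = exp(loa_low), loa_high = exp(loa_high))
  structure(list(measure = measure, n_pairs = n, mean_diff = mean_diff,
                 sd_diff = sd_diff, loa_low = loa_low, loa_high = loa_high,
                 back_transformed = bt, diffs = diffs,
                 means = (original + reproduced) / 2, level = level),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s, n = %d pairs\n", x$measure, x$n_pairs))
  cat(sprintf("  mean diff = %.4g, sd = %.4g, limits of agreement [%.4g, %.4g]\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  if (!is.null(x$back_transformed))
    cat(sprintf("  ratio scale: %.4g, limits [%.4g, %.4g]\n",
                x$back_transformed$mean_ratio, x$back_transformed$loa_low,
                x$back_transformed$loa_high))
  invisible(x)
}

#' Banksia scaling of an original/reproduced pair
#'
#' Each original summary estimate is treated as the reference: it is centred
#' on zero and its CI scaled to span one, so a symmetric original interval
#' maps to exactly `(0, -0.5, 0.5)`; the reproduced estimate and CI are
#' transformed by the same shift and scale,
#' `scaled(x) = (x - est_orig) / (hi_orig - lo_orig)`. Asymmetric original
#' intervals keep the estimate at 0 with endpoints at
#' `(lo - est)/width` and `(hi - est)/width`; set
#' `center = "midpoint"` to centre on the interval midpoint instead.
#' Ratio measures must be log-transformed first (`log = TRUE` does this).
#'
#' @param original,reproduced Length-3 numeric vectors
#'   `(estimate, ci_low, ci_high)`.
#' @param log If `TRUE`, log-transform both triples first.
#' @param center `"estimate"` (default) or `"midpoint"`.
#' @return An object of class `banksia_pair` with `original_scaled` and
#'   `reproduced_scaled`, each `(estimate, ci_low, ci_high)`.
#' @examples
#' banksia_scale(c(2, 1, 3), c(2.5, 1.5, 3.5))  # (0.25, -0.25, 0.75)
#' @export
banksia_scale <- function(original, reproduced, log = FALSE,
                          center = c("estimate", "midpoint")) {
  center <- match.arg(center)
  stopifnot(length(original) == 3, length(reproduced) == 3)
  if (log) {
    stopifnot(all(original > 0), all(reproduced > 0))
    original <- base::log(original); reproduced <- base::log(reproduced)
  }
  o_est <- original[1]; o_lo <- original[2]; o_hi <- original[3]
  stopifnot(o_lo < o_est, o_est < o_hi)
  width <- o_hi - o_lo
  if (width <= 0 || !is.finite(width))
    stop("degenerate interval: original CI has zero width", call. = FALSE)
  ref <- if (center == "estimate") o_est else (o_lo + o_hi) / 2
  sc <- function(x) (x - ref) / width
  structure(list(
    original_scaled = stats::setNames(sc(c(o_est, o_lo, o_hi)),
                                      c("estimate", "ci_low", "ci_high")),
    reproduced_scaled = stats::setNames(sc(reproduced),
                                        c("estimate", "ci_low", "ci_high")),
    center = center),
    class = "banksia_pair")
}

#' @export
print.banksia_pair <- function(x, ...) {
  cat(sprintf("<banksia_pair> original (%.3g, %.3g, %.3g) -> reproduced (%.3g, %.3g, %.3g)\n",
              x$original_scaled[1], x$original_scaled[2], x$original_scaled[3],
              x$reproduced_scaled[1], x$reproduced_scaled[2],
              x$reproduced_scaled[3]))
  invisible(x)
}

#' Per-measure agreement summaries over a corpus
#'
#' Splits paired original/reproduced pooled estimates by measure and runs
#' [bland_altman()] on each measure with at least `min_pairs` pairs;
#' measures with fewer pairs are skipped with a note (small samples give
#' unstable limits of agreement, so e.g. a measure represented by only
#' three reviews is not summarised).
#'
#' @param pairs A data frame with columns `measure`, `original`,
#'   `reproduced`, the estimates on the analysis scale.
#' @param min_pairs Minimum pairs per measure (default 4).
#' @return A list with `summaries` (named list of `agreement_summary`) and
#'   `skipped` (named integer vector of pair counts for skipped measures).
#' @export
agreement_by_measure <- function(pairs, min_pairs = 4) {
  stopifnot(all(c("measure", "original", "reproduced") %in% names(pairs)))
  out <- list(); skipped <- integer()
  for (m in unique(pairs$measure)) {
    sub <- pairs[pairs$measure == m & !is.na(pairs$reproduced), ]
    if (nrow(sub) < min_pairs) {
      skipped[m] <- nrow(sub)
      next
    }
    out[[m]] <- bland_altman(sub$original, sub$reproduced, m)
  }
  list(summaries = out, skipped = skipped)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means, with horizontal lines
#' at the mean difference and the 95% limits of agreement.
#'
#' @param x An `agreement_summary`.
#' @return A ggplot object (save with [ggplot2::ggsave()]).
#' @export
plot_bland_altman <- function(x) {
  stopifnot(inherits(x, "agreement_summary"))
  df <- data.frame(mean = x$means, diff = x$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = x$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(x$loa_low, x$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of original and reproduced estimate",
      y = "Reproduced - original",
      title = sprintf("Bland-Altman: %s (n = %d)", x$measure, x$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Banksia plot
#'
#' One horizontal strip per review: the reference band from -0.5 to 0.5
#' (every original CI after scaling) and the scaled reproduced estimate
#' with its interval.
#'
#' @param pairs A list of `banksia_pair` objects, optionally named by
#'   review.
#' @return A ggplot object.
#' @export
plot_banksia <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  ids <- names(pairs)
  if (is.null(ids)) ids <- as.character(seq_along(pairs))
  df <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    r <- pairs[[i]]$reproduced_scaled
    data.frame(review = ids[i], est = r[1], lo = r[2], hi = r[3])
  }))
  df$review <- factor(df$review, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(y = review)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = 0.5, ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::geom_vline(xintercept = c(-0.5, 0, 0.5), linetype = "dotted") +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi, yend = review)) +
    ggplot2::geom_point(ggplot2::aes(x = est)) +
    ggplot2::labs(x = "Scaled estimate (original CI spans -0.5 to 0.5)",
                  y = NULL, title = "Banksia comparison") +
    ggplot2::theme_minimal()
}
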