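#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from beta-distribution quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Vectorised
#' over `successes`/`trials`.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return A data frame of class `proportion_ci` with columns `successes`,
#'   `trials`, `point`, `lower`, `upper`, `level`.
#' @examples
#' exact_binomial_ci(104, 121)   # ~ (0.78, 0.92)
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  stopifnot(length(trials) %in% c(1, length(successes)))
  trials <- rep_len(trials, length(successes))
  if (any(trials < 1)) stop("trials must be at least 1", call. = FALSE)
  stopifnot(all(successes >= 0), all(successes <= trials),
            level > 0, level < 1)
  alpha <- 1 - level
  lower <- ifelse(successes == 0, 0,
                  stats::qbeta(alpha / 2, successes, trials - successes + 1))
  upper <- ifelse(successes == trials, 1,
                  stats::qbeta(1 - alpha / 2, successes + 1,
                               trials - successes))
  structure(data.frame(successes = successes, trials = trials,
                       point = successes / trials,
                       lower = lower, upper = upper, level = level),
            class = c("proportion_ci", "data.frame"))
}

## Percentages rounded half-up to integers, as results sections print them.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format an exact binomial interval the way a results section prints it
#'
#' @param ci A `proportion_ci` row.
#' @return Character, e.g. `"86% (95% CI 78% to 92%; n=104/121)"`.
#' @export
format_proportion_ci <- function(ci) {
  sprintf("%d%% (%d%% CI %d%% to %d%%; n=%d/%d)",
          round_half_up(100 * ci$point), round_half_up(100 * ci$level),
          round_half_up(100 * ci$lower), round_half_up(100 * ci$upper),
          ci$successes, ci$trials)
}

#' Tabulate reproducibility verdicts with exact binomial CIs
#'
#' Frequency table of the reproducibility categories — plus rows for
#' meaningful differences and P-value discordance — each with a
#' Clopper-Pearson interval for the corpus proportion. Grouping by author
#' involvement splits the category rows by whether the original authors
#' supplied data or code.
#'
#' P-discordance uses as its denominator only the reviews where both an
#' original and a reproduced P value exist, since concordance is undefined
#' otherwise.
#'
#' @param verdicts A data frame as from [verdicts_to_df()]; an
#'   `author_involved` logical column is required for grouped tabulation.
#' @param grouping `"overall"` or `"by_author_involvement"`.
#' @param level Confidence level for the intervals.
#' @return A data frame with columns `group`, `item`, `successes`, `trials`,
#'   `percent`, `ci_low_pct`, `ci_high_pct` (percentages rounded half-up to
#'   integers; raw proportions in `point`, `lower`, `upper`).
#' @export
tabulate_verdicts <- function(verdicts,
                              grouping = c("overall",
                                           "by_author_involvement"),
                              level = 0.95) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(verdicts) >= 1)
  n <- nrow(verdicts)
  categories <- c("fully_reproducible", "not_fully_reproducible",
                  "cannot_reproduce")

  row_for <- function(group, item, x, n_row) {
    ci <- exact_binomial_ci(x, n_row, level)
    data.frame(group = group, item = item, successes = x, trials = n_row,
               point = ci$point, lower = ci$lower, upper = ci$upper,
               percent = round_half_up(100 * ci$point),
               ci_low_pct = round_half_up(100 * ci$lower),
               ci_high_pct = round_half_up(100 * ci$upper),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (cat in categories)
    rows[[length(rows) + 1]] <-
      row_for("overall", cat, sum(verdicts$category == cat), n)

  if (grouping == "by_author_involvement") {
    stopifnot("author_involved" %in% names(verdicts))
    for (cat in categories) {
      for (inv in c(TRUE, FALSE)) {
        lab <- if (inv) "author_involved" else "author_not_involved"
        x <- sum(verdicts$category == cat & verdicts$author_involved == inv)
        rows[[length(rows) + 1]] <- row_for(lab, cat, x, n)
      }
    }
  }

  rows[[length(rows) + 1]] <-
    row_for("overall", "meaningful_difference",
            sum(verdicts$meaningful %in% TRUE), n)
  with_p <- !is.na(verdicts$p_concordant)
  if (any(with_p))
    rows[[length(rows) + 1]] <-
      row_for("overall", "p_discordant",
              sum(!verdicts$p_concordant[with_p]), sum(with_p))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
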