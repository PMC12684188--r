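#' Partially reported meta-analysis method details
#'
#' Captures what a review actually reported about its methods; every field
#' may be missing. Unrecognised free-text values (e.g. a software name the
#' rule table does not know) are preserved verbatim so the provenance log
#' can show them.
#'
#' @param software,package_or_command Free text as reported (e.g. `"R"`,
#'   `"meta"`, `"Stata"`, `"metan"`).
#' @param model `"fixed"`, `"random"`, or `NA`.
#' @param pooling `"inverse_variance"`, `"mantel_haenszel"`, or `NA`.
#' @param tau2_estimator `"DL"`, `"REML"`, `"PM"`, or `NA`.
#' @param ci_method `"wald_z"`, `"hartung_knapp"`, or `NA`.
#' @param continuity `"add_half"`, `"none"`, or `NA`.
#' @param level Confidence level, or `NA`.
#' @return An object of class `reported_methods`.
#' @export
reported_methods <- function(software = NA, package_or_command = NA,
                             model = NA, pooling = NA, tau2_estimator = NA,
                             ci_method = NA, continuity = NA, level = NA) {
  structure(list(software = software,
                 package_or_command = package_or_command,
                 model = model, pooling = pooling,
                 tau2_estimator = tau2_estimator, ci_method = ci_method,
                 continuity = continuity, level = level),
            class = "reported_methods")
}

## Fields of meta_config that resolution must fill.
.config_fields <- c("model", "pooling", "tau2_estimator", "ci_method",
                    "continuity", "level")

#' The shipped default method-resolution rule table
#'
#' An ordered list of rules applied top to bottom; the first rule whose
#' `when` conditions all hold (a field equals a value, case-insensitively,
#' or is `"missing"`) fills the fields in its `set` list — but never a field
#' the review itself reported. The table ends in a universal fallback, so
#' resolution is total. The shipped table encodes common software defaults
#' (RevMan and Stata's `metan` imply DerSimonian-Laird; R's `meta` implies
#' REML) and falls back to a random-effects inverse-variance REML analysis
#' when nothing is reported, matching the most common configuration of the
#' default reproduction software. Edit a copy (see
#' [read_rule_table()]) to change any of this without touching code.
#'
#' @return A list of rules of class `rule_table`.
#' @export
default_rule_table <- function() {
  rules <- list(
    list(id = "mh_implies_fixed",
         when = list(pooling = "mantel_haenszel"),
         set = list(model = "fixed", tau2_estimator = "none")),
    list(id = "fixed_implies_no_tau2",
         when = list(model = "fixed"),
         set = list(tau2_estimator = "none")),
    list(id = "revman_defaults",
         when = list(software = "revman"),
         set = list(tau2_estimator = "DL", ci_method = "wald_z")),
    list(id = "stata_metan_defaults",
         when = list(package_or_command = "metan"),
         set = list(tau2_estimator = "DL", ci_method = "wald_z")),
    list(id = "r_meta_defaults",
         when = list(software = "r"),
         set = list(tau2_estimator = "REML")),
    list(id = "fallback",
         when = list(),
         set = list(model = "random", pooling = "inverse_variance",
                    tau2_estimator = "REML", ci_method = "wald_z",
                    continuity = "add_half", level = 0.95))
  )
  structure(rules, class = "rule_table")
}

#' Read a method-resolution rule table from YAML
#'
#' The file holds a top-level `rules:` list; each entry has an `id`, an
#' optional `when:` mapping of reported-field conditions (value to match
#' case-insensitively, or the string `missing`), and a `set:` mapping of
#' configuration fields to fill. Rules apply in file order and must end in a
#' rule with an empty `when` (the universal fallback). A commented example
#' ships in `inst/extdata/default_rules.yaml`.
#'
#' @param path Path to the YAML file.
#' @return A `rule_table`.
#' @export
read_rule_table <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$rules) || length(doc$rules) == 0)
    stop("rule table is empty", call. = FALSE)
  rules <- lapply(doc$rules, function(r) {
    list(id = r$id %||% "unnamed",
         when = as.list(r$when %||% list()),
         set = as.list(r$set %||% list()))
  })
  if (length(rules[[length(rules)]]$when) != 0)
    stop("rule table must end in a universal fallback (empty 'when')",
         call. = FALSE)
  structure(rules, class = "rule_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_missing_field <- function(x) is.null(x) || length(x) == 0 || all(is.na(x))

.rule_matches <- function(rule, reported) {
  conds <- rule$when
  if (length(conds) == 0) return(TRUE)
  all(vapply(names(conds), function(f) {
    val <- reported[[f]]
    want <- conds[[f]]
    if (identical(want, "missing")) return(.is_missing_field(val))
    if (.is_missing_field(val)) return(FALSE)
    tolower(as.character(val)) == tolower(as.character(want))
  }, logical(1)))
}

#' Resolve a complete method configuration from a partial report
#'
#' Mirrors the selection step of a reproduction workflow: every
#' configuration field is taken from the review's report when available,
#' and otherwise filled by the first applicable rule of an ordered,
#' auditable rule table. The provenance of every field (`"reported"` or the
#' id of the rule that filled it) is returned alongside the configuration.
#'
#' Reported fields are never overridden; a report that is internally
#' contradictory (Mantel-Haenszel pooling with a random-effects model or a
#' continuous measure) is rejected with an error naming the clash.
#'
#' @param reported A [reported_methods()].
#' @param rules A rule table, by default [default_rule_table()].
#' @param measure Optional effect measure of the review, used to detect
#'   method/measure clashes.
#' @return A list with `config` (a [meta_config()]) and `provenance` (a
#'   named character vector over the configuration fields).
#' @examples
#' resolve_methods(reported_methods(model = "random"))
#' @export
resolve_methods <- function(reported, rules = default_rule_table(),
                            measure = NULL) {
  stopifnot(inherits(reported, "reported_methods"))
  if (!.is_missing_field(reported$pooling) &&
      reported$pooling == "mantel_haenszel") {
    if (!.is_missing_field(reported$model) && reported$model == "random")
      stop("inconsistent methods: Mantel-Haenszel pooling reported together ",
           "with a random-effects model", call. = FALSE)
    if (!is.null(measure) && !measure %in% c("logOR", "logRR"))
      stop("inconsistent methods: Mantel-Haenszel pooling reported for the ",
           "non-binary measure ", measure, call. = FALSE)
  }

  fields <- stats::setNames(vector("list", length(.config_fields)),
                            .config_fields)
  provenance <- stats::setNames(rep(NA_character_, length(.config_fields)),
                                .config_fields)
  for (f in .config_fields) {
    if (!.is_missing_field(reported[[f]])) {
      fields[[f]] <- reported[[f]]
      provenance[f] <- "reported"
    }
  }
  for (rule in rules) {
    if (!.rule_matches(rule, reported)) next
    for (f in names(rule$set)) {
      if (!f %in% .config_fields) next
      if (is.null(fields[[f]])) {
        fields[[f]] <- rule$set[[f]]
        provenance[f] <- rule$id
      }
    }
  }
  unfilled <- vapply(fields, is.null, logical(1))
  if (any(unfilled))
    stop("rule table left fields unresolved: ",
         paste(names(fields)[unfilled], collapse = ", "), call. = FALSE)

  cfg <- meta_config(model = fields$model, pooling = fields$pooling,
                     tau2_estimator = fields$tau2_estimator,
                     ci_method = fields$ci_method,
                     continuity = fields$continuity,
                     level = as.numeric(fields$level))
  list(config = cfg, provenance = provenance)
}
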