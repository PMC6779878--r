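# Case ascertainment: extreme hypouricemia without secondary causes.

#' Selection criteria for extreme-hypouricemia cases
#'
#' The threshold comparison is STRICT (`serum_ua < ua_threshold`): a subject
#' at exactly 1.3 mg/dL is not hypouricemic. Boundary subjects flip category
#' on this choice, so it is fixed rather than configurable by comparison
#' operator.
#'
#' @param ua_threshold Case threshold in mg/dL (default 1.3, the extreme-
#'   hypouricemia definition).
#' @param excluded_flags Flags disqualifying a hypouricemic subject from
#'   case status (default: all of [exclusion_flag_levels()]).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(ua_threshold = 1.3,
                               excluded_flags = exclusion_flag_levels()) {
  if (!is.numeric(ua_threshold) || ua_threshold <= 0)
    stopf("ua_threshold must be > 0")
  bad <- setdiff(excluded_flags, exclusion_flag_levels())
  if (length(bad)) stopf("unknown exclusion flag: %s", paste(bad, collapse = ", "))
  structure(list(ua_threshold = ua_threshold, excluded_flags = excluded_flags),
            class = "selection_criteria")
}

#' Select hypouricemia cases from a screening frame
#'
#' Counts every subject with serum urate strictly below the threshold, then
#' restricts to subjects free of the disqualifying flags. Both outputs are
#' deterministic and ordered by `individual_id`. The total and the case set
#' are reported separately because a screening frame typically contains
#' many hypouricemic subjects with secondary causes that are never
#' genetically tested.
#'
#' @param individuals Individuals data.frame or an `rhuc_cohort`.
#' @param criteria A [selection_criteria()].
#' @return List: `cases` (individuals data.frame), `n_hypouricemic_total`
#'   (integer), `n_screened` (integer).
#' @export
select_cases <- function(individuals, criteria = selection_criteria()) {
  if (inherits(individuals, "rhuc_cohort")) individuals <- individuals$individuals
  validate_individuals(individuals)
  hypo <- individuals$serum_ua < criteria$ua_threshold
  keep <- hypo & vapply(individuals$flags, function(f)
    length(intersect(split_flags(f), criteria$excluded_flags)) == 0L, logical(1))
  cases <- individuals[keep, , drop = FALSE]
  cases <- cases[order(cases$individual_id), , drop = FALSE]
  rownames(cases) <- NULL
  list(cases = cases, n_hypouricemic_total = sum(hypo),
       n_screened = nrow(individuals))
}

#' Prevalence of hypouricemia in a screening frame
#'
#' @param n_hypouricemic_total Hypouricemic count.
#' @param n_screened Frame size (> 0).
#' @return List: `proportion` (exact ratio) and `percent` (string rounded
#'   to 3 decimal places of percent, e.g. `"0.083%"`).
#' @export
prevalence <- function(n_hypouricemic_total, n_screened) {
  if (n_screened <= 0) stopf("n_screened must be > 0")
  if (n_hypouricemic_total < 0 || n_hypouricemic_total > n_screened)
    stopf("need 0 <= n_hypouricemic_total <= n_screened")
  list(proportion = n_hypouricemic_total / n_screened,
       percent = percent_string(n_hypouricemic_total, n_screened, digits = 3))
}
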