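#' Next-visit BCVA outcome distribution for an adjudication subset
#'
#' For the visits falling in a set of adjudication categories, looks up the
#' BCVA change to the following visit of the same eye (next chronological
#' visit, whatever the interval) and reports the outcome category
#' proportions per [bcva_delta_categories()]: stable (+/-5 letters),
#' deterioration (< -5), improvement (> +5), gain of >= 15 and loss of
#' > 15 letters. Visits without a defined follow-up BCVA are excluded from
#' the denominator and counted. Stable, deterioration and improvement
#' partition the effective denominator; the 15-letter flags overlap them.
#'
#' @param cohort a visit data frame or [validate_cohort()] result.
#' @param adjudication an [adjudicate_cohort()] result (or its `results`).
#' @param categories character vector of adjudication categories defining
#'   the subset, e.g. `c("UNDERTREAT_UNCLEAR", "UNDERTREAT_FALSE_NEGATIVE")`.
#' @param stratum `"combined"`, `"DME"` or `"RVO"`.
#' @return list: `subset`, `n_visits` (in subset), `n_no_followup`,
#'   rate records `stable`, `deterioration`, `improvement`, `gain15`,
#'   `loss15`, and `mean_interval_days` to the following visit.
#' @export
outcome_distribution <- function(cohort, adjudication, categories,
                                 stratum = c("combined", "DME", "RVO")) {
  stopifnot(length(categories) > 0)
  stratum <- match.arg(stratum)
  if (inherits(adjudication, "adjudication")) {
    adjudication <- adjudication$results
  }
  df <- as_cohort_df(cohort)
  delta <- next_visit_delta(df)
  grp <- paste(df$patient_id, df$eye, sep = "\r")
  interval <- c(as.numeric(diff(df$visit_date)), NA)
  interval[grp != c(grp[-1], "")] <- NA

  key <- paste(df$patient_id, df$eye, df$visit_index, sep = "\r")
  sel <- adjudication[adjudication$category %in% categories, , drop = FALSE]
  if (stratum != "combined") {
    sel <- sel[sel$diagnosis == stratum, , drop = FALSE]
  }
  idx <- match(paste(sel$patient_id, sel$eye, sel$visit_index, sep = "\r"),
               key)
  idx <- idx[!is.na(idx)]
  d <- delta[idx]
  ok <- !is.na(d)
  cats <- bcva_delta_categories(d[ok])
  n <- sum(ok)
  list(
    subset = categories,
    stratum = stratum,
    n_visits = length(idx),
    n_no_followup = sum(!ok),
    stable = rate_record(sum(cats$stable), n),
    deterioration = rate_record(sum(cats$deterioration), n),
    improvement = rate_record(sum(cats$improvement), n),
    gain15 = rate_record(sum(cats$gain15), n),
    loss15 = rate_record(sum(cats$loss15), n),
    mean_interval_days = if (n) mean(interval[idx][ok], na.rm = TRUE)
                         else NA_real_
  )
}
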