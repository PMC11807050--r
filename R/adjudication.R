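#' Treatment-adequacy categories
#'
#' The per-visit categories of the retrospective treatment-adequacy
#' adjudication. Visits with RC-confirmed foveal disease activity fall into
#' the first five; visits without it into the last five. Undertreatment is
#' `UNDERTREAT_UNCLEAR` + `UNDERTREAT_FALSE_NEGATIVE`; suspected
#' overtreatment is `OVERTREAT_FALSE_POSITIVE` + `OVERTREAT_UNCLEAR`.
#'
#' @format Character vector of the ten category codes.
#' @export
adjudication_categories <- c(
  "TREATED_ACTIVE", "WW_JUSTIFIED_STABLE", "WW_JUSTIFIED_DOCUMENTED",
  "UNDERTREAT_FALSE_NEGATIVE", "UNDERTREAT_UNCLEAR",
  "UNTREATED_INACTIVE", "TREAT_JUSTIFIED_VA_DECLINE",
  "TREAT_JUSTIFIED_SERIES", "OVERTREAT_FALSE_POSITIVE", "OVERTREAT_UNCLEAR"
)

undertreat_categories <- c("UNDERTREAT_UNCLEAR", "UNDERTREAT_FALSE_NEGATIVE")
overtreat_categories <- c("OVERTREAT_FALSE_POSITIVE", "OVERTREAT_UNCLEAR")

# series flag: recorded value when present, else derived (previous visit of
# the eye injected and within crit gap days)
resolve_in_series <- function(df_eye, index, gap_days = 42) {
  flag <- df_eye$injection_in_series[index]
  if (!is.na(flag)) return(flag)
  if (index == 1) return(FALSE)
  prev_inj <- df_eye$injection_given[index - 1]
  gap <- as.numeric(df_eye$visit_date[index] - df_eye$visit_date[index - 1])
  isTRUE(prev_inj) && !is.na(gap) && gap <= gap_days
}

#' Adjudicate one visit
#'
#' Walks the treatment-adequacy decision tree for the visit at `index` of
#' one eye's ordered visit sequence. With RC-confirmed foveal activity:
#' an injection makes the visit `TREATED_ACTIVE`; otherwise stability of
#' BCVA or thickness over the prior-visit window justifies watch-and-wait
#' (`WW_JUSTIFIED_STABLE`); otherwise a documented no-treatment reason,
#' non-assessable stability, or missing treatment information is classified
#' as justified (`WW_JUSTIFIED_DOCUMENTED` — the conservative rule that
#' avoids over-estimating undertreatment); otherwise the visit counts as
#' possible undertreatment, split by whether the physician missed the fluid
#' (`UNDERTREAT_FALSE_NEGATIVE`, carrying whether the RC flagged the missed
#' fluid as strongly visible) or saw it (`UNDERTREAT_UNCLEAR`). Without
#' RC-confirmed activity: no injection is `UNTREATED_INACTIVE`; an
#' injection is justified by a BCVA decline against the previous visit or
#' by being part of an injection series; otherwise it is suspected
#' overtreatment, split by whether the physician reported foveal fluid the
#' RC did not see (`OVERTREAT_FALSE_POSITIVE`) or not (`OVERTREAT_UNCLEAR`).
#'
#' @param df_eye visit data frame of a single (patient, eye), in visit
#'   order.
#' @param index 1-based row position of the visit to adjudicate.
#' @param crit a [stability_criteria()].
#' @param series_gap_days gap used when deriving the series flag (42).
#' @return list: `category`, `rc_fluid`, `stability_basis`,
#'   `strongly_visible_missed` (`NA` unless `UNDERTREAT_FALSE_NEGATIVE`),
#'   or `NULL` when the visit is non-adjudicable (no RC grading).
#' @export
adjudicate_visit <- function(df_eye, index, crit = stability_criteria(),
                             series_gap_days = 42) {
  rc_active <- foveal_activity(df_eye, "rc")[index]
  if (is.na(rc_active)) return(NULL)
  phys_active <- foveal_activity(df_eye, "phys")[index]
  inj <- df_eye$injection_given[index]
  reason <- df_eye$documented_reason[index]
  res <- list(
    category = NA_character_,
    rc_fluid = rc_active,
    stability_basis = "none",
    strongly_visible_missed = NA
  )

  if (rc_active) {
    if (isTRUE(inj)) {
      res$category <- "TREATED_ACTIVE"
      return(res)
    }
    st <- is_stable(df_eye$bcva_letters, df_eye$phys_csrt_um, index, crit)
    res$stability_basis <- st$basis
    if (isTRUE(st$stable)) {
      res$category <- "WW_JUSTIFIED_STABLE"
    } else if ((!is.na(reason) && reason %in% reason_levels) ||
               is.na(st$stable) || is.na(inj) || is.na(reason)) {
      # documented reason, non-assessable stability, or missing treatment
      # information: classified as justified to avoid over-estimating
      # undertreatment
      res$category <- "WW_JUSTIFIED_DOCUMENTED"
    } else if (identical(phys_active, FALSE)) {
      res$category <- "UNDERTREAT_FALSE_NEGATIVE"
      res$strongly_visible_missed <-
        isTRUE(df_eye$rc_irf_strong[index]) ||
        isTRUE(df_eye$rc_srf_strong[index])
    } else {
      res$category <- "UNDERTREAT_UNCLEAR"
    }
  } else {
    if (!isTRUE(inj)) {
      res$category <- "UNTREATED_INACTIVE"
      return(res)
    }
    d_prev <- if (index > 1) {
      df_eye$bcva_letters[index] - df_eye$bcva_letters[index - 1]
    } else {
      NA_integer_
    }
    if (!is.na(d_prev) && d_prev < -crit$va_decline_letters) {
      res$category <- "TREAT_JUSTIFIED_VA_DECLINE"
    } else if (resolve_in_series(df_eye, index, series_gap_days)) {
      res$category <- "TREAT_JUSTIFIED_SERIES"
    } else if (isTRUE(phys_active)) {
      res$category <- "OVERTREAT_FALSE_POSITIVE"
    } else {
      res$category <- "OVERTREAT_UNCLEAR"
    }
  }
  res
}

#' Adjudicate every visit of a cohort
#'
#' Applies [adjudicate_visit()] along each eye's visit sequence and tallies
#' categories per diagnosis stratum. Visits without an RC grading are
#' non-adjudicable and reported in `excluded`. The per-stratum summary is a
#' partition: category counts sum exactly to the number of adjudicable
#' visits on each side of the RC fluid split.
#'
#' @param cohort a visit data frame or [validate_cohort()] result.
#' @param crit a [stability_criteria()].
#' @param series_gap_days see [adjudicate_visit()].
#' @return list of class `"adjudication"`: `results` (one row per
#'   adjudicated visit), `excluded` (visit keys + reason), `summary`
#'   (named list of per-stratum count lists, see
#'   [summarize_adjudication()]), `criteria`.
#' @export
adjudicate_cohort <- function(cohort, crit = stability_criteria(),
                              series_gap_days = 42) {
  df <- as_cohort_df(cohort)
  grp <- paste(df$patient_id, df$eye, sep = "\r")
  rows <- vector("list", nrow(df))
  excl <- vector("list", nrow(df))
  for (g in split(seq_len(nrow(df)), factor(grp, unique(grp)))) {
    df_eye <- df[g, , drop = FALSE]
    for (i in seq_along(g)) {
      res <- adjudicate_visit(df_eye, i, crit, series_gap_days)
      key <- data.frame(
        patient_id = df_eye$patient_id[i], eye = df_eye$eye[i],
        visit_index = df_eye$visit_index[i],
        diagnosis = df_eye$diagnosis[i], stringsAsFactors = FALSE
      )
      if (is.null(res)) {
        excl[[g[i]]] <- cbind(key, reason = "rc_grading_missing")
      } else {
        rows[[g[i]]] <- cbind(key, data.frame(
          category = res$category, rc_fluid = res$rc_fluid,
          stability_basis = res$stability_basis,
          strongly_visible_missed = res$strongly_visible_missed,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  excluded <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(
      patient_id = character(), eye = character(), visit_index = integer(),
      diagnosis = character(), category = character(), rc_fluid = logical(),
      stability_basis = character(), strongly_visible_missed = logical(),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(excluded)) {
    excluded <- data.frame(
      patient_id = character(), eye = character(), visit_index = integer(),
      diagnosis = character(), reason = character(), stringsAsFactors = FALSE
    )
  }
  rownames(results) <- NULL
  rownames(excluded) <- NULL
  structure(
    list(
      results = results,
      excluded = excluded,
      summary = list(
        combined = summarize_adjudication(results),
        DME = summarize_adjudication(results[results$diagnosis == "DME", ]),
        RVO = summarize_adjudication(results[results$diagnosis == "RVO", ])
      ),
      criteria = crit
    ),
    class = "adjudication"
  )
}

#' Count adjudication categories
#'
#' Tallies per-visit adjudication results into the count structure of the
#' published treatment-decision tree: on the RC-fluid side treated /
#' justified watch-and-wait (stable, documented) / possible undertreatment
#' (unclear, false negative, and how many missed fluids were strongly
#' visible); on the no-fluid side untreated / justified injection (VA
#' decline, series) / suspected overtreatment (false positive, unclear).
#'
#' @param results the `results` data frame of an [adjudicate_cohort()].
#' @return named list of integer counts.
#' @export
summarize_adjudication <- function(results) {
  cnt <- function(cats) sum(results$category %in% cats)
  list(
    adjudicated = nrow(results),
    rc_fluid_total = sum(results$rc_fluid),
    treated_active = cnt("TREATED_ACTIVE"),
    ww_justified_total = cnt(c("WW_JUSTIFIED_STABLE",
                               "WW_JUSTIFIED_DOCUMENTED")),
    ww_justified_stable = cnt("WW_JUSTIFIED_STABLE"),
    ww_justified_documented = cnt("WW_JUSTIFIED_DOCUMENTED"),
    undertreat_total = cnt(undertreat_categories),
    undertreat_unclear = cnt("UNDERTREAT_UNCLEAR"),
    undertreat_false_negative = cnt("UNDERTREAT_FALSE_NEGATIVE"),
    undertreat_strongly_visible = sum(
      results$category == "UNDERTREAT_FALSE_NEGATIVE" &
        results$strongly_visible_missed %in% TRUE
    ),
    no_fluid_total = sum(!results$rc_fluid),
    untreated_inactive = cnt("UNTREATED_INACTIVE"),
    injected_no_fluid = cnt(c("TREAT_JUSTIFIED_VA_DECLINE",
                              "TREAT_JUSTIFIED_SERIES",
                              overtreat_categories)),
    treat_justified_total = cnt(c("TREAT_JUSTIFIED_VA_DECLINE",
                                  "TREAT_JUSTIFIED_SERIES")),
    treat_justified_va_decline = cnt("TREAT_JUSTIFIED_VA_DECLINE"),
    treat_justified_series = cnt("TREAT_JUSTIFIED_SERIES"),
    overtreat_total = cnt(overtreat_categories),
    overtreat_false_positive = cnt("OVERTREAT_FALSE_POSITIVE"),
    overtreat_unclear = cnt("OVERTREAT_UNCLEAR")
  )
}

#' Per-patient rollup of adjudication flags
#'
#' Flags each patient as possibly undertreated (any visit, any eye, in an
#' undertreatment category) and possibly overtreated (any visit in an
#' overtreatment category), with counts and proportions per diagnosis and
#' combined.
#'
#' @param results the `results` data frame of an [adjudicate_cohort()], or
#'   the `"adjudication"` object itself.
#' @return list: `patients` (one row per patient: diagnosis, flags,
#'   visit counts) and `summary` (per-stratum rate records for
#'   `undertreated_ever` / `overtreated_ever`).
#' @export
patient_rollup <- function(results) {
  if (inherits(results, "adjudication")) results <- results$results
  by_pat <- split(results, results$patient_id)
  patients <- do.call(rbind, lapply(by_pat, function(d) {
    data.frame(
      patient_id = d$patient_id[1],
      diagnosis = d$diagnosis[1],
      n_visits_adjudicated = nrow(d),
      undertreated_ever = any(d$category %in% undertreat_categories),
      overtreated_ever = any(d$category %in% overtreat_categories),
      stringsAsFactors = FALSE
    )
  }))
  rownames(patients) <- NULL
  strat <- function(d) {
    list(
      n_patients = nrow(d),
      undertreated_ever = rate_record(sum(d$undertreated_ever), nrow(d)),
      overtreated_ever = rate_record(sum(d$overtreated_ever), nrow(d))
    )
  }
  list(
    patients = patients,
    summary = list(
      combined = strat(patients),
      DME = strat(patients[patients$diagnosis == "DME", ]),
      RVO = strat(patients[patients$diagnosis == "RVO", ])
    )
  )
}
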