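#' Stability criteria for the watch-and-wait justification
#'
#' The retrospective adjudication accepts a no-treatment decision when BCVA
#' or retinal thickness were stable over three prior visits. `is_stable()`
#' implements that as a window of `n_prior_visits` visits ending at (and by
#' default including) the decision visit: stable when the BCVA range within
#' the window is at most `bcva_window_letters` OR the physician CSRT range
#' is at most `csrt_window_um`. The +/-5-letter width is the study's own
#' stable-vision convention; the 25 um thickness window is a configurable
#' choice near published OCT test-retest variability (the source cohort
#' never states a numeric criterion).
#'
#' @param bcva_window_letters maximum BCVA range (ETDRS letters, default 5).
#' @param csrt_window_um maximum physician CSRT range (micrometres, 25).
#' @param n_prior_visits window length in visits (default 3).
#' @param include_index if `TRUE` (default) the window is the decision visit
#'   plus the `n_prior_visits - 1` visits before it; if `FALSE`, the
#'   `n_prior_visits` visits strictly before the decision visit.
#' @param va_decline_letters BCVA drop vs the previous visit (letters) that
#'   justifies an injection without RC-confirmed fluid (default 5, i.e.
#'   decline means delta < -5).
#' @return list of class `"stability_criteria"`.
#' @export
stability_criteria <- function(bcva_window_letters = 5,
                               csrt_window_um = 25,
                               n_prior_visits = 3,
                               include_index = TRUE,
                               va_decline_letters = 5) {
  stopifnot(bcva_window_letters > 0, csrt_window_um > 0, n_prior_visits > 0,
            va_decline_letters > 0)
  structure(
    list(
      bcva_window_letters = bcva_window_letters,
      csrt_window_um = csrt_window_um,
      n_prior_visits = as.integer(n_prior_visits),
      include_index = isTRUE(include_index),
      va_decline_letters = va_decline_letters
    ),
    class = "stability_criteria"
  )
}

#' Stability of an eye at a visit
#'
#' Applies [stability_criteria()] to one position in an ordered per-eye
#' visit sequence. A criterion with any missing value inside the window is
#' non-assessable by that basis (never counted as stable); if the window
#' does not fit (too few visits), the result is non-assessable altogether
#' (`stable = NA`), which the adjudication's conservative rule maps to a
#' justified watch-and-wait.
#'
#' @param bcva numeric vector of BCVA (letters) for the eye, visit order.
#' @param csrt numeric vector of physician CSRT (um), same order.
#' @param index 1-based visit position to assess.
#' @param crit a [stability_criteria()].
#' @return list: `stable` (`TRUE`/`FALSE`/`NA`), `basis` (`"bcva"`,
#'   `"thickness"`, `"both"`, `"none"`).
#' @export
is_stable <- function(bcva, csrt, index, crit = stability_criteria()) {
  n <- length(bcva)
  stopifnot(length(csrt) == n)
  if (index < 1 || index > n) stop("index out of range")
  last <- if (crit$include_index) index else index - 1
  first <- last - crit$n_prior_visits + 1
  if (first < 1 || last < 1) {
    return(list(stable = NA, basis = "none"))
  }
  win_ok <- function(x, width) {
    w <- x[first:last]
    if (anyNA(w)) return(NA)
    diff(range(w)) <= width
  }
  b <- win_ok(bcva, crit$bcva_window_letters)
  t <- win_ok(csrt, crit$csrt_window_um)
  stable_b <- isTRUE(b)
  stable_t <- isTRUE(t)
  if (stable_b && stable_t) {
    list(stable = TRUE, basis = "both")
  } else if (stable_b) {
    list(stable = TRUE, basis = "bcva")
  } else if (stable_t) {
    list(stable = TRUE, basis = "thickness")
  } else if (is.na(b) && is.na(t)) {
    list(stable = NA, basis = "none")
  } else {
    list(stable = FALSE, basis = "none")
  }
}

#' BCVA change to the following visit
#'
#' Letter change delta = next visit's BCVA minus the current one, with the
#' outcome categories used throughout: `stable` iff |delta| <= 5 letters;
#' `deterioration` iff delta < -5; `gain15` iff delta >= +15 (inclusive);
#' `loss15` iff delta < -15 (strict). The flags overlap by design (loss15
#' implies deterioration).
#'
#' @param delta numeric vector of letter changes (may contain `NA` for
#'   visits without a follow-up BCVA).
#' @return data frame with columns `delta`, `stable`, `deterioration`,
#'   `improvement` (delta > +5), `gain15`, `loss15`.
#' @export
bcva_delta_categories <- function(delta) {
  data.frame(
    delta = delta,
    stable = !is.na(delta) & abs(delta) <= 5,
    deterioration = !is.na(delta) & delta < -5,
    improvement = !is.na(delta) & delta > 5,
    gain15 = !is.na(delta) & delta >= 15,
    loss15 = !is.na(delta) & delta < -15
  )
}

# next-visit BCVA delta per row of an ordered cohort (NA on each eye's
# last visit and wherever either BCVA is missing)
next_visit_delta <- function(df) {
  grp <- paste(df$patient_id, df$eye, sep = "\r")
  nxt <- c(df$bcva_letters[-1], NA)
  nxt[grp != c(grp[-1], "")] <- NA
  nxt - df$bcva_letters
}

# previous-visit BCVA delta (current minus previous), NA on first visits
prev_visit_delta <- function(df) {
  grp <- paste(df$patient_id, df$eye, sep = "\r")
  prv <- c(NA, df$bcva_letters[-nrow(df)])
  prv[grp != c("", grp[-length(grp)])] <- NA
  df$bcva_letters - prv
}

#' Fluid-change concordance between physician and RC
#'
#' 3x3 cross-tab of the reported change in foveal IRF/SRF since the previous
#' visit (increased / stable / decreased; physician rows, RC columns), over
#' visits where both raters reported an applicable change, plus the
#' agreement proportion conditional on each physician category (the
#' convention of the published change comparison).
#'
#' @inheritParams foveal_fluid_crosstab
#' @return list: `crosstab` (3x3 [crosstab()]), `agreement_by_phys_category`
#'   (named list of rate records), `overall_agreement`.
#' @export
change_concordance <- function(cohort,
                               stratum = c("combined", "DME", "RVO")) {
  stratum <- match.arg(stratum)
  df <- as_cohort_df(cohort)
  if (stratum != "combined") df <- df[df$diagnosis == stratum, , drop = FALSE]
  lv <- c("increased", "stable", "decreased")
  keep <- df$phys_change %in% lv & df$rc_change %in% lv
  pf <- factor(df$phys_change[keep], levels = lv)
  rf <- factor(df$rc_change[keep], levels = lv)
  ct <- crosstab(unclass(table(physician = pf, rc = rf)))
  m <- ct$counts
  by_cat <- lapply(seq_along(lv), function(i) rate_record(m[i, i], sum(m[i, ])))
  names(by_cat) <- lv
  list(
    crosstab = ct,
    agreement_by_phys_category = by_cat,
    overall_agreement = rate_record(sum(diag(m)), ct$n)
  )
}
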