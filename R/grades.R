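#' Grading vocabulary
#'
#' The grading questionnaire offers four options for the presence of an OCT
#' parameter: `"yes"`, `"no"`, `"questionable"` and `"cannot_grade"`. A fifth
#' state, missingness (`NA`), means the rater supplied no evaluation for the
#' scan at all; it is deliberately distinct from `"cannot_grade"` (an
#' evaluation that failed) because the two enter denominators differently.
#'
#' @format Character vector of the four recordable grade values.
#' @export
grade_levels <- c("yes", "no", "questionable", "cannot_grade")

#' Harmonize a tri-state grading to binary presence
#'
#' Collapses the questionnaire's four grade options to a binary presence
#' call: `"yes"` maps to `TRUE`; `"no"`, `"questionable"` and
#' `"cannot_grade"` all map to `FALSE`, because no definite presence was
#' confirmed. Missing evaluations (`NA`) are an error by default: a rater
#' who never graded the scan must be excluded upstream, never silently
#' counted as "absent".
#'
#' @param g character vector of grade values (see [grade_levels]).
#' @param na_ok if `TRUE`, `NA` input yields `NA` output instead of an
#'   error. Use only where the caller accounts for missingness explicitly.
#' @return logical vector: `TRUE` = present, `FALSE` = absent.
#' @export
#' @examples
#' harmonize_grade(c("yes", "questionable", "cannot_grade", "no"))
harmonize_grade <- function(g, na_ok = FALSE) {
  bad <- !is.na(g) & !g %in% grade_levels
  if (any(bad)) {
    stop("invalid grade value(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  if (!na_ok && anyNA(g)) {
    stop("missing grading (NA) cannot be harmonized; exclude it upstream")
  }
  out <- g == "yes"
  out[is.na(g)] <- NA
  out
}

# OR over harmonized components, vectorized over visits. A component that is
# NA counts as absent unless *all* components are NA, in which case the
# composite itself is NA (no evaluation at all).
or_harmonized <- function(...) {
  comps <- lapply(list(...), harmonize_grade, na_ok = TRUE)
  m <- do.call(cbind, comps)
  any_yes <- rowSums(m, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  ifelse(all_na, NA, any_yes)
}

#' Foveal fluid composite (IRF and/or SRF with foveal involvement)
#'
#' The binary composite used for the physician-vs-RC consensus
#' cross-tabulation: harmonized foveal IRF OR harmonized foveal SRF.
#' Diffuse foveal thickening is *not* part of this composite (the consensus
#' table concerns fluid with foveal involvement); it enters only the full
#' disease-activity definition, [foveal_activity()].
#'
#' @param cohort a visit data frame (see [cohort_columns()]).
#' @param rater `"phys"` or `"rc"`: whose grading to use.
#' @return logical vector, one element per visit; `NA` when the rater
#'   supplied no foveal-fluid evaluation for the visit.
#' @seealso [foveal_activity()]
#' @export
foveal_fluid <- function(cohort, rater = c("phys", "rc")) {
  rater <- match.arg(rater)
  or_harmonized(
    cohort[[paste0(rater, "_irf_foveal")]],
    cohort[[paste0(rater, "_srf_foveal")]]
  )
}

#' OCT disease activity at the fovea
#'
#' A scan shows OCT signs of disease activity when it has intraretinal
#' and/or subretinal fluid with foveal involvement and/or diffuse foveal
#' thickening, after harmonizing each tri-state grading with
#' [harmonize_grade()]. This is the activity definition the
#' treatment-adequacy adjudication is built on.
#'
#' @inheritParams foveal_fluid
#' @return logical vector, `NA` when the rater graded none of the three
#'   components.
#' @export
foveal_activity <- function(cohort, rater = c("phys", "rc")) {
  rater <- match.arg(rater)
  or_harmonized(
    cohort[[paste0(rater, "_irf_foveal")]],
    cohort[[paste0(rater, "_srf_foveal")]],
    cohort[[paste0(rater, "_diffuse_thickening")]]
  )
}
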