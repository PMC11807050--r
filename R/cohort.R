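#' Visit-table column dictionary
#'
#' A cohort is a plain data frame with one row per (patient, eye, visit) and
#' exactly these columns. Grade columns take `yes`, `no`, `questionable`,
#' `cannot_grade` or `NA` (missing evaluation); change columns take
#' `increased`, `stable`, `decreased`, `not_applicable` or `NA`; boolean
#' columns are logical; thickness is in micrometres; BCVA in ETDRS letters
#' (0-100).
#'
#' @return named character vector mapping column name to storage type.
#' @export
cohort_columns <- function() {
  c(
    patient_id = "character",
    eye = "character",
    visit_index = "integer",
    visit_date = "date",
    diagnosis = "character",
    phys_irf_any = "grade",
    phys_srf_any = "grade",
    phys_irf_foveal = "grade",
    phys_srf_foveal = "grade",
    phys_diffuse_thickening = "grade",
    phys_change = "change",
    phys_csrt_um = "numeric",
    phys_fcpt_um = "numeric",
    phys_segmentation_adequate = "grade",
    phys_grid_corrected = "logical",
    rc_irf_any = "grade",
    rc_srf_any = "grade",
    rc_irf_foveal = "grade",
    rc_srf_foveal = "grade",
    rc_diffuse_thickening = "grade",
    rc_irf_strong = "logical",
    rc_srf_strong = "logical",
    rc_change = "change",
    rc_csrt_um = "numeric",
    rc_fcpt_um = "numeric",
    rc_segmentation_adequate = "grade",
    rc_grid_corrected = "logical",
    bcva_letters = "integer",
    injection_given = "logical",
    injection_in_series = "logical",
    documented_reason = "character"
  )
}

#' Documented reasons for a no-treatment decision
#'
#' Reasons a physician may record for withholding an injection: planned for
#' a later visit, patient lost to follow-up, no further injections
#' requested, therapy change, patient preference, adverse event, or other.
#' `"none"` means the field was filled and no reason given; `NA` means the
#' field is missing.
#'
#' @format Character vector of recordable reason codes (excluding `"none"`).
#' @export
reason_levels <- c(
  "planned_later", "lost_to_followup", "no_further_injections_requested",
  "therapy_change", "patient_preference", "adverse_event", "other"
)

#' Fluid-change categories relative to the previous visit
#' @format Character vector of recordable change codes.
#' @export
change_levels <- c("increased", "stable", "decreased", "not_applicable")

# TRUE where the rater supplied at least one fluid/thickening grading.
has_grading <- function(cohort, rater) {
  cols <- paste0(rater, c(
    "_irf_any", "_srf_any", "_irf_foveal", "_srf_foveal",
    "_diffuse_thickening"
  ))
  rowSums(!is.na(as.matrix(cohort[cols]))) > 0
}

#' Validate a visit-level cohort
#'
#' Checks the cohort against the data-model invariants, reorders visits
#' within each (patient, eye) by visit date (input order breaks ties, for
#' reproducibility) and returns the reordered cohort together with a
#' structured issue list. A duplicate (patient, eye, visit_index) key is
#' fatal. Visits lacking one or both raters' gradings are flagged and
#' retained; agreement statistics later exclude them by construction.
#' Validation is a projection: validating a validated cohort changes
#' nothing.
#'
#' @param cohort a visit data frame with the [cohort_columns()] schema.
#' @return list with class `"validated_cohort"`: `cohort` (reordered data
#'   frame), `issues` (data frame with columns `level`, `rule`, `message`,
#'   `n`).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(names(cohort_columns()), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  issues <- list()
  note <- function(level, rule, message, n) {
    issues[[length(issues) + 1]] <<- data.frame(
      level = level, rule = rule, message = message, n = n,
      stringsAsFactors = FALSE
    )
  }

  if (nrow(cohort)) {
    key <- paste(cohort$patient_id, cohort$eye, cohort$visit_index, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (patient_id, eye, visit_index) visit key")
    }
    ord <- order(cohort$patient_id, cohort$eye, cohort$visit_date,
                 seq_len(nrow(cohort)), method = "radix")
    cohort <- cohort[ord, , drop = FALSE]
    rownames(cohort) <- NULL

    eye_grp <- paste(cohort$patient_id, cohort$eye, sep = "\r")
    idx_ok <- unlist(lapply(
      split(cohort$visit_index, factor(eye_grp, unique(eye_grp))),
      function(v) c(TRUE, diff(v) > 0)
    ), use.names = FALSE)
    if (any(!idx_ok)) {
      note("error", "visit_index_order",
           "visit_index not strictly increasing with visit_date", sum(!idx_ok))
    }

    dx_n <- vapply(split(cohort$diagnosis, cohort$patient_id),
                   function(d) length(unique(d)), integer(1))
    if (any(dx_n > 1)) {
      note("error", "diagnosis_constant",
           "diagnosis varies within a patient", sum(dx_n > 1))
    }

    bad_dx <- !cohort$diagnosis %in% c("DME", "RVO")
    if (any(bad_dx)) {
      note("error", "diagnosis_values",
           "diagnosis outside {DME, RVO}", sum(bad_dx))
    }

    for (meas in c("phys_csrt_um", "phys_fcpt_um", "rc_csrt_um", "rc_fcpt_um")) {
      bad <- !is.na(cohort[[meas]]) &
        (!is.finite(cohort[[meas]]) | cohort[[meas]] <= 0)
      if (any(bad)) {
        note("error", "thickness_positive",
             paste0(meas, " must be finite and > 0"), sum(bad))
      }
    }

    bad_bcva <- !is.na(cohort$bcva_letters) &
      (cohort$bcva_letters < 0 | cohort$bcva_letters > 100)
    if (any(bad_bcva)) {
      note("error", "bcva_range", "bcva_letters outside 0-100", sum(bad_bcva))
    }

    # foveal fluid implies fluid anywhere, per compartment and rater
    for (rater in c("phys", "rc")) {
      for (comp in c("irf", "srf")) {
        fov <- harmonize_grade(cohort[[paste0(rater, "_", comp, "_foveal")]],
                               na_ok = TRUE)
        any_ <- harmonize_grade(cohort[[paste0(rater, "_", comp, "_any")]],
                                na_ok = TRUE)
        bad <- !is.na(fov) & !is.na(any_) & fov & !any_
        if (any(bad)) {
          note("error", "foveal_implies_any",
               paste0(rater, " ", toupper(comp),
                      " foveal presence with compartment graded absent"),
               sum(bad))
        }
      }
    }

    # strong-visibility flags only meaningful on RC-present compartments
    for (comp in c("irf", "srf")) {
      pres <- harmonize_grade(cohort[[paste0("rc_", comp, "_any")]],
                              na_ok = TRUE)
      strong <- cohort[[paste0("rc_", comp, "_strong")]]
      bad <- !is.na(strong) & strong & !(pres %in% TRUE)
      if (any(bad)) {
        note("error", "strong_requires_present",
             paste0("rc_", comp, "_strong set without RC-present ",
                    toupper(comp)), sum(bad))
      }
    }

    bad_reason <- !is.na(cohort$documented_reason) &
      !cohort$documented_reason %in% c(reason_levels, "none")
    if (any(bad_reason)) {
      note("error", "reason_values",
           "documented_reason outside the recordable codes", sum(bad_reason))
    }

    no_phys <- !has_grading(cohort, "phys")
    no_rc <- !has_grading(cohort, "rc")
    if (any(no_phys)) {
      note("info", "physician_grading_missing",
           "visits without any physician fluid grading", sum(no_phys))
    }
    if (any(no_rc)) {
      note("info", "rc_grading_missing",
           "visits without any RC fluid grading", sum(no_rc))
    }
    if (any(no_phys & no_rc)) {
      note("warning", "no_grading_at_all",
           "visits with neither rater's grading (kept; excluded from agreement)",
           sum(no_phys & no_rc))
    }
  }

  issues <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(level = character(), rule = character(),
               message = character(), n = integer(), stringsAsFactors = FALSE)
  }
  structure(list(cohort = cohort, issues = issues),
            class = "validated_cohort")
}

#' @export
print.validated_cohort <- function(x, ...) {
  cat(sprintf("Validated cohort: %d visits, %d patients, %d issue(s)\n",
              nrow(x$cohort), length(unique(x$cohort$patient_id)),
              nrow(x$issues)))
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

# Accept either a raw visit data frame or an already-validated cohort;
# always returns the reordered data frame, stopping on fatal problems.
as_cohort_df <- function(cohort) {
  if (inherits(cohort, "validated_cohort")) {
    return(cohort$cohort)
  }
  validate_cohort(cohort)$cohort
}

#' Read a visit-level cohort CSV
#'
#' Reads the visit CSV dialect (one row per patient-eye-visit, columns per
#' [cohort_columns()]; empty cells are missing values).
#'
#' @param path file path.
#' @return a visit data frame.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(names(cohort_columns()), names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[names(cohort_columns())]
  types <- cohort_columns()
  for (col in names(types)) {
    raw[[col]] <- switch(
      types[[col]],
      character = , grade = , change = raw[[col]],
      integer = as.integer(raw[[col]]),
      numeric = as.numeric(raw[[col]]),
      logical = parse_bool(raw[[col]], col),
      date = as.Date(raw[[col]])
    )
  }
  raw
}

parse_bool <- function(x, col) {
  out <- rep(NA, length(x))
  out[x %in% c("true", "TRUE", "True", "1", "yes")] <- TRUE
  out[x %in% c("false", "FALSE", "False", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("column ", col, ": unparseable boolean value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Write a visit-level cohort CSV
#'
#' Inverse of [read_cohort_csv()]. Logical columns are written as
#' `true`/`false`, dates as ISO-8601, missing values as empty cells. The
#' output is byte-stable: the same cohort always serializes identically.
#'
#' @param cohort a visit data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[names(cohort_columns())]
  for (col in names(out)) {
    v <- out[[col]]
    if (is.logical(v)) {
      v <- ifelse(is.na(v), NA_character_, ifelse(v, "true", "false"))
    } else if (inherits(v, "Date")) {
      v <- format(v, "%Y-%m-%d")
    } else {
      v <- as.character(v)
    }
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   eol = "\n")
  invisible(path)
}
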