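#' Paired-rater count table
#'
#' A small container for physician-by-RC contingency tables. Rows index the
#' physician's categories, columns the RC's; `n` is always the sum of all
#' cells.
#'
#' @param counts integer matrix of non-negative counts with dimnames
#'   (physician categories in rows, RC categories in columns).
#' @return an object of class `"crosstab"`.
#' @export
crosstab <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("crosstab counts must be non-negative integers")
  }
  if (is.null(dimnames(counts))) {
    stop("crosstab counts need dimnames (physician rows, RC columns)")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n = sum(counts)), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("Physician x RC cross-tab (n = %d)\n", x$n))
  print(x$counts)
  invisible(x)
}

# 2x2 crosstab from two logical vectors (TRUE = present), physician rows.
crosstab_from_logical <- function(phys, rc,
                                  levels = c("present", "absent")) {
  keep <- !is.na(phys) & !is.na(rc)
  pf <- factor(ifelse(phys[keep], levels[1], levels[2]), levels = levels)
  rf <- factor(ifelse(rc[keep], levels[1], levels[2]), levels = levels)
  counts <- table(physician = pf, rc = rf)
  crosstab(unclass(counts))
}

#' Physician-vs-RC cross-tab of foveal fluid
#'
#' Tabulates the harmonized foveal fluid composite (IRF and/or SRF with
#' foveal involvement, [foveal_fluid()]) of the physician against the RC,
#' over visits where both raters supplied an evaluation. Physician calls are
#' rows, RC calls columns. Diffuse foveal thickening is not part of this
#' composite; use `composite = "activity"` for the full disease-activity
#' definition.
#'
#' @param cohort a visit data frame or [validate_cohort()] result.
#' @param stratum `"combined"`, `"DME"` or `"RVO"`.
#' @param composite `"fluid"` (foveal IRF/SRF, the consensus-table
#'   definition) or `"activity"` (adds diffuse foveal thickening).
#' @return a [crosstab()] (2x2, present/absent).
#' @export
foveal_fluid_crosstab <- function(cohort,
                                  stratum = c("combined", "DME", "RVO"),
                                  composite = c("fluid", "activity")) {
  stratum <- match.arg(stratum)
  composite <- match.arg(composite)
  df <- as_cohort_df(cohort)
  if (stratum != "combined") df <- df[df$diagnosis == stratum, , drop = FALSE]
  f <- if (composite == "fluid") foveal_fluid else foveal_activity
  crosstab_from_logical(f(df, "phys"), f(df, "rc"))
}

#' Agreement rates from a 2x2 cross-tab
#'
#' Computes the paired-rater agreement summary for a present/absent
#' cross-tab: overall agreement, positive confirmation (physician present
#' given RC present — the physician's sensitivity against the RC reference),
#' negative confirmation (physician absent given RC absent — specificity),
#' and each rater's prevalence. Every rate is returned with its integer
#' numerator and denominator; a zero denominator yields `NA`, never a 0/0
#' coercion.
#'
#' @param ct a 2x2 [crosstab()] with rows/columns ordered (present, absent).
#' @return list of class `"agreement_rates"`; each element is a record with
#'   `numerator`, `denominator`, `proportion`, `percent`.
#' @export
agreement_rates <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  m <- ct$counts
  if (!all(dim(m) == c(2, 2))) {
    stop("agreement_rates needs a 2x2 present/absent cross-tab")
  }
  n <- ct$n
  structure(list(
    overall_agreement = rate_record(m[1, 1] + m[2, 2], n),
    positive_confirmation = rate_record(m[1, 1], m[1, 1] + m[2, 1]),
    negative_confirmation = rate_record(m[2, 2], m[1, 2] + m[2, 2]),
    prevalence_rc = rate_record(m[1, 1] + m[2, 1], n),
    prevalence_phys = rate_record(m[1, 1] + m[1, 2], n)
  ), class = "agreement_rates")
}

#' @export
print.agreement_rates <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("%-22s %4d/%4d = %5.1f%%\n", nm, r$numerator,
                r$denominator, r$percent))
  }
  invisible(x)
}

#' Cohen's kappa for a square cross-tab
#'
#' Chance-corrected agreement: kappa = (po - pe) / (1 - pe), with expected
#' agreement pe from the row and column margins. Returns `NA` when pe = 1
#' (both raters degenerate on one category).
#'
#' @param ct a square [crosstab()].
#' @return kappa in \[-1, 1\], or `NA`.
#' @export
cohens_kappa <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  m <- ct$counts
  if (nrow(m) != ncol(m)) stop("cohens_kappa needs a square cross-tab")
  n <- ct$n
  if (n == 0) return(NA_real_)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Whole-scan compartment confirmation rates
#'
#' For IRF or SRF anywhere in the OCT volume scan, conditions on the
#' physician's harmonized call (the whole-scan comparison convention):
#' the proportion of physician-present scans where the RC confirms presence,
#' the proportion of physician-absent scans where the RC confirms absence,
#' the physician false-negative set (physician absent, RC present), and the
#' fraction of those false negatives the RC flagged as strongly visible.
#' The opposite conditioning (on the RC call) is returned alongside, since
#' the consensus table uses it.
#'
#' @inheritParams foveal_fluid_crosstab
#' @param compartment `"IRF"` or `"SRF"`.
#' @return list with the cross-tab, both conditioning directions as rate
#'   records, `false_negatives` (count) and `false_negative_strong`.
#' @export
compartment_confirmation <- function(cohort, compartment = c("IRF", "SRF"),
                                     stratum = c("combined", "DME", "RVO")) {
  compartment <- match.arg(compartment)
  stratum <- match.arg(stratum)
  df <- as_cohort_df(cohort)
  if (stratum != "combined") df <- df[df$diagnosis == stratum, , drop = FALSE]
  comp <- tolower(compartment)
  phys <- harmonize_grade(df[[paste0("phys_", comp, "_any")]], na_ok = TRUE)
  rc <- harmonize_grade(df[[paste0("rc_", comp, "_any")]], na_ok = TRUE)
  keep <- !is.na(phys) & !is.na(rc)
  phys <- phys[keep]
  rc <- rc[keep]
  strong <- df[[paste0("rc_", comp, "_strong")]][keep]
  ct <- crosstab_from_logical(phys, rc)
  m <- ct$counts
  fn <- phys == FALSE & rc == TRUE
  list(
    compartment = compartment,
    crosstab = ct,
    # conditioned on the physician's call
    rc_confirms_presence = rate_record(m[1, 1], m[1, 1] + m[1, 2]),
    rc_confirms_absence = rate_record(m[2, 2], m[2, 1] + m[2, 2]),
    # conditioned on the RC's call
    phys_detects_rc_presence = rate_record(m[1, 1], m[1, 1] + m[2, 1]),
    phys_confirms_rc_absence = rate_record(m[2, 2], m[1, 2] + m[2, 2]),
    false_negatives = sum(fn),
    false_negative_strong = rate_record(sum(fn & strong %in% TRUE), sum(fn))
  )
}

#' Segmentation and ETDRS-grid agreement
#'
#' Per rater, the proportion of scans whose automatic retinal segmentation
#' was rated adequate and the proportion where the grid position was
#' manually corrected; plus the both-adequate agreement proportion over
#' scans both raters evaluated.
#'
#' @inheritParams foveal_fluid_crosstab
#' @return list of rate records.
#' @export
segmentation_agreement <- function(cohort,
                                   stratum = c("combined", "DME", "RVO")) {
  stratum <- match.arg(stratum)
  df <- as_cohort_df(cohort)
  if (stratum != "combined") df <- df[df$diagnosis == stratum, , drop = FALSE]
  ph <- harmonize_grade(df$phys_segmentation_adequate, na_ok = TRUE)
  rc <- harmonize_grade(df$rc_segmentation_adequate, na_ok = TRUE)
  both <- !is.na(ph) & !is.na(rc)
  list(
    adequate_phys = rate_record(sum(ph, na.rm = TRUE), sum(!is.na(ph))),
    adequate_rc = rate_record(sum(rc, na.rm = TRUE), sum(!is.na(rc))),
    both_adequate = rate_record(sum(both & ph & rc, na.rm = TRUE), sum(both)),
    grid_corrected_phys = rate_record(
      sum(df$phys_grid_corrected, na.rm = TRUE),
      sum(!is.na(df$phys_grid_corrected))
    ),
    grid_corrected_rc = rate_record(
      sum(df$rc_grid_corrected, na.rm = TRUE),
      sum(!is.na(df$rc_grid_corrected))
    )
  )
}

#' Paired physician-vs-RC thickness comparison
#'
#' Per-visit differences (physician minus RC) in CSRT or FCPT over visits
#' where both raters measured, with a paired two-sided t-test.
#'
#' @inheritParams foveal_fluid_crosstab
#' @param measure `"CSRT"` or `"FCPT"`.
#' @return list: `measure`, `sign_convention`, `n`, `mean_diff_um`,
#'   `sd_diff_um`, `mean_phys_um`, `sd_phys_um`, `mean_rc_um`, `sd_rc_um`,
#'   `p_value` (`NA` when n < 2).
#' @export
thickness_comparison <- function(cohort, measure = c("CSRT", "FCPT"),
                                 stratum = c("combined", "DME", "RVO")) {
  measure <- match.arg(measure)
  stratum <- match.arg(stratum)
  df <- as_cohort_df(cohort)
  if (stratum != "combined") df <- df[df$diagnosis == stratum, , drop = FALSE]
  col <- if (measure == "CSRT") "csrt_um" else "fcpt_um"
  ph <- df[[paste0("phys_", col)]]
  rc <- df[[paste0("rc_", col)]]
  keep <- !is.na(ph) & !is.na(rc)
  ph <- ph[keep]
  rc <- rc[keep]
  d <- ph - rc
  n <- length(d)
  list(
    measure = measure,
    sign_convention = "physician minus RC",
    n = n,
    mean_diff_um = if (n) mean(d) else NA_real_,
    sd_diff_um = if (n > 1) stats::sd(d) else NA_real_,
    mean_phys_um = if (n) mean(ph) else NA_real_,
    sd_phys_um = if (n > 1) stats::sd(ph) else NA_real_,
    mean_rc_um = if (n) mean(rc) else NA_real_,
    sd_rc_um = if (n > 1) stats::sd(rc) else NA_real_,
    p_value = if (n >= 2 && stats::sd(d) > 0) {
      stats::t.test(ph, rc, paired = TRUE)$p.value
    } else {
      NA_real_
    }
  )
}
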