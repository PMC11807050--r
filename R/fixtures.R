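orca_fixtures <- local({
  t1 <- function(pp, pa, ap, aa) {
    crosstab(matrix(
      c(pp, pa, ap, aa), nrow = 2, byrow = TRUE,
      dimnames = list(physician = c("present", "absent"),
                      rc = c("present", "absent"))
    ))
  }
  list(
    orca_table1_dme = list(
      source = "ORCA 24-month follow-up, consensus table, DME cohort",
      crosstab = t1(437, 135, 73, 62)
    ),
    orca_table1_rvo = list(
      source = "ORCA 24-month follow-up, consensus table, RVO cohort",
      crosstab = t1(192, 68, 36, 51)
    ),
    orca_fig2_counts = list(
      source = "ORCA 24-month follow-up, treatment-decision tree counts",
      combined = list(
        rc_fluid_total = 792L, treated_active = 282L,
        ww_justified_total = 270L, ww_justified_stable = 225L,
        undertreat_total = 240L, undertreat_unclear = 130L,
        undertreat_false_negative = 110L,
        undertreat_strongly_visible = 79L,
        no_fluid_total = 820L, injected_no_fluid = 323L,
        treat_justified_total = 153L, treat_justified_va_decline = 69L,
        treat_justified_series = 84L, overtreat_total = 170L,
        overtreat_false_positive = 46L
      ),
      DME = list(
        rc_fluid_total = 550L, treated_active = 203L,
        ww_justified_total = 194L, ww_justified_stable = 177L,
        undertreat_total = 153L, undertreat_unclear = 78L,
        undertreat_false_negative = 75L,
        no_fluid_total = 428L, injected_no_fluid = 177L,
        treat_justified_total = 83L, treat_justified_va_decline = 35L,
        treat_justified_series = 48L, overtreat_total = 94L,
        overtreat_false_positive = 28L
      ),
      RVO = list(
        rc_fluid_total = 242L, treated_active = 79L,
        ww_justified_total = 76L, ww_justified_stable = 48L,
        undertreat_total = 87L, undertreat_unclear = 52L,
        undertreat_false_negative = 35L,
        no_fluid_total = 392L, injected_no_fluid = 146L,
        treat_justified_total = 70L, treat_justified_va_decline = 24L,
        treat_justified_series = 36L, overtreat_total = 76L,
        overtreat_false_positive = 18L
      )
    ),
    orca_marginals = list(
      source = "ORCA 24-month follow-up, in-text counts",
      scans_total = 1612L, scans_dme = 978L, scans_rvo = 634L,
      rc_fluid_scans = 792L, rc_fluid_scans_dme = 550L,
      rc_fluid_scans_rvo = 242L,
      phys_fluid_scans = 852L,
      dual_graded_scans = 1054L,
      agree_present = 629L, agree_absent = 113L,
      rc_present_dual = 738L, rc_absent_dual = 316L,
      patients_total = 133L, patients_dme = 77L, patients_rvo = 56L,
      undertreated_patients = 77L, undertreated_patients_dme = 48L,
      undertreated_patients_rvo = 29L,
      overtreated_patients = 66L, overtreated_patients_dme = 37L,
      overtreated_patients_rvo = 29L,
      irf_false_negatives = 253L, irf_false_negatives_strong = 102L,
      irf_false_negatives_dme = 161L, irf_false_negatives_strong_dme = 82L,
      irf_false_negatives_rvo = 92L, irf_false_negatives_strong_rvo = 20L,
      srf_false_negatives = 28L, srf_false_negatives_strong = 11L
    )
  )
})

#' Packaged count fixtures from the ORCA 24-month follow-up
#'
#' The raw ORCA visit data are not public; what is public are integer count
#' tables (the physician-vs-RC consensus cross-tabs per cohort, the
#' treatment-decision tree counts, and the in-text marginal tallies). These
#' fixtures store those printed counts exactly, with a `source` note per
#' fixture, so that every published percentage can be recomputed from its
#' counts by the package's own rate machinery rather than asserted.
#'
#' @param name one of `"orca_table1_dme"`, `"orca_table1_rvo"`,
#'   `"orca_fig2_counts"`, `"orca_marginals"`.
#' @return the fixture: a list of counts (and, for the consensus tables, a
#'   [crosstab()]).
#' @export
#' @examples
#' load_fixture("orca_table1_dme")$crosstab
load_fixture <- function(name) {
  if (!name %in% names(orca_fixtures)) {
    stop("unknown fixture: ", name, " (see list_fixtures())")
  }
  orca_fixtures[[name]]
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() names(orca_fixtures)

# combined-cohort consensus cross-tab: DME + RVO cell sums
combined_table1 <- function() {
  crosstab(orca_fixtures$orca_table1_dme$crosstab$counts +
           orca_fixtures$orca_table1_rvo$crosstab$counts)
}
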