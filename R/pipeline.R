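#' Run the full cohort analysis pipeline
#'
#' Executes validate -> agreement -> longitudinal -> adjudication ->
#' outcomes on a visit-level cohort and collects every stage's output into
#' one summary structure. Deterministic given input, criteria and (for a
#' simulated input) seed. Every percentage in the summary is accompanied by
#' its integer numerator and denominator.
#'
#' @param input a visit data frame, a path to a visit CSV, or a
#'   `sim_config` (the cohort is then generated).
#' @param crit a [stability_criteria()].
#' @param series_gap_days see [adjudicate_visit()].
#' @return list of class `"cohort_summary"` with sections `provenance`,
#'   `validation`, `agreement`, `longitudinal`, `thickness`,
#'   `adjudication`, `outcomes`.
#' @export
run_pipeline <- function(input, crit = stability_criteria(),
                         series_gap_days = 42) {
  src <- "data.frame"
  input_hash <- NA_character_
  seed <- NA_integer_
  if (inherits(input, "sim_config")) {
    seed <- input$seed
    src <- "simulated"
    input <- generate_cohort(input)
  } else if (is.character(input) && length(input) == 1) {
    src <- input
    input_hash <- unname(tools::md5sum(input))
    input <- read_cohort_csv(input)
  }
  val <- validate_cohort(input)
  df <- val$cohort

  strata <- c("combined", "DME", "RVO")
  agreement <- lapply(strata, function(s) {
    ct <- foveal_fluid_crosstab(val, s)
    list(
      crosstab = ct,
      rates = if (all(dim(ct$counts) == 2) && ct$n > 0) {
        agreement_rates(ct)
      },
      kappa = cohens_kappa(ct),
      irf = compartment_confirmation(val, "IRF", s),
      srf = compartment_confirmation(val, "SRF", s),
      segmentation = segmentation_agreement(val, s)
    )
  })
  names(agreement) <- strata

  thickness <- lapply(strata, function(s) {
    list(csrt = thickness_comparison(val, "CSRT", s),
         fcpt = thickness_comparison(val, "FCPT", s))
  })
  names(thickness) <- strata

  longitudinal <- lapply(strata, function(s) change_concordance(val, s))
  names(longitudinal) <- strata

  adj <- adjudicate_cohort(val, crit, series_gap_days)
  rollup <- if (nrow(adj$results)) patient_rollup(adj) else NULL

  outcomes <- if (nrow(adj$results)) {
    list(
      undertreated = outcome_distribution(val, adj, undertreat_categories),
      treated_active = outcome_distribution(val, adj, "TREATED_ACTIVE"),
      ww_justified = outcome_distribution(
        val, adj, c("WW_JUSTIFIED_STABLE", "WW_JUSTIFIED_DOCUMENTED")
      )
    )
  }

  structure(list(
    provenance = list(
      input = src,
      input_md5 = input_hash,
      seed = seed,
      n_visits = nrow(df),
      n_patients = length(unique(df$patient_id)),
      criteria = unclass(crit),
      package_version = as.character(utils::packageVersion("octagree"))
    ),
    validation = list(issues = val$issues),
    agreement = agreement,
    thickness = thickness,
    longitudinal = longitudinal,
    adjudication = list(
      summary = adj$summary,
      n_excluded = nrow(adj$excluded),
      patient_rollup = if (!is.null(rollup)) rollup$summary
    ),
    outcomes = outcomes
  ), class = "cohort_summary")
}

# jsonlite-friendly view: crosstabs to named count lists, data frames kept
summary_to_list <- function(x) {
  convert <- function(v) {
    if (inherits(v, "crosstab")) {
      list(labels_phys = rownames(v$counts), labels_rc = colnames(v$counts),
           counts = unclass(v$counts), n = v$n)
    } else if (is.list(v) && !is.data.frame(v)) {
      lapply(v, convert)
    } else {
      v
    }
  }
  convert(unclass(x))
}

#' Serialize a cohort summary to JSON
#'
#' Writes the [run_pipeline()] summary as JSON. Serialization is stable:
#' serialize -> parse -> serialize is byte-identical.
#'
#' @param summary a `"cohort_summary"`.
#' @param path output path; when `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_summary_json <- function(summary, path = NULL) {
  render <- function(x) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                     pretty = TRUE)
  }
  # canonical form: one parse-serialize pass, so that serialize -> parse ->
  # serialize is byte-identical
  js <- render(jsonlite::fromJSON(render(summary_to_list(summary)),
                                  simplifyVector = FALSE))
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Recompute the published percentages from the packaged counts
#'
#' Runs the package's rate machinery over the packaged count fixtures
#' ([load_fixture()]) and returns every reproducible published percentage
#' next to its integer counts: the consensus cross-tab rates per cohort and
#' combined, the fluid-prevalence marginals, the treatment-decision tree
#' proportions, the patient-level rollups, and the strongly-visible-missed
#' fraction. Percentages use half-up rounding to one decimal, under which
#' each printed value reproduces exactly from its counts.
#'
#' @return data frame: `quantity`, `stratum`, `numerator`, `denominator`,
#'   `percent`.
#' @export
reproduce_published <- function() {
  rows <- list()
  add <- function(quantity, stratum, num, den) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, stratum = stratum,
      numerator = as.integer(num), denominator = as.integer(den),
      percent = pct1(num, den), stringsAsFactors = FALSE
    )
  }

  m <- load_fixture("orca_marginals")
  add("rc_foveal_fluid_prevalence", "combined", m$rc_fluid_scans,
      m$scans_total)
  add("rc_foveal_fluid_prevalence", "DME", m$rc_fluid_scans_dme, m$scans_dme)
  add("rc_foveal_fluid_prevalence", "RVO", m$rc_fluid_scans_rvo, m$scans_rvo)
  add("phys_foveal_fluid_prevalence", "combined", m$phys_fluid_scans,
      m$scans_total)

  for (s in c("combined", "DME", "RVO")) {
    ct <- switch(s,
      combined = combined_table1(),
      DME = load_fixture("orca_table1_dme")$crosstab,
      RVO = load_fixture("orca_table1_rvo")$crosstab
    )
    r <- agreement_rates(ct)
    add("agreement_overall", s, r$overall_agreement$numerator,
        r$overall_agreement$denominator)
    add("phys_sensitivity_foveal_fluid", s,
        r$positive_confirmation$numerator,
        r$positive_confirmation$denominator)
    add("phys_specificity_foveal_fluid", s,
        r$negative_confirmation$numerator,
        r$negative_confirmation$denominator)
    add("agreement_on_presence", s, ct$counts[1, 1], ct$n)
    add("agreement_on_absence", s, ct$counts[2, 2], ct$n)
  }

  f2 <- load_fixture("orca_fig2_counts")
  for (s in c("combined", "DME", "RVO")) {
    c2 <- f2[[s]]
    add("treated_given_rc_fluid", s, c2$treated_active, c2$rc_fluid_total)
    add("ww_justified_given_rc_fluid", s, c2$ww_justified_total,
        c2$rc_fluid_total)
    add("undertreat_given_rc_fluid", s, c2$undertreat_total,
        c2$rc_fluid_total)
    add("undertreat_unclear_share", s, c2$undertreat_unclear,
        c2$undertreat_total)
    add("undertreat_false_negative_share", s, c2$undertreat_false_negative,
        c2$undertreat_total)
    add("ww_stable_share", s, c2$ww_justified_stable, c2$ww_justified_total)
    add("injected_given_no_rc_fluid", s, c2$injected_no_fluid,
        c2$no_fluid_total)
    add("overtreat_false_positive_share", s, c2$overtreat_false_positive,
        c2$overtreat_total)
  }

  add("patients_possibly_undertreated", "combined", m$undertreated_patients,
      m$patients_total)
  add("patients_possibly_undertreated", "DME", m$undertreated_patients_dme,
      m$patients_dme)
  add("patients_possibly_undertreated", "RVO", m$undertreated_patients_rvo,
      m$patients_rvo)
  add("patients_possibly_overtreated", "combined", m$overtreated_patients,
      m$patients_total)
  add("irf_false_negative_strongly_visible", "combined",
      m$irf_false_negatives_strong, m$irf_false_negatives)
  add("irf_false_negative_strongly_visible", "DME",
      m$irf_false_negatives_strong_dme, m$irf_false_negatives_dme)
  add("irf_false_negative_strongly_visible", "RVO",
      m$irf_false_negatives_strong_rvo, m$irf_false_negatives_rvo)
  add("srf_false_negative_strongly_visible", "combined",
      m$srf_false_negatives_strong, m$srf_false_negatives)

  do.call(rbind, rows)
}
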