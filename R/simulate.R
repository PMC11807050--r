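#' Default simulation configuration
#'
#' Returns the configuration of the synthetic cohort generator. The defaults
#' are anchored to the marginal rates of the 24-month ORCA follow-up
#' cohorts: 77 DME and 56 RVO patients; RC prevalence of foveal fluid 0.562
#' (DME) and 0.382 (RVO); physician sensitivity 0.852 and specificity 0.358
#' for foveal fluid relative to the RC; injection probability 0.356 given
#' RC-confirmed foveal fluid and 0.394 without it; roughly a third of visits
#' lacking a physician grading. Where no published value exists (fluid
#' compartment mixture, thickness distributions, BCVA process) the defaults
#' are values typical of macular-oedema cohorts; see the package vignette.
#'
#' @param ... named overrides of individual fields.
#' @return a list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- default_sim_config(n_patients_dme = 5, n_patients_rvo = 5)
#' cohort <- generate_cohort(cfg)
default_sim_config <- function(...) {
  cfg <- list(
    n_patients_dme = 77L,
    n_patients_rvo = 56L,
    visits_per_patient = c(8L, 16L),
    visit_interval_days = c(21L, 42L),
    rc_foveal_prevalence = c(DME = 0.562, RVO = 0.382),
    phys_sensitivity_foveal = 0.852,
    phys_specificity_foveal = 0.358,
    irf_given_foveal = 0.90,
    srf_given_foveal = 0.30,
    p_extrafoveal_irf = 0.15,
    p_extrafoveal_srf = 0.05,
    p_diffuse_thickening_active = 0.15,
    p_strongly_visible = 0.40,
    p_questionable = 0.10,
    p_cannot_grade = 0.03,
    p_compartment_agreement = 0.90,
    p_seg_adequate_phys = 0.926,
    p_seg_adequate_rc = 0.799,
    p_grid_corrected_phys = 0.093,
    p_grid_corrected_rc = 0.413,
    p_inject_given_rc_fluid = 0.356,
    p_inject_given_no_rc_fluid = 0.394,
    p_documented_reason = 0.09,
    reason_distribution = c(
      planned_later = 0.25, lost_to_followup = 0.10,
      no_further_injections_requested = 0.15, therapy_change = 0.10,
      patient_preference = 0.20, adverse_event = 0.05, other = 0.15
    ),
    bcva_baseline_mean = 65,
    bcva_baseline_sd = 12,
    bcva_drift_untreated_fluid = -1.5,
    bcva_noise_sd = 3,
    csrt_active_mean = 380,
    csrt_active_sd = 70,
    csrt_quiet_mean = 285,
    csrt_quiet_sd = 35,
    paired_thickness_noise_sd = 15,
    change_threshold_um = 25,
    series_gap_days = 42L,
    p_missing_physician_grading = 0.346,
    seed = 0L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly, after checking ranges.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  probs <- c(
    cfg$rc_foveal_prevalence, cfg$phys_sensitivity_foveal,
    cfg$phys_specificity_foveal, cfg$irf_given_foveal, cfg$srf_given_foveal,
    cfg$p_extrafoveal_irf, cfg$p_extrafoveal_srf,
    cfg$p_diffuse_thickening_active, cfg$p_strongly_visible,
    cfg$p_questionable, cfg$p_cannot_grade, cfg$p_compartment_agreement,
    cfg$p_seg_adequate_phys, cfg$p_seg_adequate_rc,
    cfg$p_grid_corrected_phys, cfg$p_grid_corrected_rc,
    cfg$p_inject_given_rc_fluid, cfg$p_inject_given_no_rc_fluid,
    cfg$p_documented_reason, cfg$reason_distribution,
    cfg$p_missing_physician_grading
  )
  if (any(probs < 0 | probs > 1)) stop("sim_config: probability outside [0, 1]")
  if (cfg$n_patients_dme < 0 || cfg$n_patients_rvo < 0) {
    stop("sim_config: patient counts must be >= 0")
  }
  sds <- c(cfg$bcva_baseline_sd, cfg$bcva_noise_sd, cfg$csrt_active_sd,
           cfg$csrt_quiet_sd, cfg$paired_thickness_noise_sd)
  if (any(sds < 0)) stop("sim_config: standard deviations must be >= 0")
  if (length(cfg$visits_per_patient) != 2 ||
      any(cfg$visits_per_patient < 1) ||
      diff(cfg$visits_per_patient) < 0) {
    stop("sim_config: visits_per_patient must be an increasing pair >= 1")
  }
  if (!setequal(names(cfg$rc_foveal_prevalence), c("DME", "RVO"))) {
    stop("sim_config: rc_foveal_prevalence needs DME and RVO entries")
  }
  if (abs(sum(cfg$reason_distribution) - 1) > 1e-8) {
    stop("sim_config: reason_distribution must sum to 1")
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_sim_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s) in YAML: ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.list(v)) v <- unlist(v)
    cfg[[nm]] <- v
  }
  validate_sim_config(cfg)
  cfg
}

#' @rdname read_sim_config
#' @param cfg a `sim_config` list.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  plain <- lapply(unclass(cfg), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

grade_from_bool <- function(present, p_questionable, p_cannot_grade) {
  n <- length(present)
  out <- rep("no", n)
  u <- stats::runif(n)
  out[u < p_questionable] <- "questionable"
  out[u >= p_questionable & u < p_questionable + p_cannot_grade] <-
    "cannot_grade"
  out[present] <- "yes"
  out
}

#' Generate a synthetic visit-level cohort
#'
#' Simulates a two-stratum (DME / RVO) cohort with the statistical structure
#' the downstream analysis assumes. Per visit a latent foveal-fluid state is
#' drawn at the configured prevalence; the RC grading reports that state
#' without error (the RC is the reference evaluation), while the physician
#' grading is a noisy channel with the configured sensitivity and
#' specificity, emitting `questionable`/`cannot_grade` at configured rates
#' among its negative calls. CSRT is drawn from an active or quiet
#' distribution with independent paired measurement noise per rater; the
#' per-rater fluid-change category is derived from that rater's CSRT
#' difference against the previous visit (threshold
#' `cfg$change_threshold_um`). BCVA follows baseline plus cumulative drift
#' while fluid goes untreated, plus noise. Injections are drawn from the
#' two-probability policy; a configured fraction of no-treatment visits
#' carries a documented reason. The same config and seed always produce the
#' identical cohort.
#'
#' @param cfg a `sim_config`, e.g. from [default_sim_config()].
#' @return a visit data frame ([cohort_columns()] schema) with a
#'   `metadata` attribute recording the seed and config.
#' @export
generate_cohort <- function(cfg = default_sim_config()) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n_pat <- cfg$n_patients_dme + cfg$n_patients_rvo
  empty <- function() {
    types <- cohort_columns()
    out <- lapply(types, function(t) {
      switch(t,
        character = , grade = , change = character(),
        integer = integer(), numeric = numeric(), logical = logical(),
        date = as.Date(character())
      )
    })
    structure(as.data.frame(out, stringsAsFactors = FALSE),
              names = names(types))
  }
  if (n_pat == 0) {
    out <- empty()
    attr(out, "metadata") <- list(seed = cfg$seed, config = cfg)
    return(out)
  }

  diagnosis_pat <- c(rep("DME", cfg$n_patients_dme),
                     rep("RVO", cfg$n_patients_rvo))
  ids <- sprintf("%s-%04d", diagnosis_pat,
                 c(seq_len(cfg$n_patients_dme), seq_len(cfg$n_patients_rvo)))
  n_visits <- sample(cfg$visits_per_patient[1]:cfg$visits_per_patient[2],
                     n_pat, replace = TRUE)

  chunks <- vector("list", n_pat)
  for (p in seq_len(n_pat)) {
    nv <- n_visits[p]
    dx <- diagnosis_pat[p]
    gaps <- sample(cfg$visit_interval_days[1]:cfg$visit_interval_days[2],
                   nv, replace = TRUE)
    dates <- as.Date("2020-01-06") + cumsum(gaps)

    active <- stats::runif(nv) < cfg$rc_foveal_prevalence[[dx]]

    # RC grading: error-free report of the latent state, decomposed into
    # compartments; at least one foveal compartment carries the fluid.
    rc_irf_fov <- active & stats::runif(nv) < cfg$irf_given_foveal
    rc_srf_fov <- active & stats::runif(nv) < cfg$srf_given_foveal
    none <- active & !rc_irf_fov & !rc_srf_fov
    rc_irf_fov[none] <- TRUE
    rc_diffuse <- active & stats::runif(nv) < cfg$p_diffuse_thickening_active
    rc_irf_anyb <- rc_irf_fov | stats::runif(nv) < cfg$p_extrafoveal_irf
    rc_srf_anyb <- rc_srf_fov | stats::runif(nv) < cfg$p_extrafoveal_srf

    rc_irf_strong <- ifelse(rc_irf_anyb,
                            stats::runif(nv) < cfg$p_strongly_visible, NA)
    rc_srf_strong <- ifelse(rc_srf_anyb,
                            stats::runif(nv) < cfg$p_strongly_visible, NA)

    # physician channel on the foveal composite
    phys_pos <- ifelse(active,
                       stats::runif(nv) < cfg$phys_sensitivity_foveal,
                       stats::runif(nv) >= cfg$phys_specificity_foveal)
    ph_irf_fov <- phys_pos & ifelse(active, rc_irf_fov, TRUE)
    ph_srf_fov <- phys_pos & active & rc_srf_fov
    ph_diffuse <- phys_pos & active & rc_diffuse
    agree <- stats::runif(nv) < cfg$p_compartment_agreement
    ph_irf_anyb <- ph_irf_fov | (ifelse(agree, rc_irf_anyb, !rc_irf_anyb))
    agree2 <- stats::runif(nv) < cfg$p_compartment_agreement
    ph_srf_anyb <- ph_srf_fov | (ifelse(agree2, rc_srf_anyb, !rc_srf_anyb))

    # thickness: shared latent CSRT, independent paired noise per rater
    latent_csrt <- stats::rnorm(
      nv,
      ifelse(active, cfg$csrt_active_mean, cfg$csrt_quiet_mean),
      ifelse(active, cfg$csrt_active_sd, cfg$csrt_quiet_sd)
    )
    ph_csrt <- pmax(80, round(latent_csrt +
      stats::rnorm(nv, 0, cfg$paired_thickness_noise_sd)))
    rc_csrt <- pmax(80, round(latent_csrt +
      stats::rnorm(nv, 0, cfg$paired_thickness_noise_sd)))
    ph_fcpt <- pmax(60, round(ph_csrt - 15 + stats::rnorm(nv, 0, 10)))
    rc_fcpt <- pmax(60, round(rc_csrt - 15 + stats::rnorm(nv, 0, 10)))

    change_cat <- function(csrt) {
      d <- c(NA, diff(csrt))
      out <- rep("stable", nv)
      out[!is.na(d) & d > cfg$change_threshold_um] <- "increased"
      out[!is.na(d) & d < -cfg$change_threshold_um] <- "decreased"
      out[1] <- "not_applicable"
      out
    }
    ph_change <- change_cat(ph_csrt)
    rc_change <- change_cat(rc_csrt)

    # injection policy keyed on the RC fluid state
    inject <- ifelse(active,
                     stats::runif(nv) < cfg$p_inject_given_rc_fluid,
                     stats::runif(nv) < cfg$p_inject_given_no_rc_fluid)
    in_series <- c(FALSE, inject[-nv] & gaps[-1] <= cfg$series_gap_days)

    reason <- rep(NA_character_, nv)
    untreated <- !inject
    has_reason <- untreated & stats::runif(nv) < cfg$p_documented_reason
    reason[untreated] <- "none"
    if (any(has_reason)) {
      reason[has_reason] <- sample(
        names(cfg$reason_distribution), sum(has_reason), replace = TRUE,
        prob = cfg$reason_distribution
      )
    }

    # BCVA: baseline + cumulative drift while fluid went untreated + noise
    b0 <- min(95, max(10, round(stats::rnorm(
      1, cfg$bcva_baseline_mean, cfg$bcva_baseline_sd
    ))))
    drift_step <- c(0, (active & !inject)[-nv] * cfg$bcva_drift_untreated_fluid)
    bcva <- round(b0 + cumsum(drift_step) +
                    stats::rnorm(nv, 0, cfg$bcva_noise_sd))
    bcva <- pmin(100L, pmax(0L, as.integer(bcva)))

    qg <- function(present) {
      grade_from_bool(present, cfg$p_questionable, cfg$p_cannot_grade)
    }
    seg_ph <- qg(stats::runif(nv) < cfg$p_seg_adequate_phys)
    seg_rc <- qg(stats::runif(nv) < cfg$p_seg_adequate_rc)
    grid_ph <- stats::runif(nv) < cfg$p_grid_corrected_phys
    grid_rc <- stats::runif(nv) < cfg$p_grid_corrected_rc

    phys_missing <- stats::runif(nv) < cfg$p_missing_physician_grading

    ch <- list(
      patient_id = rep(ids[p], nv),
      eye = rep("OD", nv),
      visit_index = seq_len(nv) - 1L,
      visit_date = dates,
      diagnosis = rep(dx, nv),
      phys_irf_any = qg(ph_irf_anyb),
      phys_srf_any = qg(ph_srf_anyb),
      phys_irf_foveal = qg(ph_irf_fov),
      phys_srf_foveal = qg(ph_srf_fov),
      phys_diffuse_thickening = qg(ph_diffuse),
      phys_change = ph_change,
      phys_csrt_um = ph_csrt,
      phys_fcpt_um = ph_fcpt,
      phys_segmentation_adequate = seg_ph,
      phys_grid_corrected = grid_ph,
      rc_irf_any = ifelse(rc_irf_anyb, "yes", "no"),
      rc_srf_any = ifelse(rc_srf_anyb, "yes", "no"),
      rc_irf_foveal = ifelse(rc_irf_fov, "yes", "no"),
      rc_srf_foveal = ifelse(rc_srf_fov, "yes", "no"),
      rc_diffuse_thickening = ifelse(rc_diffuse, "yes", "no"),
      rc_irf_strong = rc_irf_strong,
      rc_srf_strong = rc_srf_strong,
      rc_change = rc_change,
      rc_csrt_um = rc_csrt,
      rc_fcpt_um = rc_fcpt,
      rc_segmentation_adequate = seg_rc,
      rc_grid_corrected = grid_rc,
      bcva_letters = bcva,
      injection_given = inject,
      injection_in_series = in_series,
      documented_reason = reason
    )
    blank <- c(
      "phys_irf_any", "phys_srf_any", "phys_irf_foveal", "phys_srf_foveal",
      "phys_diffuse_thickening", "phys_change", "phys_csrt_um",
      "phys_fcpt_um", "phys_segmentation_adequate", "phys_grid_corrected"
    )
    for (col in blank) ch[[col]][phys_missing] <- NA
    chunks[[p]] <- ch
  }

  cols <- names(cohort_columns())
  out <- lapply(cols, function(col) {
    do.call(c, lapply(chunks, `[[`, col))
  })
  names(out) <- cols
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$visit_date <- as.Date(out$visit_date,
                            origin = "1970-01-01")
  attr(out, "metadata") <- list(seed = cfg$seed, config = cfg)
  out
}
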