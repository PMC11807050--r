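# Hand-built visit rows for toy cohorts. Defaults describe a quiet,
# untreated DME visit; override any field by name.
toy_visit <- function(patient_id = "P1", eye = "OD", visit_index = 0L,
                      visit_date = as.Date("2021-01-01") + 30 * visit_index,
                      diagnosis = "DME",
                      phys_irf_any = "no", phys_srf_any = "no",
                      phys_irf_foveal = "no", phys_srf_foveal = "no",
                      phys_diffuse_thickening = "no",
                      phys_change = NA_character_,
                      phys_csrt_um = 300, phys_fcpt_um = 280,
                      phys_segmentation_adequate = "yes",
                      phys_grid_corrected = FALSE,
                      rc_irf_any = "no", rc_srf_any = "no",
                      rc_irf_foveal = "no", rc_srf_foveal = "no",
                      rc_diffuse_thickening = "no",
                      rc_irf_strong = NA, rc_srf_strong = NA,
                      rc_change = NA_character_,
                      rc_csrt_um = 300, rc_fcpt_um = 280,
                      rc_segmentation_adequate = "yes",
                      rc_grid_corrected = FALSE,
                      bcva_letters = 70L,
                      injection_given = FALSE,
                      injection_in_series = FALSE,
                      documented_reason = "none") {
  data.frame(
    patient_id = patient_id, eye = eye, visit_index = as.integer(visit_index),
    visit_date = visit_date, diagnosis = diagnosis,
    phys_irf_any = phys_irf_any, phys_srf_any = phys_srf_any,
    phys_irf_foveal = phys_irf_foveal, phys_srf_foveal = phys_srf_foveal,
    phys_diffuse_thickening = phys_diffuse_thickening,
    phys_change = phys_change, phys_csrt_um = phys_csrt_um,
    phys_fcpt_um = phys_fcpt_um,
    phys_segmentation_adequate = phys_segmentation_adequate,
    phys_grid_corrected = phys_grid_corrected,
    rc_irf_any = rc_irf_any, rc_srf_any = rc_srf_any,
    rc_irf_foveal = rc_irf_foveal, rc_srf_foveal = rc_srf_foveal,
    rc_diffuse_thickening = rc_diffuse_thickening,
    rc_irf_strong = rc_irf_strong, rc_srf_strong = rc_srf_strong,
    rc_change = rc_change, rc_csrt_um = rc_csrt_um,
    rc_fcpt_um = rc_fcpt_um,
    rc_segmentation_adequate = rc_segmentation_adequate,
    rc_grid_corrected = rc_grid_corrected,
    bcva_letters = as.integer(bcva_letters),
    injection_given = injection_given,
    injection_in_series = injection_in_series,
    documented_reason = documented_reason,
    stringsAsFactors = FALSE
  )
}

toy_cohort <- function(...) do.call(rbind, list(...))

# a fluid-positive visit as graded by both raters; overrides win
active_visit <- function(...) {
  args <- utils::modifyList(
    list(phys_irf_any = "yes", phys_irf_foveal = "yes",
         rc_irf_any = "yes", rc_irf_foveal = "yes", rc_irf_strong = TRUE),
    list(...)
  )
  do.call(toy_visit, args)
}
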