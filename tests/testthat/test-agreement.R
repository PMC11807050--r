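test_that("the foveal-fluid cross-tab equals a per-record tally", {
  set.seed(97)
  rows <- lapply(1:10, function(i) {
    toy_visit(
      patient_id = sprintf("P%02d", i),
      phys_irf_foveal = sample(grade_levels, 1),
      phys_srf_foveal = sample(grade_levels, 1),
      rc_irf_foveal = sample(grade_levels, 1),
      rc_srf_foveal = sample(grade_levels, 1),
      phys_irf_any = "yes", phys_srf_any = "yes",
      rc_irf_any = "yes", rc_srf_any = "yes"
    )
  })
  co <- do.call(rbind, rows)
  ct <- foveal_fluid_crosstab(co)
  expect_identical(unclass(ct$counts), unclass(oracle_crosstab(co)))
  expect_identical(ct$n, sum(oracle_crosstab(co)))
})

test_that("degenerate and empty strata tabulate without error", {
  co <- do.call(rbind, lapply(1:5, function(i) {
    active_visit(patient_id = sprintf("P%d", i))
  }))
  ct <- foveal_fluid_crosstab(co)
  expect_identical(ct$counts[1, 1], 5L)
  expect_identical(ct$n, 5L)
  expect_identical(foveal_fluid_crosstab(co, "RVO")$n, 0L)
})

test_that("agreement rates carry integer counts and match enumeration", {
  ct <- crosstab(matrix(c(3L, 1L, 2L, 4L), 2, byrow = TRUE,
                        dimnames = list(physician = c("present", "absent"),
                                        rc = c("present", "absent"))))
  r <- agreement_rates(ct)
  # enumerate the 10 implied records and tally them directly
  phys <- c(rep(TRUE, 3), TRUE, rep(FALSE, 2), rep(FALSE, 4))
  rc <- c(rep(TRUE, 3), FALSE, rep(TRUE, 2), rep(FALSE, 4))
  o <- oracle_rates(phys, rc)
  expect_equal(r$overall_agreement$proportion, o$overall)
  expect_equal(r$positive_confirmation$proportion, o$positive)
  expect_equal(r$negative_confirmation$proportion, o$negative)
  expect_identical(r$overall_agreement$numerator, 7L)
  expect_identical(r$overall_agreement$denominator, 10L)
  expect_equal(r$overall_agreement$proportion,
               r$overall_agreement$numerator /
                 r$overall_agreement$denominator)

  all_agree <- crosstab(matrix(c(6L, 0L, 0L, 4L), 2, byrow = TRUE,
                               dimnames = dimnames(ct$counts)))
  expect_equal(agreement_rates(all_agree)$overall_agreement$proportion, 1)

  # zero denominator yields NA, not 0/0
  rc_all_present <- crosstab(matrix(c(5L, 0L, 3L, 0L), 2, byrow = TRUE,
                                    dimnames = dimnames(ct$counts)))
  expect_true(is.na(agreement_rates(rc_all_present)$negative_confirmation$
                      proportion))
  expect_error(agreement_rates(crosstab(matrix(1:9, 3, dimnames = list(
    physician = letters[1:3], rc = letters[1:3]
  )))), "2x2")
})

test_that("Cohen's kappa matches hand computation and its fixed points", {
  dn <- list(physician = c("present", "absent"), rc = c("present", "absent"))
  perfect <- crosstab(matrix(c(30L, 0L, 0L, 20L), 2, byrow = TRUE,
                             dimnames = dn))
  expect_equal(cohens_kappa(perfect), 1)
  # counts equal to the outer product of the margins: independence
  indep <- crosstab(matrix(c(12L, 8L, 18L, 12L), 2, byrow = TRUE,
                           dimnames = dn))
  expect_equal(cohens_kappa(indep), 0)
  # po = 35/50 = 0.7; pe = (25*30 + 25*20)/50^2 = 0.5; kappa = 0.4
  hand <- crosstab(matrix(c(20L, 5L, 10L, 15L), 2, byrow = TRUE,
                          dimnames = dn))
  expect_equal(cohens_kappa(hand), 0.4)
  degenerate <- crosstab(matrix(c(10L, 0L, 0L, 0L), 2, byrow = TRUE,
                                dimnames = dn))
  expect_true(is.na(cohens_kappa(degenerate)))
  expect_error(cohens_kappa(crosstab(matrix(1:6, 2, dimnames = list(
    physician = c("a", "b"), rc = c("x", "y", "z")
  )))), "square")
})

test_that("compartment confirmation conditions on the physician call", {
  # physician copies RC exactly: both confirmations are 1
  copy <- do.call(rbind, lapply(1:6, function(i) {
    g <- if (i %% 2) "yes" else "no"
    toy_visit(patient_id = sprintf("P%d", i), phys_irf_any = g,
              rc_irf_any = g, rc_irf_strong = if (g == "yes") TRUE else NA)
  }))
  cc <- compartment_confirmation(copy, "IRF")
  expect_equal(cc$rc_confirms_presence$proportion, 1)
  expect_equal(cc$rc_confirms_absence$proportion, 1)
  expect_identical(cc$false_negatives, 0L)

  # 12-record toy set vs direct tally
  set.seed(13)
  toy <- do.call(rbind, lapply(1:12, function(i) {
    toy_visit(patient_id = sprintf("P%02d", i),
              phys_irf_any = sample(c("yes", "no", "questionable"), 1),
              rc_irf_any = sample(c("yes", "no"), 1))
  }))
  toy$rc_irf_strong <- ifelse(toy$rc_irf_any == "yes",
                              c(TRUE, FALSE)[1 + seq_len(12) %% 2], NA)
  cc <- compartment_confirmation(toy, "IRF")
  p <- toy$phys_irf_any == "yes"
  r <- toy$rc_irf_any == "yes"
  expect_identical(cc$rc_confirms_presence$numerator, sum(p & r))
  expect_identical(cc$rc_confirms_presence$denominator, sum(p))
  expect_identical(cc$rc_confirms_absence$numerator, sum(!p & !r))
  expect_identical(cc$rc_confirms_absence$denominator, sum(!p))
  expect_identical(cc$false_negatives, sum(!p & r))
  expect_identical(cc$false_negative_strong$numerator,
                   sum(!p & r & toy$rc_irf_strong %in% TRUE))
})

test_that("segmentation and grid proportions match a hand tally", {
  seg_ph <- c("yes", "yes", "no", "yes", "cannot_grade", "yes", "yes", "no")
  seg_rc <- c("yes", "no", "no", "yes", "yes", "questionable", "yes", "yes")
  grid_ph <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  grid_rc <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  co <- do.call(rbind, lapply(1:8, function(i) {
    toy_visit(patient_id = sprintf("P%d", i),
              phys_segmentation_adequate = seg_ph[i],
              rc_segmentation_adequate = seg_rc[i],
              phys_grid_corrected = grid_ph[i],
              rc_grid_corrected = grid_rc[i])
  }))
  s <- segmentation_agreement(co)
  expect_identical(s$adequate_phys$numerator, 5L)
  expect_identical(s$adequate_rc$numerator, 5L)
  expect_identical(s$both_adequate$numerator, 3L)  # visits 1, 4, 7
  expect_identical(s$both_adequate$denominator, 8L)
  expect_identical(s$grid_corrected_phys$numerator, 2L)
  expect_identical(s$grid_corrected_rc$numerator, 5L)
})

test_that("paired thickness comparison recovers a known difference", {
  same <- do.call(rbind, lapply(1:5, function(i) {
    toy_visit(patient_id = sprintf("P%d", i), phys_csrt_um = 300 + i,
              rc_csrt_um = 300 + i)
  }))
  t0 <- thickness_comparison(same, "CSRT")
  expect_equal(t0$mean_diff_um, 0)
  expect_equal(t0$sd_diff_um, 0)

  shifted <- same
  shifted$phys_csrt_um <- shifted$rc_csrt_um + 10
  t10 <- thickness_comparison(shifted, "CSRT")
  expect_equal(t10$mean_diff_um, 10)
  expect_equal(t10$sd_diff_um, 0)

  # Monte-Carlo recovery: true diff 5, sd 20, n 500
  set.seed(314)
  n <- 500
  rc <- rnorm(n, 300, 50)
  ph <- rc + rnorm(n, 5, 20)
  co <- do.call(rbind, lapply(seq_len(n), function(i) {
    toy_visit(patient_id = sprintf("P%04d", i), phys_csrt_um = ph[i],
              rc_csrt_um = rc[i])
  }))
  tt <- thickness_comparison(co, "CSRT")
  expect_identical(tt$n, 500L)
  expect_lt(abs(tt$mean_diff_um - 5), 3 * 20 / sqrt(n))
  expect_lt(tt$p_value, 0.01)
})
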