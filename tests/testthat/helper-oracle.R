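# Independent brute-force oracles. These re-derive every statistic by
# explicit per-record loops, sharing no code with the package internals, so
# that pipeline outputs can be checked against a second implementation.

oracle_present <- function(g) {
  if (is.na(g)) return(NA)
  if (g == "yes") TRUE else FALSE
}

# foveal composite for one visit row; NA when the rater graded nothing
oracle_composite <- function(row, rater, with_thickening = FALSE) {
  fields <- paste0(rater, c("_irf_foveal", "_srf_foveal",
                            if (with_thickening) "_diffuse_thickening"))
  vals <- unlist(row[fields], use.names = FALSE)
  if (all(is.na(vals))) return(NA)
  out <- FALSE
  for (v in vals) {
    p <- oracle_present(v)
    if (isTRUE(p)) out <- TRUE
  }
  out
}

oracle_crosstab <- function(df) {
  m <- matrix(0L, 2, 2,
              dimnames = list(physician = c("present", "absent"),
                              rc = c("present", "absent")))
  for (i in seq_len(nrow(df))) {
    p <- oracle_composite(df[i, ], "phys")
    r <- oracle_composite(df[i, ], "rc")
    if (is.na(p) || is.na(r)) next
    m[if (p) 1 else 2, if (r) 1 else 2] <-
      m[if (p) 1 else 2, if (r) 1 else 2] + 1L
  }
  m
}

# agreement rates by counting individual (phys, rc) record pairs
oracle_rates <- function(phys, rc) {
  agree <- pos_n <- pos_d <- neg_n <- neg_d <- 0L
  for (i in seq_along(phys)) {
    if (phys[i] == rc[i]) agree <- agree + 1L
    if (rc[i]) {
      pos_d <- pos_d + 1L
      if (phys[i]) pos_n <- pos_n + 1L
    } else {
      neg_d <- neg_d + 1L
      if (!phys[i]) neg_n <- neg_n + 1L
    }
  }
  list(overall = agree / length(phys),
       positive = if (pos_d) pos_n / pos_d else NA_real_,
       negative = if (neg_d) neg_n / neg_d else NA_real_)
}

oracle_change_tab <- function(df) {
  lv <- c("increased", "stable", "decreased")
  m <- matrix(0L, 3, 3, dimnames = list(physician = lv, rc = lv))
  for (i in seq_len(nrow(df))) {
    p <- df$phys_change[i]
    r <- df$rc_change[i]
    if (is.na(p) || is.na(r) || !(p %in% lv) || !(r %in% lv)) next
    m[match(p, lv), match(r, lv)] <- m[match(p, lv), match(r, lv)] + 1L
  }
  m
}

# literal tree walk over one eye's ordered visits; returns a category per
# visit (NA where the RC grading is absent)
oracle_adjudicate_eye <- function(d, bcva_win = 5, csrt_win = 25, k = 3,
                                  va_decline = 5, gap_days = 42) {
  n <- nrow(d)
  reasons <- c("planned_later", "lost_to_followup",
               "no_further_injections_requested", "therapy_change",
               "patient_preference", "adverse_event", "other")
  stability <- function(i) {
    lo <- i - k + 1
    if (lo < 1) return(NA)
    b <- d$bcva_letters[lo:i]
    t <- d$phys_csrt_um[lo:i]
    sb <- if (any(is.na(b))) NA else (max(b) - min(b)) <= bcva_win
    st <- if (any(is.na(t))) NA else (max(t) - min(t)) <= csrt_win
    if (isTRUE(sb) || isTRUE(st)) return(TRUE)
    if (is.na(sb) && is.na(st)) return(NA)
    FALSE
  }
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rc <- oracle_composite(d[i, ], "rc", with_thickening = TRUE)
    if (is.na(rc)) next
    ph <- oracle_composite(d[i, ], "phys", with_thickening = TRUE)
    inj <- d$injection_given[i]
    rsn <- d$documented_reason[i]
    if (rc) {
      if (isTRUE(inj)) {
        out[i] <- "TREATED_ACTIVE"
        next
      }
      stb <- stability(i)
      if (isTRUE(stb)) {
        out[i] <- "WW_JUSTIFIED_STABLE"
      } else if ((!is.na(rsn) && rsn %in% reasons) || is.na(stb) ||
                 is.na(inj) || is.na(rsn)) {
        out[i] <- "WW_JUSTIFIED_DOCUMENTED"
      } else if (isFALSE(ph)) {
        out[i] <- "UNDERTREAT_FALSE_NEGATIVE"
      } else {
        out[i] <- "UNDERTREAT_UNCLEAR"
      }
    } else {
      if (!isTRUE(inj)) {
        out[i] <- "UNTREATED_INACTIVE"
        next
      }
      declined <- FALSE
      if (i > 1 && !is.na(d$bcva_letters[i]) && !is.na(d$bcva_letters[i - 1])) {
        declined <- (d$bcva_letters[i] - d$bcva_letters[i - 1]) < -va_decline
      }
      series <- d$injection_in_series[i]
      if (is.na(series)) {
        series <- i > 1 && isTRUE(d$injection_given[i - 1]) &&
          as.numeric(d$visit_date[i] - d$visit_date[i - 1]) <= gap_days
      }
      if (declined) {
        out[i] <- "TREAT_JUSTIFIED_VA_DECLINE"
      } else if (isTRUE(series)) {
        out[i] <- "TREAT_JUSTIFIED_SERIES"
      } else if (isTRUE(ph)) {
        out[i] <- "OVERTREAT_FALSE_POSITIVE"
      } else {
        out[i] <- "OVERTREAT_UNCLEAR"
      }
    }
  }
  out
}

oracle_adjudicate <- function(df) {
  df <- df[order(df$patient_id, df$eye, df$visit_date), ]
  out <- list()
  for (key in unique(paste(df$patient_id, df$eye))) {
    d <- df[paste(df$patient_id, df$eye) == key, ]
    cats <- oracle_adjudicate_eye(d)
    out[[key]] <- data.frame(
      patient_id = d$patient_id, eye = d$eye, visit_index = d$visit_index,
      category = cats, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# small randomized cohort for oracle-equivalence sweeps: a generated
# mini-cohort with extra missingness injected to exercise the NA paths
random_mini_cohort <- function(seed) {
  cfg <- default_sim_config(
    n_patients_dme = 2, n_patients_rvo = 1,
    visits_per_patient = c(2L, 6L),
    p_documented_reason = 0.4,
    seed = seed
  )
  co <- generate_cohort(cfg)
  withr::with_seed(seed + 10000L, {
    n <- nrow(co)
    drop_rc <- runif(n) < 0.1
    for (col in grep("^rc_(irf|srf|diffuse)", names(co), value = TRUE)) {
      co[[col]][drop_rc] <- NA
    }
    co$documented_reason[runif(n) < 0.2] <- NA
    co$injection_in_series[runif(n) < 0.3] <- NA
    co$bcva_letters[runif(n) < 0.1] <- NA
  })
  co
}
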