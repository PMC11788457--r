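# Eligibility rule engine: trace filters, adverse-outcome flags, NPO
# screening, and end-to-end labeling with audit.

test_that("trace filters apply the published thresholds with closed bounds", {
  co <- make_clean_cohort(6)
  co$signal_loss_fraction <- c(0.05, 0.31, 0.30, 0.05, 0.05, 0.05)
  co$dr_analysis_complete[4] <- FALSE
  co$trace_to_delivery_hours <- c(10, 10, 10, 10, 48.0, 48.1)

  kept <- filter_traces(co)
  expect_identical(kept$subject_id, c("S001", "S003", "S005"))
  # 48.0 h is retained (closed interval); 0.30 signal loss is retained
  expect_true("S005" %in% kept$subject_id)
  audit <- attr(kept, "filter_audit")
  expect_identical(unname(audit["signal_loss"]), 1L)
  expect_identical(unname(audit["n_removed"]), 3L)

  expect_identical(nrow(filter_traces(co[0, ])), 0L)
  expect_error(filter_traces(dplyr::select(co, -"signal_loss_fraction")),
               class = "ctgperf_schema_error")
})

test_that("adverse-outcome flags fire on their definitions only", {
  co <- make_clean_cohort(4)
  co$apgar1[1] <- 3L # low_apgar via 1-min < 4
  co$stillbirth[2] <- TRUE
  co$liveborn[2] <- FALSE
  co$apgar1[3] <- 4L # both Apgar thresholds just passed
  co$apgar5[3] <- 7L

  flags <- assign_apo(co)
  expect_identical(flags$apo_flags[[1]], "low_apgar")
  expect_identical(flags$apo_flags[[2]], "stillbirth")
  expect_identical(flags$apo_flags[[3]], character(0))
  expect_identical(flags$apo_flags[[4]], character(0))
  expect_identical(flags$is_apo, c(TRUE, TRUE, FALSE, FALSE))

  # missing scores never fire a flag (affirmative evidence only)
  co$apgar1[4] <- NA_integer_
  co$apgar5[4] <- NA_integer_
  expect_false(assign_apo(co)$low_apgar[4])
})

test_that("NPO screening applies the labor-dependent acid-base rule", {
  co <- make_clean_cohort(6)
  # labored neonate just inside the labored thresholds -> eligible
  co$art_ph[1] <- 7.06
  co$art_base_deficit_mmol_l[1] <- 13.9
  # unlabored Cesarean at pH exactly 7.13 -> strict inequality fails
  co$labored[2] <- FALSE
  co$mode[2] <- "elective_cs"
  co$labor_duration_hours[2] <- NA_real_
  co$art_ph[2] <- 7.13
  # missing CPR is acceptable; a measured CPR at or below 1.5 is not
  co$cpr_36wk[3] <- NA_real_
  co$cpr_36wk[4] <- 1.4
  # missing arterial pH falls back to venous with shifted cutoff
  co$art_ph[5] <- NA_real_
  co$ven_ph[5] <- 7.30
  co$art_ph[6] <- NA_real_
  co$ven_ph[6] <- 7.08 # 7.08 - 0.05 = 7.03 < 7.05 -> fails

  npo <- assign_npo(co)
  expect_identical(npo$npo_eligible, c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                       FALSE))
  expect_identical(npo$reasons[[2]], "ph_rule")
  expect_identical(npo$reasons[[4]], "cpr")
  expect_identical(npo$reasons[[6]], "ph_rule")
  expect_identical(npo$reasons[[1]], character(0))
})

test_that("NPO exclusions and unverifiable inclusions each leave a reason", {
  co <- make_clean_cohort(5)
  co$mode[1] <- "emergency_cs"
  co$labor_duration_hours[2] <- 24 # must be strictly < 24 h
  co$apgar1[3] <- NA_integer_ # unverifiable -> ineligible
  co$hypertensive_disorder[4] <- TRUE
  co$birthweight_centile[5] <- 9.9

  npo <- assign_npo(co)
  expect_identical(npo$npo_eligible, rep(FALSE, 5))
  expect_identical(npo$reasons[[1]], "excl_emergency_cs")
  expect_identical(npo$reasons[[2]], "labor_duration")
  expect_identical(npo$reasons[[3]], "apgar")
  expect_identical(npo$reasons[[4]], "excl_hypertension")
  expect_identical(npo$reasons[[5]], "birthweight_centile")
})

test_that("build_cohorts partitions a hand-built fixture (5 APO, 10 NPO, 3 filtered)", {
  co <- make_clean_cohort(18)
  co$stillbirth[1:2] <- TRUE
  co$liveborn[1:2] <- FALSE
  co$acidemia[3] <- TRUE
  co$hie[4] <- TRUE
  co$apgar5[5] <- 5L
  co$signal_loss_fraction[16] <- 0.5
  co$dr_analysis_complete[17] <- FALSE
  co$trace_to_delivery_hours[18] <- 50

  lab <- build_cohorts(co)
  audit <- cohort_audit(lab)
  expect_identical(unname(audit$labels),
                   c(5L, 10L, 3L))
  expect_identical(sort(lab$subject_id[lab$label == "APO"]),
                   sprintf("S%03d", 1:5))
  # every ineligible record carries at least one machine-readable reason
  inel <- lab$exclusion_reasons[lab$label == "ineligible"]
  expect_true(all(lengths(inel) >= 1))
  expect_identical(lab$exclusion_reasons[[16]],
                   "trace_filter/signal_loss")
  # eligible / APO rows carry none
  expect_true(all(lengths(lab$exclusion_reasons[lab$label != "ineligible"])
                  == 0))
})

test_that("labeling is order-independent and flags APO/NPO contradictions", {
  co <- generate_cohort(cohort_config(n_subjects = 400, seed = 21))
  lab <- build_cohorts(co)

  perm <- withr::with_seed(1, sample.int(nrow(co)))
  lab_perm <- build_cohorts(co[perm, ])
  expect_identical(
    lab_perm[order(lab_perm$subject_id), ],
    {
      x <- lab[order(lab$subject_id), ]
      attr(x, "audit") <- attr(lab_perm, "audit")
      x
    }
  )
  expect_identical(cohort_audit(lab)$labels,
                   cohort_audit(lab_perm)$labels)

  # an asphyxia-only record passes every NPO screen: audited, labeled APO
  clean <- make_clean_cohort(2)
  clean$asphyxia[1] <- TRUE
  lab2 <- build_cohorts(clean)
  expect_identical(lab2$label, c("APO", "NPO"))
  expect_identical(cohort_audit(lab2)$contradictions, 1L)
})

test_that("an all-normal table yields no APO labels", {
  lab <- build_cohorts(make_clean_cohort(12))
  expect_identical(unname(cohort_audit(lab)$labels[["APO"]]), 0L)
  expect_true(all(lab$label == "NPO"))
})

test_that("the reconstructed published-count cohort labels 1658/1658", {
  dc <- demo_cohort()
  lab <- build_cohorts(dc)
  expect_identical(unname(cohort_audit(lab)$labels),
                   c(1658L, 1658L, 0L))
  cm <- confusion(dc, lab)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn),
                   c(301L, 155L, 1357L, 1503L))
})
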