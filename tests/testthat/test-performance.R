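# Confusion matrix, performance metrics, prevalence-standardized predictive
# values with logit-method intervals, stratified reports, and comparisons.

table1_cm <- function() confusion_matrix(301, 155, 1357, 1503)

test_that("confusion applies the outcome-positive labeling convention", {
  co <- make_clean_cohort(8)
  co$stillbirth[1:3] <- TRUE
  co$liveborn[1:3] <- FALSE
  co$dr_result <- c("criteria_not_met", "criteria_met", "criteria_met",
                    "criteria_not_met", rep("criteria_met", 4))
  lab <- build_cohorts(co)
  cm <- confusion(co, lab)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1L, 1L, 2L, 4L))

  # inverting the cohort labels transposes tp<->fp and fn<->tn
  lab_inv <- dplyr::mutate(
    lab, label = ifelse(label == "APO", "NPO", "APO")
  )
  cm_inv <- confusion(co, lab_inv)
  expect_identical(c(cm_inv$tp, cm_inv$fp, cm_inv$fn, cm_inv$tn),
                   c(cm$fp, cm$tp, cm$tn, cm$fn))

  # an all-negative call sheet has no positives of either kind
  co$dr_result <- "criteria_met"
  cm0 <- confusion(co, lab)
  expect_identical(c(cm0$tp, cm0$fp), c(0L, 0L))

  # ineligible labels must be screened out first
  co2 <- make_clean_cohort(2)
  co2$mode[2] <- "emergency_cs"
  expect_error(confusion(co2, build_cohorts(co2)), "ineligible")
})

test_that("point metrics and Wald intervals are computed per definition", {
  pm <- point_metrics(table1_cm())
  expect_equal(pm$estimate, c(1804 / 3316, 301 / 1658, 1503 / 1658))

  # independently computed Wald bounds (effective n = 1658 pairs for
  # accuracy)
  z <- qnorm(0.975)
  wald <- function(p, n) p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
  expect_equal(unlist(pm[1, c("conf_low", "conf_high")], use.names = FALSE),
               wald(1804 / 3316, 1658))
  expect_equal(unlist(pm[2, c("conf_low", "conf_high")], use.names = FALSE),
               wald(301 / 1658, 1658))
  # the traces variant widens nothing but halves the accuracy variance
  pm_t <- point_metrics(table1_cm(), accuracy_n = "traces")
  expect_equal(unlist(pm_t[1, c("conf_low", "conf_high")],
                      use.names = FALSE),
               wald(1804 / 3316, 3316))

  # perfect classifier
  pm1 <- point_metrics(confusion_matrix(1, 0, 0, 1))
  expect_equal(pm1$estimate, c(1, 1, 1))
  # degenerate: no APO -> sensitivity undefined, specificity defined
  pm2 <- point_metrics(confusion_matrix(0, 5, 0, 95))
  expect_true(is.na(pm2$estimate[pm2$metric == "sensitivity"]))
  expect_equal(pm2$estimate[pm2$metric == "specificity"], 0.95)
})

test_that("standardized predictive values follow Bayes' rule", {
  se <- 301 / 1658
  sp <- 1503 / 1658
  # at the matched 50% prevalence the standardized values collapse to the
  # raw confusion-matrix ratios
  expect_equal(adjusted_ppv(se, sp, 0.5), 301 / 456, tolerance = 1e-12)
  expect_equal(adjusted_npv(se, sp, 0.5), 1503 / 2860, tolerance = 1e-12)
  # the published high-risk stratum values
  expect_identical(fmt_pct(adjusted_ppv(se, sp, 0.30)), "45.4")
  expect_identical(fmt_pct(adjusted_npv(se, sp, 0.30)), "72.1")
  # perfect test
  expect_equal(adjusted_ppv(1, 1, 0.37), 1)
  expect_equal(adjusted_npv(1, 1, 0.37), 1)
  expect_error(adjusted_ppv(1.2, 0.5, 0.5), class = "ctgperf_config_error")
})

test_that("PPV rises and NPV falls with prevalence (property)", {
  pts <- withr::with_seed(91, {
    tibble::tibble(se = runif(1000, 0.01, 0.99),
                   sp = runif(1000, 0.01, 0.99),
                   p1 = runif(1000, 0.01, 0.49))
  })
  p2 <- pts$p1 + 0.4
  expect_true(all(adjusted_ppv(pts$se, pts$sp, p2) >
                    adjusted_ppv(pts$se, pts$sp, pts$p1)))
  expect_true(all(adjusted_npv(pts$se, pts$sp, p2) <
                    adjusted_npv(pts$se, pts$sp, pts$p1)))
})

test_that("logit-method predictive-value intervals match the stated formulas", {
  cm <- table1_cm()
  se <- 301 / 1658
  sp <- 1503 / 1658
  # independent computation straight from the delta-method expressions
  oracle <- function(p) {
    v_ppv <- (1 - se) / (se * 1658) + sp / ((1 - sp) * 1658)
    v_npv <- se / ((1 - se) * 1658) + (1 - sp) / (sp * 1658)
    z <- qnorm(0.975)
    ppv <- se * p / (se * p + (1 - sp) * (1 - p))
    npv <- sp * (1 - p) / (sp * (1 - p) + (1 - se) * p)
    list(
      ppv = plogis(qlogis(ppv) + c(-1, 1) * z * sqrt(v_ppv)),
      npv = plogis(qlogis(npv) + c(-1, 1) * z * sqrt(v_npv))
    )
  }
  for (p in c(0.01, 0.10, 0.30)) {
    got <- pv_confidence_interval(cm, p)
    want <- oracle(p)
    expect_equal(c(got$ppv_low, got$ppv_high), want$ppv)
    expect_equal(c(got$npv_low, got$npv_high), want$npv)
  }
  # interval width vanishes as both arms grow
  big <- confusion_matrix(301e4, 155e4, 1357e4, 1503e4)
  got_big <- pv_confidence_interval(big, 0.1)
  got_small <- pv_confidence_interval(cm, 0.1)
  expect_lt(got_big$ppv_high - got_big$ppv_low,
            (got_small$ppv_high - got_small$ppv_low) / 50)
  # symmetric matrix (tp = tn, fp = fn) at p = 0.5: se = sp, the two logit
  # variances coincide, and the PPV interval mirrors the NPV interval
  sym <- pv_confidence_interval(confusion_matrix(40, 25, 25, 40), 0.5)
  expect_equal(sym$ppv, sym$npv)
  expect_equal(sym$ppv_low, sym$npv_low)
  expect_equal(sym$ppv_high, sym$npv_high)
  # degenerate operating point is clipped with a warning
  expect_warning(pv_confidence_interval(confusion_matrix(10, 5, 0, 5), 0.1),
                 "Degenerate")
})

test_that("window stratification recovers a built-in sensitivity gradient", {
  cal <- calibrate_sensitivity_decay(0.23, 0.132)
  co <- generate_cohort(cohort_config(
    n_subjects = 10000, apo_prevalence = 0.5,
    true_sensitivity = cal$true_sensitivity,
    sensitivity_decay_per_24h = cal$sensitivity_decay_per_24h,
    confounding_coefficients = numeric(0), seed = 101
  ))
  lab <- tibble::tibble(subject_id = co$subject_id,
                        label = ifelse(co$apo_true, "APO", "NPO"))
  rep <- stratified_report(co, lab, by = "window")
  expect_identical(rep$stratum, c("0-24h", "24-48h"))
  n1 <- rep$tp + rep$fn
  expect_lt(abs(rep$sensitivity[1] - 0.23),
            3 * sqrt(0.23 * 0.77 / n1[1]))
  expect_lt(abs(rep$sensitivity[2] - 0.132),
            3 * sqrt(0.132 * 0.868 / n1[2]))
  # the two windows partition the whole table
  cm_all <- confusion(co, lab)
  expect_identical(sum(rep$tp) + sum(rep$fn) + sum(rep$fp) + sum(rep$tn),
                   cm_all$tp + cm_all$fn + cm_all$fp + cm_all$tn)

  # a single stratum covering all data equals the unstratified report
  co_early <- dplyr::mutate(co, trace_to_delivery_hours =
                              trace_to_delivery_hours / 2.01)
  rep_one <- stratified_report(co_early, lab, by = "window")
  expect_identical(rep_one$tp[1], cm_all$tp)
  expect_equal(rep_one$sensitivity[1],
               point_metrics(cm_all)$estimate[2])
  # the empty stratum is flagged undefined, not dropped
  expect_true(is.na(rep_one$sensitivity[2]))
})

test_that("per-outcome strata use each outcome's cases vs all controls", {
  co <- make_clean_cohort(12)
  co$acidemia[1:3] <- TRUE
  co$hie[3:4] <- TRUE # subject 3 carries both outcomes
  co$dr_result[c(1, 3)] <- "criteria_not_met"
  lab <- build_cohorts(co)
  rep <- stratified_report(co, dplyr::filter(lab, label != "ineligible"),
                           by = "outcome")
  acid <- rep[rep$stratum == "acidemia", ]
  hie <- rep[rep$stratum == "hie", ]
  expect_identical(acid$tp + acid$fn, 3L)
  expect_identical(hie$tp + hie$fn, 2L)
  # all eight NPO controls appear in every stratum
  expect_identical(unique(rep$fp + rep$tn), 8L)
  # strata with no cases report undefined sensitivity
  expect_true(is.na(rep$sensitivity[rep$stratum == "stillbirth"]))
})

test_that("stratum comparisons agree with the closed-form chi-square", {
  # identical proportions -> zero statistic, p = 1
  same <- compare_strata(confusion_matrix(50, 0, 50, 0),
                         confusion_matrix(50, 0, 50, 0), "sensitivity")
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  # hand-computed 2x2 chi-square for 23/100 vs 13/100
  a <- compare_strata(confusion_matrix(23, 0, 77, 0),
                      confusion_matrix(13, 0, 87, 0), "sensitivity")
  tab <- rbind(c(23, 77), c(13, 87))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  expect_equal(a$statistic, x2)
  expect_equal(a$p_value, pchisq(x2, df = 1, lower.tail = FALSE))

  # specificity near 0.90 in both windows is far from significant
  b <- compare_strata(confusion_matrix(0, 755 - 686, 0, 686),
                      confusion_matrix(0, 760 - 686, 0, 686),
                      "specificity")
  expect_gt(b$p_value, 0.5)

  # tiny expected counts fall back to the exact test
  expect_warning(
    ft <- compare_strata(confusion_matrix(1, 0, 9, 0),
                         confusion_matrix(0, 0, 10, 0), "sensitivity"),
    "Fisher"
  )
  expect_identical(ft$method, "Fisher exact")

  # predictive values at a theoretical prevalence: delta-method z-test
  pvcmp <- compare_strata(confusion_matrix(23, 9, 77, 91),
                          confusion_matrix(13, 10, 87, 90), "ppv",
                          prevalence = 0.05)
  expect_true(pvcmp$p_value >= 0 && pvcmp$p_value <= 1)
  same_pv <- compare_strata(confusion_matrix(23, 9, 77, 91),
                            confusion_matrix(23, 9, 77, 91), "ppv")
  expect_equal(same_pv$p_value, 1)
})

test_that("Mann-Whitney comparison matches the exact enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2 * 1/20 = 0.1
  expect_equal(compare_continuous(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compare_continuous(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_continuous(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(7)
  expect_lt(compare_continuous(rnorm(200), rnorm(200, 2)), 0.001)
  expect_error(compare_continuous(numeric(0), 1), "non-empty")
})
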