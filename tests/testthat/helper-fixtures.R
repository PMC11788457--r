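# Fixture builders and independent oracle implementations used across the
# suite. Oracles deliberately use naive algorithms (full scans, grid search)
# so they stay independent of the package's code paths.

# A fully specified cohort table of n uneventful, NPO-eligible term
# deliveries; tests then override individual fields.
make_clean_cohort <- function(n) {
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    ga_at_monitoring_days = 270L,
    fetal_sex = "female",
    maternal_bmi = 25,
    maternal_age_years = 30,
    parity = 0L,
    gravidity = 1L,
    trace_to_delivery_hours = 10,
    signal_loss_fraction = 0.05,
    dr_analysis_complete = TRUE,
    apo_true = FALSE,
    ga_at_delivery_days = 271L,
    liveborn = TRUE,
    breech = FALSE,
    labored = TRUE,
    mode = "spontaneous",
    labor_duration_hours = 8,
    birthweight_centile = 50,
    apgar1 = 9L,
    apgar5 = 10L,
    art_ph = 7.25,
    ven_ph = 7.30,
    art_base_deficit_mmol_l = 5,
    cpr_36wk = NA_real_,
    neonatal_death_3mo = FALSE,
    resuscitation = FALSE,
    scbu_admission = FALSE,
    scbu_extended = FALSE,
    cooling = FALSE,
    hie = FALSE,
    asphyxia = FALSE,
    acidemia = FALSE,
    stillbirth = FALSE,
    hypertensive_disorder = FALSE,
    suspected_infection = FALSE,
    dr_result = "criteria_met"
  )
}

# a propensity_model shell carrying given logit scores, for matcher tests
fake_model <- function(ids, labels, logits) {
  structure(
    list(scores = tibble::tibble(
      subject_id = ids, label = labels,
      score = stats::plogis(logits), logit = logits
    )),
    class = "propensity_model"
  )
}

# Brute-force greedy matcher: same seeded case order and tie-break contract
# as match_pairs(), but nearest neighbours found by scanning every
# still-available control.
brute_force_match <- function(model, caliper_multiplier, seed) {
  scores <- model$scores
  caliper <- caliper_multiplier * stats::sd(scores$logit)
  cases <- scores[scores$label == "APO", ]
  ctrls <- scores[scores$label == "NPO", ]
  case_order <- withr::with_seed(as.integer(seed),
                                 sample.int(nrow(cases)))
  alive <- rep(TRUE, nrow(ctrls))
  out <- list()
  for (i in case_order) {
    if (!any(alive)) break
    d <- abs(ctrls$logit - cases$logit[i])
    d[!alive] <- Inf
    best <- min(d)
    if (best > caliper) next
    cand <- which(d == best)
    j <- cand[order(ctrls$subject_id[cand])][1]
    alive[j] <- FALSE
    out[[length(out) + 1]] <- tibble::tibble(
      apo_id = cases$subject_id[i], npo_id = ctrls$subject_id[j],
      distance = best
    )
  }
  dplyr::bind_rows(out)
}

# pairs/cohort fixture with a given discordant/concordant layout
pair_fixture <- function(n10, n01, n_both = 0, n_neither = 0) {
  n <- n10 + n01 + n_both + n_neither
  case_exposed <- c(rep(TRUE, n10), rep(FALSE, n01), rep(TRUE, n_both),
                    rep(FALSE, n_neither))
  ctrl_exposed <- c(rep(FALSE, n10), rep(TRUE, n01), rep(TRUE, n_both),
                    rep(FALSE, n_neither))
  pairs <- tibble::tibble(apo_id = sprintf("A%04d", seq_len(n)),
                          npo_id = sprintf("B%04d", seq_len(n)))
  cohort <- tibble::tibble(
    subject_id = c(pairs$apo_id, pairs$npo_id),
    dr_result = ifelse(c(case_exposed, ctrl_exposed),
                       "criteria_not_met", "criteria_met")
  )
  list(pairs = pairs, cohort = cohort)
}

# Grid-search maximizer of the conditional log-likelihood for 1:1 binary
# exposure, as an oracle for the Newton-Raphson fitter.
grid_search_clogit <- function(n10, n01, lo = -8, hi = 8, steps = 4e5) {
  grid <- seq(lo, hi, length.out = steps)
  ll <- n10 * stats::plogis(grid, log.p = TRUE) +
    n01 * stats::plogis(-grid, log.p = TRUE)
  grid[which.max(ll)]
}
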