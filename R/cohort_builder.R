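# Trace-level filters and NPO/APO eligibility rules.
#
# The rule engine labels each trace APO (at least one of seven adverse
# neonatal outcomes), NPO (passes every normal-outcome inclusion rule and
# triggers no exclusion), or ineligible, with a machine-readable reason for
# every failure. All rules are pure functions of a single record.

apo_flag_names <- function() {
  c("acidemia", "stillbirth", "asphyxia", "scbu_extended", "hie",
    "low_apgar", "resuscitation")
}

trace_filter_columns <- function() {
  c("signal_loss_fraction", "dr_analysis_complete",
    "trace_to_delivery_hours", "ga_at_monitoring_days")
}

#' Apply the trace-level quality and timing filters
#'
#' Retains traces with at most 30% signal loss, a complete computerized
#' analysis, a trace-to-delivery interval within the closed window
#' \[0, 48\] h, and gestational age at monitoring within 37+0 to 41+6 weeks
#' (259–293 days). Missing values in any filter column fail that filter.
#'
#' @param data Cohort tibble.
#' @return The retained rows, with a `filter_audit` attribute counting the
#'   rows removed by each rule (a row failing several rules is counted under
#'   each).
#' @export
filter_traces <- function(data) {
  check_columns(data, trace_filter_columns(), "filter_traces()")
  fails <- trace_filter_fails(data)
  keep <- !Reduce(`|`, fails)
  out <- data[keep, , drop = FALSE]
  audit <- c(vapply(fails, sum, integer(1)),
             n_in = nrow(data), n_removed = sum(!keep))
  attr(out, "filter_audit") <- audit
  out
}

trace_filter_fails <- function(data) {
  na_true <- function(x) is.na(x) | x
  list(
    signal_loss = na_true(data$signal_loss_fraction > 0.30),
    incomplete_analysis = is.na(data$dr_analysis_complete) |
      !data$dr_analysis_complete,
    delivery_interval = na_true(data$trace_to_delivery_hours < 0 |
                                  data$trace_to_delivery_hours > 48),
    ga_window = na_true(data$ga_at_monitoring_days < 259 |
                          data$ga_at_monitoring_days > 293)
  )
}

#' Assign adverse pregnancy outcome flags
#'
#' Evaluates the seven adverse-outcome definitions per record: acidemia,
#' stillbirth, asphyxia, extended special-care (SCBU) admission,
#' hypoxic-ischemic encephalopathy, low Apgar scores (1-min score below 4 or
#' 5-min score below 7), and neonatal resuscitation (a single boolean input
#' covering cardiac massage and tromethamine/bicarbonate administration).
#' Flags require affirmative evidence: a missing field never fires a flag.
#'
#' @param data Cohort tibble.
#' @return A tibble with `subject_id`, one logical column per flag, an
#'   `apo_flags` list-column of fired flag names, and `is_apo`.
#' @export
assign_apo <- function(data) {
  check_columns(
    data,
    c("subject_id", "acidemia", "stillbirth", "asphyxia", "scbu_extended",
      "hie", "apgar1", "apgar5", "resuscitation"),
    "assign_apo()"
  )
  aff <- function(x) !is.na(x) & x
  out <- tibble::tibble(
    subject_id = data$subject_id,
    acidemia = aff(data$acidemia),
    stillbirth = aff(data$stillbirth),
    asphyxia = aff(data$asphyxia),
    scbu_extended = aff(data$scbu_extended),
    hie = aff(data$hie),
    low_apgar = aff(data$apgar1 < 4) | aff(data$apgar5 < 7),
    resuscitation = aff(data$resuscitation)
  )
  flag_mat <- as.matrix(out[apo_flag_names()])
  out$apo_flags <- apply(flag_mat, 1,
                         function(r) apo_flag_names()[r],
                         simplify = FALSE)
  out$is_apo <- rowSums(flag_mat) > 0
  out
}

#' Screen records against the normal pregnancy outcome rules
#'
#' Inclusion requires: liveborn singleton at 37+0 to 41+6 weeks' gestation
#' at delivery, maternal age 18–50 years, birth weight at or above the 10th
#' centile, labor shorter than 24 h (for labored deliveries), 1-min and
#' 5-min Apgar scores of at least 4 and 7, cord pH and base deficit within
#' the normal range (arterial pH > 7.13 with base deficit < 10.0 mmol/L for
#' Cesarean delivery without labor; arterial pH > 7.05 with base deficit
#' < 14.0 mmol/L after labor), and — when measured — a cerebroplacental
#' ratio above 1.5 at 36 weeks. Exclusions: neonatal death within 3 months,
#' emergency Cesarean section, breech presentation, neonatal resuscitation,
#' SCBU admission or cooling, hypertensive disorders of pregnancy, and
#' suspected infection or sepsis.
#'
#' Missing Apgar or acid-base fields make a record ineligible (inclusion
#' cannot be verified); a missing cerebroplacental ratio does not, since
#' that measurement was only required when available. When arterial pH is
#' missing, venous pH is accepted with the same cutoffs shifted by
#' `venous_ph_shift` (venous blood runs slightly more alkaline).
#'
#' @param data Cohort tibble.
#' @param venous_ph_shift Added to the arterial pH cutoffs when screening on
#'   venous pH; default 0.05.
#' @return A tibble with `subject_id`, `npo_eligible`, and a `reasons`
#'   list-column of failed rule identifiers (empty when eligible).
#' @export
assign_npo <- function(data, venous_ph_shift = 0.05) {
  check_columns(
    data,
    c("subject_id", "liveborn", "ga_at_delivery_days", "maternal_age_years",
      "birthweight_centile", "labored", "labor_duration_hours", "apgar1",
      "apgar5", "art_ph", "ven_ph", "art_base_deficit_mmol_l", "cpr_36wk",
      "mode", "neonatal_death_3mo", "breech", "resuscitation",
      "scbu_admission", "cooling", "hypertensive_disorder",
      "suspected_infection"),
    "assign_npo()"
  )
  pass <- function(x) !is.na(x) & x # NA cannot be verified -> fail
  fires <- function(x) !is.na(x) & x # NA exclusion evidence -> no fire

  ph <- ifelse(is.na(data$art_ph), data$ven_ph - venous_ph_shift,
               data$art_ph)
  ph_cut <- ifelse(data$labored, 7.05, 7.13)
  bd_cut <- ifelse(data$labored, 14.0, 10.0)

  rules <- list(
    liveborn = pass(data$liveborn),
    ga_delivery = pass(data$ga_at_delivery_days >= 259 &
                         data$ga_at_delivery_days <= 293),
    maternal_age = pass(data$maternal_age_years >= 18 &
                          data$maternal_age_years <= 50),
    birthweight_centile = pass(data$birthweight_centile >= 10),
    labor_duration = ifelse(pass(!data$labored), TRUE,
                            pass(data$labor_duration_hours < 24)),
    apgar = pass(data$apgar1 >= 4) & pass(data$apgar5 >= 7),
    ph_rule = pass(ph > ph_cut) &
      pass(data$art_base_deficit_mmol_l < bd_cut),
    cpr = is.na(data$cpr_36wk) | data$cpr_36wk > 1.5,
    excl_neonatal_death = !fires(data$neonatal_death_3mo),
    excl_emergency_cs = !fires(data$mode == "emergency_cs"),
    excl_breech = !fires(data$breech),
    excl_resuscitation = !fires(data$resuscitation),
    excl_scbu_admission = !fires(data$scbu_admission),
    excl_cooling = !fires(data$cooling),
    excl_hypertension = !fires(data$hypertensive_disorder),
    excl_infection = !fires(data$suspected_infection)
  )
  rule_mat <- do.call(cbind, rules)
  eligible <- rowSums(!rule_mat) == 0
  tibble::tibble(
    subject_id = data$subject_id,
    npo_eligible = eligible,
    reasons = apply(!rule_mat, 1, function(r) names(rules)[r],
                    simplify = FALSE)
  )
}

#' Label a cohort as APO, NPO, or ineligible
#'
#' Applies the trace filters (rows failing them are labeled ineligible with
#' `trace_filter/...` reasons), then assigns the APO label to any record
#' with at least one adverse-outcome flag, screens the remainder against the
#' NPO rules, and labels everything else ineligible with its failed rules.
#' APO assignment takes precedence: a record carrying an adverse-outcome
#' flag that would also screen as NPO-eligible is labeled APO and counted in
#' the audit's `contradictions`.
#'
#' @param data Cohort tibble.
#' @param apply_filters Apply [filter_traces()] first (default `TRUE`).
#' @param venous_ph_shift Passed to [assign_npo()].
#' @return A tibble with `subject_id`, `label` (`"APO"`, `"NPO"`, or
#'   `"ineligible"`), `apo_flags`, and `exclusion_reasons` list-columns;
#'   retrieve the per-rule audit with [cohort_audit()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 200, seed = 3))
#' labels <- build_cohorts(cohort)
#' dplyr::count(labels, label)
#' @export
build_cohorts <- function(data, apply_filters = TRUE,
                          venous_ph_shift = 0.05) {
  check_columns(data, "subject_id", "build_cohorts()")

  if (apply_filters) {
    check_columns(data, trace_filter_columns(), "build_cohorts()")
    fails <- trace_filter_fails(data)
    fail_mat <- do.call(cbind, fails)
    filtered_out <- rowSums(fail_mat) > 0
    filter_reasons <- apply(fail_mat, 1, function(r) {
      paste0("trace_filter/", names(fails)[r])
    }, simplify = FALSE)
  } else {
    filtered_out <- rep(FALSE, nrow(data))
    filter_reasons <- rep(list(character(0)), nrow(data))
  }

  apo <- assign_apo(data)
  npo <- assign_npo(data, venous_ph_shift = venous_ph_shift)

  is_apo <- apo$is_apo & !filtered_out
  is_npo <- !is_apo & npo$npo_eligible & !filtered_out

  label <- dplyr::case_when(
    is_apo ~ "APO",
    is_npo ~ "NPO",
    .default = "ineligible"
  )
  reasons <- purrr::pmap(
    list(filtered_out, filter_reasons, label, npo$reasons),
    function(fo, fr, lab, nr) {
      if (lab != "ineligible") character(0) else if (fo) fr else nr
    }
  )
  flags <- apo$apo_flags
  flags[filtered_out] <- list(character(0))
  out <- tibble::tibble(
    subject_id = data$subject_id,
    label = label,
    apo_flags = flags,
    exclusion_reasons = reasons
  )

  reason_counts <- sort(table(unlist(reasons)), decreasing = TRUE)
  flag_counts <- vapply(
    apo_flag_names(),
    function(f) sum(purrr::map_lgl(out$apo_flags, ~ f %in% .x)),
    integer(1)
  )
  attr(out, "audit") <- list(
    n = nrow(data),
    labels = c(APO = sum(label == "APO"), NPO = sum(label == "NPO"),
               ineligible = sum(label == "ineligible")),
    apo_flag_counts = flag_counts,
    ineligibility_reasons = as.list(reason_counts),
    contradictions = sum(is_apo & npo$npo_eligible)
  )
  out
}

#' Retrieve the audit trail attached to a labeled cohort
#'
#' @param labels Output of [build_cohorts()].
#' @return A list with label counts, per-flag APO counts, per-rule
#'   ineligibility counts, and the number of records that carried an
#'   adverse-outcome flag while also screening NPO-eligible.
#' @export
cohort_audit <- function(labels) {
  audit <- attr(labels, "audit")
  if (is.null(audit)) {
    abort("No audit attribute; was this produced by build_cohorts()?")
  }
  audit
}
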