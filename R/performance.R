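# Confusion matrix under the outcome-positive labeling convention,
# performance metrics with confidence intervals, prevalence-standardized
# predictive values with logit-method (Mercaldo) intervals, stratified
# reports, and between-stratum comparison tests.
#
# Labeling convention: a trace is test-positive when the computerized call
# is "criteria not met"; a pregnancy is outcome-positive when it belongs to
# the adverse-outcome (APO) cohort.

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts: true positives (APO,
#'   criteria not met), false positives (NPO, criteria not met), false
#'   negatives (APO, criteria met), true negatives (NPO, criteria met).
#' @return A `confusion_matrix` object.
#' @examples
#' confusion_matrix(301, 155, 1357, 1503)
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "confusion_matrix")
}

#' @method print confusion_matrix
#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(
    c(x$tp, x$fp, x$tp + x$fp, x$fn, x$tn, x$fn + x$tn,
      x$tp + x$fn, x$fp + x$tn, x$tp + x$fp + x$fn + x$tn),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Criteria not met", "Criteria met", "Total"),
                    c("Adverse", "Normal", "Total"))
  )
  print(m)
  invisible(x)
}

#' Cross-tabulate the CTG call against cohort membership
#'
#' @param data Cohort tibble with `subject_id` and `dr_result`.
#' @param labels Labeled cohort from [build_cohorts()], or any tibble with
#'   `subject_id` and `label`; every joined label must be `"APO"` or
#'   `"NPO"` — filter ineligible records out (or pass the matched subjects
#'   only) before tabulating.
#' @return A [confusion_matrix()].
#' @export
confusion <- function(data, labels) {
  check_columns(data, c("subject_id", "dr_result"), "confusion()")
  check_columns(labels, c("subject_id", "label"), "confusion()")
  df <- dplyr::inner_join(
    data[, c("subject_id", "dr_result")],
    labels[, c("subject_id", "label")],
    by = "subject_id"
  )
  if (any(!df$label %in% c("APO", "NPO"))) {
    abort(paste0(
      "confusion() requires APO/NPO labels only; ",
      "ineligible records must be filtered out first."
    ))
  }
  bad <- setdiff(unique(df$dr_result), c("criteria_met", "criteria_not_met"))
  if (length(bad) > 0) {
    abort(paste0("Unknown dr_result value(s): ", paste(bad, collapse = ", ")))
  }
  pos <- df$dr_result == "criteria_not_met"
  apo <- df$label == "APO"
  confusion_matrix(
    tp = sum(pos & apo), fp = sum(pos & !apo),
    fn = sum(!pos & apo), tn = sum(!pos & !apo)
  )
}

wald_ci <- function(p, n, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

wilson_ci <- function(x, n, conf_level) {
  as.numeric(suppressWarnings(
    prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int
  ))
}

#' Accuracy, sensitivity and specificity with confidence intervals
#'
#' Wald intervals by default (Wilson by flag). The accuracy interval uses an
#' effective sample size of the number of matched pairs (half the trace
#' count) by default, reflecting the pair-level dependence of a 1:1 matched
#' design; `accuracy_n = "traces"` uses the full count.
#'
#' @param cm A [confusion_matrix()].
#' @param conf_level Confidence level, default 0.95.
#' @param ci `"wald"` or `"wilson"`.
#' @param accuracy_n `"pairs"` (default) or `"traces"`.
#' @return A tibble with columns `metric`, `estimate`, `conf_low`,
#'   `conf_high` (proportions); a metric with a zero denominator is `NA`.
#' @export
point_metrics <- function(cm, conf_level = 0.95, ci = c("wald", "wilson"),
                          accuracy_n = c("pairs", "traces")) {
  ci <- match.arg(ci)
  accuracy_n <- match.arg(accuracy_n)
  n1 <- cm$tp + cm$fn
  n0 <- cm$fp + cm$tn
  n <- n1 + n0
  n_acc <- if (accuracy_n == "pairs") n / 2 else n

  one <- function(x, denom, n_eff = denom) {
    if (denom == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- x / denom
    bounds <- if (ci == "wald") wald_ci(p, n_eff, conf_level)
              else wilson_ci(x, round(n_eff), conf_level)
    c(p, pmax(bounds[1], 0), pmin(bounds[2], 1))
  }
  rows <- rbind(
    accuracy = one(cm$tp + cm$tn, n, n_acc),
    sensitivity = one(cm$tp, n1),
    specificity = one(cm$tn, n0)
  )
  tibble::tibble(
    metric = rownames(rows),
    estimate = unname(rows[, 1]),
    conf_low = unname(rows[, 2]),
    conf_high = unname(rows[, 3])
  )
}

#' Prevalence-standardized predictive values
#'
#' Bayes'-rule predictive values at a hypothetical outcome prevalence `p`:
#' `PPV = se p / (se p + (1 - sp)(1 - p))` and
#' `NPV = sp (1 - p) / (sp (1 - p) + (1 - se) p)`. PPV is strictly
#' increasing and NPV strictly decreasing in `p` for operating points
#' strictly inside the unit square.
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @param p Prevalence strictly in (0, 1). Vectorized over `p`.
#' @return Numeric vector of predictive values; `NaN` (flagged with a
#'   warning) when numerator and denominator are both zero.
#' @examples
#' adjusted_ppv(301 / 1658, 1503 / 1658, 0.30)
#' @export
adjusted_ppv <- function(se, sp, p) {
  check_proportion(se, "se", open = FALSE)
  check_proportion(sp, "sp", open = FALSE)
  check_proportion(p, "p")
  num <- se * p
  den <- se * p + (1 - sp) * (1 - p)
  if (any(den == 0)) warn("PPV undefined: zero numerator and denominator.")
  num / den
}

#' @rdname adjusted_ppv
#' @export
adjusted_npv <- function(se, sp, p) {
  check_proportion(se, "se", open = FALSE)
  check_proportion(sp, "sp", open = FALSE)
  check_proportion(p, "p")
  num <- sp * (1 - p)
  den <- sp * (1 - p) + (1 - se) * p
  if (any(den == 0)) warn("NPV undefined: zero numerator and denominator.")
  num / den
}

#' Logit-method confidence intervals for standardized predictive values
#'
#' Delta-method intervals on the logit scale for the prevalence-adjusted
#' PPV and NPV (the method of Mercaldo and colleagues for case-control
#' designs):
#' `var(logit PPV) = (1 - se) / (se n1) + sp / ((1 - sp) n0)` and
#' `var(logit NPV) = se / ((1 - se) n1) + (1 - sp) / (sp n0)`, where `n1`
#' and `n0` are the diseased and non-diseased sample sizes, back-transformed
#' from `logit(point) +/- z SE`. Degenerate operating points (se or sp equal
#' to 0 or 1) are clipped with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param p Prevalence vector, each strictly in (0, 1).
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with one row per prevalence: `prevalence`, `ppv`,
#'   `ppv_low`, `ppv_high`, `npv`, `npv_low`, `npv_high`.
#' @export
pv_confidence_interval <- function(cm, p, conf_level = 0.95) {
  n1 <- cm$tp + cm$fn
  n0 <- cm$fp + cm$tn
  if (n1 == 0 || n0 == 0) {
    abort("Both cohorts must be non-empty for predictive-value intervals.")
  }
  se <- cm$tp / n1
  sp <- cm$tn / n0
  if (se %in% c(0, 1) || sp %in% c(0, 1)) {
    warn(paste0(
      "Degenerate operating point (se or sp at 0 or 1); ",
      "intervals are computed at clipped rates."
    ))
    eps <- 0.5 / max(n1, n0)
    se <- min(max(se, eps), 1 - eps)
    sp <- min(max(sp, eps), 1 - eps)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  var_logit_ppv <- (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
  var_logit_npv <- se / ((1 - se) * n1) + (1 - sp) / (sp * n0)

  ppv <- adjusted_ppv(se, sp, p)
  npv <- adjusted_npv(se, sp, p)
  back <- function(point, v) {
    lo <- plogis(qlogis(point) - z * sqrt(v))
    hi <- plogis(qlogis(point) + z * sqrt(v))
    list(lo = lo, hi = hi)
  }
  bp <- back(ppv, var_logit_ppv)
  bn <- back(npv, var_logit_npv)
  tibble::tibble(
    prevalence = p,
    ppv = ppv, ppv_low = bp$lo, ppv_high = bp$hi,
    npv = npv, npv_low = bn$lo, npv_high = bn$hi
  )
}

#' Full performance report over a prevalence profile
#'
#' Combines [point_metrics()] with prevalence-standardized predictive
#' values and their logit-method intervals.
#'
#' @inheritParams point_metrics
#' @param prevalences Prevalence profile; default the four theoretical risk
#'   strata 1% (very low), 10% (low), 20% (medium), and 30% (high risk).
#' @return A `perf_report` list with elements `metrics` (tibble),
#'   `predictive_values` (tibble) and `cm`.
#' @examples
#' cm <- confusion_matrix(301, 155, 1357, 1503)
#' perf_report(cm)
#' @export
perf_report <- function(cm, prevalences = c(0.01, 0.10, 0.20, 0.30),
                        conf_level = 0.95, ci = c("wald", "wilson"),
                        accuracy_n = c("pairs", "traces")) {
  structure(
    list(
      metrics = point_metrics(cm, conf_level, ci, accuracy_n),
      predictive_values = pv_confidence_interval(cm, prevalences,
                                                 conf_level),
      cm = cm
    ),
    class = "perf_report"
  )
}

#' @method print perf_report
#' @export
print.perf_report <- function(x, ...) {
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-12s %s\n", m$metric[i],
                fmt_pct_ci(m$estimate[i], m$conf_low[i], m$conf_high[i])))
  }
  pv <- x$predictive_values
  for (i in seq_len(nrow(pv))) {
    cat(sprintf(
      "p = %-5s PPV %s   NPV %s\n", fmt_pct(pv$prevalence[i], 0),
      fmt_pct_ci(pv$ppv[i], pv$ppv_low[i], pv$ppv_high[i]),
      fmt_pct_ci(pv$npv[i], pv$npv_low[i], pv$npv_high[i])
    ))
  }
  invisible(x)
}

#' @method tidy perf_report
#' @export
tidy.perf_report <- function(x, ...) {
  pv <- x$predictive_values
  dplyr::bind_rows(
    x$metrics |> dplyr::mutate(prevalence = NA_real_),
    tibble::tibble(metric = "ppv", estimate = pv$ppv,
                   conf_low = pv$ppv_low, conf_high = pv$ppv_high,
                   prevalence = pv$prevalence),
    tibble::tibble(metric = "npv", estimate = pv$npv,
                   conf_low = pv$npv_low, conf_high = pv$npv_high,
                   prevalence = pv$prevalence)
  )
}

#' @method glance perf_report
#' @export
glance.perf_report <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n = x$cm$tp + x$cm$fp + x$cm$fn + x$cm$tn,
    accuracy = m$estimate[m$metric == "accuracy"],
    sensitivity = m$estimate[m$metric == "sensitivity"],
    specificity = m$estimate[m$metric == "specificity"]
  )
}

#' Stratified performance reports
#'
#' Two stratification modes. `by = "window"` partitions traces into the
#' \[0, 24) h and \[24, 48\] h trace-to-delivery windows and reports each.
#' `by = "outcome"` evaluates each adverse-outcome subgroup separately,
#' using that outcome's APO cases against all NPO controls (subgroups
#' overlap when outcomes co-occur). Subgroup predictive values default to a
#' 5% prevalence.
#'
#' @param data Cohort tibble (must include `trace_to_delivery_hours` for
#'   window stratification).
#' @param labels Labeled cohort restricted to APO/NPO (e.g. the matched
#'   subjects).
#' @param by `"window"` or `"outcome"`.
#' @param prevalence Single prevalence for the stratified predictive
#'   values; default 0.05.
#' @inheritParams point_metrics
#' @return A `stratified_report` tibble: one row per stratum with counts,
#'   metric estimates and CIs, and predictive values at `prevalence`.
#'   Metrics with an empty denominator are `NA`.
#' @export
stratified_report <- function(data, labels, by = c("window", "outcome"),
                              prevalence = 0.05, conf_level = 0.95,
                              ci = c("wald", "wilson"),
                              accuracy_n = c("pairs", "traces")) {
  by <- match.arg(by)
  check_columns(data, c("subject_id", "dr_result"), "stratified_report()")
  df <- dplyr::inner_join(
    labels, data, by = "subject_id",
    suffix = c("", ".cohort")
  )

  strata <- if (by == "window") {
    check_columns(data, "trace_to_delivery_hours", "stratified_report()")
    list(
      "0-24h" = df[df$trace_to_delivery_hours < 24, ],
      "24-48h" = df[df$trace_to_delivery_hours >= 24, ]
    )
  } else {
    flags <- assign_apo(data)
    npo_part <- df[df$label == "NPO", ]
    lapply(
      setNames(apo_flag_names(), apo_flag_names()),
      function(f) {
        ids <- flags$subject_id[flags[[f]]]
        dplyr::bind_rows(
          df[df$label == "APO" & df$subject_id %in% ids, ],
          npo_part
        )
      }
    )
  }

  purrr::imap(strata, function(sdf, nm) {
    cm <- if (nrow(sdf) == 0) confusion_matrix(0, 0, 0, 0)
          else confusion(sdf, sdf[, c("subject_id", "label")])
    pm <- point_metrics(cm, conf_level, ci, accuracy_n)
    pv <- if ((cm$tp + cm$fn) > 0 && (cm$fp + cm$tn) > 0) {
      pv_confidence_interval(cm, prevalence, conf_level)
    } else {
      tibble::tibble(prevalence = prevalence, ppv = NA_real_,
                     ppv_low = NA_real_, ppv_high = NA_real_,
                     npv = NA_real_, npv_low = NA_real_,
                     npv_high = NA_real_)
    }
    wide <- tibble::as_tibble(c(
      setNames(as.list(pm$estimate), pm$metric),
      setNames(as.list(pm$conf_low), paste0(pm$metric, "_low")),
      setNames(as.list(pm$conf_high), paste0(pm$metric, "_high"))
    ))
    dplyr::bind_cols(
      tibble::tibble(stratum = nm, tp = cm$tp, fp = cm$fp, fn = cm$fn,
                     tn = cm$tn),
      wide, pv
    )
  }) |>
    dplyr::bind_rows() |>
    structure(class = c("stratified_report", "tbl_df", "tbl", "data.frame"),
              prevalence = prevalence, by = by)
}

#' Compare a performance metric between two strata
#'
#' Sensitivity, specificity, and accuracy are compared on their underlying
#' counts with a 1-df two-proportion chi-square test (no continuity
#' correction by default), falling back to Fisher's exact test with a
#' warning when an expected cell drops below 1. Predictive values at a
#' fixed theoretical prevalence are deterministic functions of the two
#' operating points, so they are compared with a delta-method z-test on the
#' logit of the adjusted values.
#'
#' @param cm_a,cm_b [confusion_matrix()] objects for the two strata.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"accuracy"`,
#'   `"ppv"`, `"npv"`.
#' @param prevalence Prevalence for `"ppv"`/`"npv"` comparisons.
#' @param correct Apply the continuity correction in the chi-square test.
#' @return A tibble: `metric`, `value_a`, `value_b`, `statistic`,
#'   `p_value`, `method`.
#' @export
compare_strata <- function(cm_a, cm_b,
                           metric = c("sensitivity", "specificity",
                                      "accuracy", "ppv", "npv"),
                           prevalence = 0.05, correct = FALSE) {
  metric <- match.arg(metric)

  counts <- function(cm) {
    switch(metric,
      sensitivity = c(cm$tp, cm$tp + cm$fn),
      specificity = c(cm$tn, cm$fp + cm$tn),
      accuracy = c(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn),
      NULL
    )
  }

  if (metric %in% c("ppv", "npv")) {
    return(compare_pv(cm_a, cm_b, metric, prevalence))
  }

  ca <- counts(cm_a)
  cb <- counts(cm_b)
  if (ca[2] == 0 || cb[2] == 0) {
    abort("Both strata need a non-zero denominator for this metric.")
  }
  tab <- rbind(c(ca[1], ca[2] - ca[1]), c(cb[1], cb[2] - cb[1]))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warn("Expected cell below 1; using Fisher's exact test.")
    ft <- fisher.test(tab)
    return(tibble::tibble(
      metric = metric, value_a = ca[1] / ca[2], value_b = cb[1] / cb[2],
      statistic = NA_real_, p_value = ft$p.value,
      method = "Fisher exact"
    ))
  }
  ht <- suppressWarnings(
    prop.test(c(ca[1], cb[1]), c(ca[2], cb[2]), correct = correct)
  )
  tibble::tibble(
    metric = metric, value_a = ca[1] / ca[2], value_b = cb[1] / cb[2],
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = paste0("chi-square", if (correct) " (corrected)" else "")
  )
}

compare_pv <- function(cm_a, cm_b, metric, prevalence) {
  pv_one <- function(cm) {
    pv <- pv_confidence_interval(cm, prevalence)
    n1 <- cm$tp + cm$fn
    n0 <- cm$fp + cm$tn
    se <- cm$tp / n1
    sp <- cm$tn / n0
    v <- if (metric == "ppv") {
      (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
    } else {
      se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
    }
    list(point = pv[[metric]], var_logit = v)
  }
  a <- pv_one(cm_a)
  b <- pv_one(cm_b)
  z <- (qlogis(a$point) - qlogis(b$point)) /
    sqrt(a$var_logit + b$var_logit)
  tibble::tibble(
    metric = metric, value_a = a$point, value_b = b$point,
    statistic = unname(z), p_value = 2 * pnorm(-abs(z)),
    method = "delta-method z on logit of adjusted value"
  )
}

#' Compare a continuous variable between two groups
#'
#' Two-sided Mann–Whitney U-test (tie-corrected normal approximation for
#' larger samples, exact for small untied samples). If every value across
#' both samples is identical the p-value is 1 by convention.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return The two-sided p-value.
#' @examples
#' compare_continuous(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
compare_continuous <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("Both samples must be non-empty.")
  }
  if (length(unique(c(sample_a, sample_b))) == 1) return(1)
  suppressWarnings(wilcox.test(sample_a, sample_b)$p.value)
}
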