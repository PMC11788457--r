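# End-to-end orchestration: simulate/ingest -> filter -> label -> match ->
# evaluate -> infer, with a seeded, reproducible report bundle and renderers
# mirroring the published table layouts.

#' Configure an end-to-end pipeline run
#'
#' @param input Path to a cohort CSV to ingest, or `NULL` to simulate with
#'   `generator`.
#' @param generator A [cohort_config()] used when `input` is `NULL`.
#' @param seed Single integer governing the generator and the matching
#'   order.
#' @param caliper_multiplier Passed to [match_pairs()].
#' @param prevalences Prevalence profile for the main report.
#' @param subgroup_prevalence Prevalence for window/outcome strata.
#' @param ci,accuracy_n Confidence-interval variants, see
#'   [point_metrics()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = cohort_config(),
                            seed = 1L, caliper_multiplier = 0.05,
                            prevalences = c(0.01, 0.10, 0.20, 0.30),
                            subgroup_prevalence = 0.05,
                            ci = "wald", accuracy_n = "pairs") {
  check_proportion(prevalences, "prevalences")
  check_proportion(subgroup_prevalence, "subgroup_prevalence")
  if (!is.null(input) && !file.exists(input)) {
    abort(sprintf("Input path not resolvable: %s", input),
          class = "ctgperf_config_error")
  }
  structure(
    list(
      input = input, generator = generator, seed = as.integer(seed),
      caliper_multiplier = caliper_multiplier, prevalences = prevalences,
      subgroup_prevalence = subgroup_prevalence, ci = ci,
      accuracy_n = accuracy_n
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `generator` mapping mirrors [cohort_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "ctgperf_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  gen_args <- raw$generator %||% list()
  if (!is.null(gen_args$confounding_coefficients)) {
    gen_args$confounding_coefficients <-
      unlist(gen_args$confounding_coefficients)
  }
  raw$generator <- do.call(cohort_config, gen_args)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "ctgperf_stage_error", parent = e)
  })
}

#' Run the evaluation pipeline end to end
#'
#' Ingests or simulates a cohort, applies the trace filters and eligibility
#' rules, fits the propensity model and performs 1:1 caliper matching,
#' tabulates the matched confusion matrix, computes the performance report
#' over the prevalence profile plus time-window and per-outcome stratified
#' reports, and fits the conditional logistic model on the matched pairs.
#' A fixed seed makes the whole run deterministic.
#'
#' @param config A [pipeline_config()].
#' @return A `ctg_report` list bundling every stage's output: `cohort`,
#'   `labels`, `audit`, `model`, `pairs`, `balance`, `cm`, `performance`,
#'   `by_window`, `by_outcome`, `conditional_fit`, `seed`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by pipeline_config().")
  }

  cohort <- stage("ingest", {
    if (is.null(config$input)) {
      gen <- config$generator
      gen$seed <- config$seed
      generate_cohort(gen)
    } else {
      read_cohort_csv(config$input)
    }
  })

  labels <- stage("label", build_cohorts(cohort))
  model <- stage("match", fit_propensity(cohort, labels))
  pairs <- stage("match", match_pairs(model, config$caliper_multiplier,
                                      seed = config$seed))
  balance <- stage("match", balance_report(model, pairs))

  matched_labels <- stage("evaluate", {
    tibble::tibble(
      subject_id = c(pairs$apo_id, pairs$npo_id),
      label = rep(c("APO", "NPO"), each = nrow(pairs))
    )
  })
  cm <- stage("evaluate", confusion(cohort, matched_labels))
  performance <- stage("evaluate", perf_report(
    cm, prevalences = config$prevalences, ci = config$ci,
    accuracy_n = config$accuracy_n
  ))
  by_window <- stage("evaluate", stratified_report(
    cohort, matched_labels, by = "window",
    prevalence = config$subgroup_prevalence, ci = config$ci,
    accuracy_n = config$accuracy_n
  ))
  by_outcome <- stage("evaluate", stratified_report(
    cohort, matched_labels, by = "outcome",
    prevalence = config$subgroup_prevalence, ci = config$ci,
    accuracy_n = config$accuracy_n
  ))
  conditional_fit <- stage("infer", fit_conditional_logit(pairs, cohort))

  structure(
    list(
      cohort = cohort, labels = labels, audit = cohort_audit(labels),
      model = model, pairs = pairs, balance = balance, cm = cm,
      performance = performance, by_window = by_window,
      by_outcome = by_outcome, conditional_fit = conditional_fit,
      seed = config$seed, config = config
    ),
    class = "ctg_report"
  )
}

#' Ingest a cohort CSV
#'
#' @param path CSV with one row per trace; see the column dictionary in the
#'   vignette.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(
    df,
    c("subject_id", "dr_result", trace_filter_columns()),
    "read_cohort_csv()"
  )
  df
}

#' @method print ctg_report
#' @export
print.ctg_report <- function(x, ...) {
  cat(sprintf("CTG performance evaluation (seed %d)\n", x$seed))
  cat(sprintf(
    "  cohort: %d traces -> %d APO / %d NPO / %d ineligible\n",
    x$audit$n, x$audit$labels[["APO"]], x$audit$labels[["NPO"]],
    x$audit$labels[["ineligible"]]
  ))
  cat(sprintf("  matched pairs: %d (caliper %.4f)\n",
              nrow(x$pairs), attr(x$pairs, "caliper")))
  cat(sprintf("  confusion: tp %d fp %d fn %d tn %d\n",
              x$cm$tp, x$cm$fp, x$cm$fn, x$cm$tn))
  print(x$performance)
  cat(sprintf("  conditional OR: %.2f\n",
              x$conditional_fit$odds_ratio))
  invisible(x)
}

#' Render the report bundle as publication-style tables
#'
#' Emits the confusion matrix in the published row layout, the performance
#' table (percentages to one decimal place, round-half-even, interval in
#' parentheses), and the time-window comparison table with p-values.
#' Undefined entries render as an em dash.
#'
#' @param report A [run_pipeline()] result.
#' @return A list of tibbles: `confusion`, `performance`, `windows`.
#' @export
render_tables <- function(report) {
  cm <- report$cm
  confusion_tbl <- tibble::tibble(
    dr_result = c("Criteria not met", "Criteria met", "Total"),
    adverse = c(cm$tp, cm$fn, cm$tp + cm$fn),
    normal = c(cm$fp, cm$tn, cm$fp + cm$tn),
    total = c(cm$tp + cm$fp, cm$fn + cm$tn,
              cm$tp + cm$fp + cm$fn + cm$tn)
  )

  m <- report$performance$metrics
  pv <- report$performance$predictive_values
  risk_label <- function(p) {
    dplyr::case_when(
      p <= 0.01 ~ "very low risk", p <= 0.10 ~ "low risk",
      p <= 0.20 ~ "medium risk", .default = "high risk"
    )
  }
  performance_tbl <- dplyr::bind_rows(
    tibble::tibble(
      metric = m$metric, group = NA_character_,
      value = fmt_pct_ci(m$estimate, m$conf_low, m$conf_high)
    ),
    tibble::tibble(
      metric = "ppv", group = paste0(risk_label(pv$prevalence), " (",
                                     fmt_pct(pv$prevalence, 0), "%)"),
      value = fmt_pct_ci(pv$ppv, pv$ppv_low, pv$ppv_high)
    ),
    tibble::tibble(
      metric = "npv", group = paste0(risk_label(pv$prevalence), " (",
                                     fmt_pct(pv$prevalence, 0), "%)"),
      value = fmt_pct_ci(pv$npv, pv$npv_low, pv$npv_high)
    )
  )

  windows_tbl <- render_window_comparison(report)
  list(confusion = confusion_tbl, performance = performance_tbl,
       windows = windows_tbl)
}

render_window_comparison <- function(report) {
  w <- report$by_window
  if (nrow(w) != 2) return(tibble::tibble())
  cms <- lapply(seq_len(2), function(i) {
    confusion_matrix(w$tp[i], w$fp[i], w$fn[i], w$tn[i])
  })
  p <- attr(w, "prevalence") %||% 0.05
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  rows <- lapply(metrics, function(mt) {
    cell <- function(i) {
      est <- w[[mt]][i]
      lo <- w[[paste0(mt, "_low")]][i]
      hi <- w[[paste0(mt, "_high")]][i]
      fmt_pct_ci(est, lo, hi)
    }
    pval <- tryCatch(
      compare_strata(cms[[1]], cms[[2]], mt, prevalence = p)$p_value,
      error = function(e) NA_real_
    )
    tibble::tibble(
      metric = mt, `0-24h` = cell(1), `24-48h` = cell(2),
      p_value = pval
    )
  })
  dplyr::bind_rows(rows)
}

#' Write the report bundle to disk
#'
#' Writes the rendered tables as CSV, the matched pairs as CSV, and a JSON
#' summary (label audit, balance, confusion counts, metrics, stratified
#' reports, conditional fit, and the seed).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- render_tables(report)
  paths <- c(
    confusion = file.path(dir, "table_confusion.csv"),
    performance = file.path(dir, "table_performance.csv"),
    windows = file.path(dir, "table_windows.csv"),
    pairs = file.path(dir, "matched_pairs.csv"),
    summary = file.path(dir, "report.json")
  )
  readr::write_csv(tabs$confusion, paths[["confusion"]])
  readr::write_csv(tabs$performance, paths[["performance"]])
  readr::write_csv(tabs$windows, paths[["windows"]])
  readr::write_csv(tibble::as_tibble(report$pairs), paths[["pairs"]])

  summary <- list(
    seed = report$seed,
    audit = report$audit,
    balance = list(
      smd = as.data.frame(report$balance),
      auc = attr(report$balance, "auc"),
      brier = attr(report$balance, "brier"),
      caliper = attr(report$pairs, "caliper"),
      n_matched = nrow(report$pairs)
    ),
    confusion = report$cm[c("tp", "fp", "fn", "tn")],
    metrics = as.data.frame(report$performance$metrics),
    predictive_values = as.data.frame(
      report$performance$predictive_values
    ),
    by_window = as.data.frame(report$by_window),
    by_outcome = as.data.frame(report$by_outcome),
    conditional_fit = report$conditional_fit[
      c("beta", "se_beta", "odds_ratio", "ci", "p_value", "n10", "n01",
        "n_concordant")
    ]
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
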