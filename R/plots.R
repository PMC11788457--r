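# ggplot2 renderings of the result objects.

#' Love plot of covariate balance
#'
#' Standardized mean differences per covariate before and after matching,
#' with the conventional 0.10 acceptability threshold.
#'
#' @param object A [balance_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot balance_report
#' @export
autoplot.balance_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("smd_before", "smd_after"),
                        names_to = "stage", values_to = "smd") |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("smd_before", "smd_after"),
                                 labels = c("before matching",
                                            "after matching")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                   colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0.10, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "standardized mean difference", y = NULL,
                  colour = NULL,
                  title = "Covariate balance") +
    ggplot2::theme_minimal()
}

#' Predictive values across the prevalence range
#'
#' PPV and NPV of the operating point in a report, traced over a fine
#' prevalence grid, with the report's prevalence profile marked.
#'
#' @param object A [perf_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perf_report
#' @export
autoplot.perf_report <- function(object, ...) {
  cm <- object$cm
  se <- cm$tp / (cm$tp + cm$fn)
  sp <- cm$tn / (cm$fp + cm$tn)
  grid <- seq(0.005, 0.995, by = 0.005)
  curve <- dplyr::bind_rows(
    tibble::tibble(prevalence = grid, metric = "PPV",
                   value = adjusted_ppv(se, sp, grid)),
    tibble::tibble(prevalence = grid, metric = "NPV",
                   value = adjusted_npv(se, sp, grid))
  )
  marks <- object$predictive_values |>
    dplyr::select("prevalence", PPV = "ppv", NPV = "npv") |>
    tidyr::pivot_longer(c("PPV", "NPV"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$prevalence,
                                      y = .data$value,
                                      colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, size = 2.5) +
    ggplot2::scale_y_continuous(labels = function(v) fmt_pct(v, 0)) +
    ggplot2::labs(x = "adverse-outcome prevalence",
                  y = "predictive value (%)", colour = NULL,
                  title = "Prevalence-standardized predictive values") +
    ggplot2::theme_minimal()
}

#' Distribution of matched logit distances
#'
#' @param object A [match_pairs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot matched_pairs
#' @export
autoplot.matched_pairs <- function(object, ...) {
  caliper <- attr(object, "caliper")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = caliper, linetype = "dashed") +
    ggplot2::labs(x = "|logit propensity difference|", y = "pairs",
                  title = sprintf("Matched-pair distances (caliper %.4f)",
                                  caliper)) +
    ggplot2::theme_minimal()
}
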