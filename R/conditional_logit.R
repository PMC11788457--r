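# Conditional logistic regression on 1:1 matched pairs.
#
# Each matched pair contributes exp(b x_case) / (exp(b x_case) +
# exp(b x_control)) to the conditional likelihood; writing d = x_case -
# x_control this is plogis(b d), so concordant pairs (d = 0) contribute a
# constant and only discordant pairs inform the estimate. For a binary
# exposure the maximizer has the closed form b = log(n10 / n01), used in
# tests as the oracle against the Newton-Raphson path.

#' Conditional logistic regression for a matched-pair design
#'
#' Fits the single-exposure conditional logistic model linking the CTG call
#' to outcome status across 1:1 APO–NPO matched pairs, maximizing the
#' conditional log-likelihood by Newton–Raphson with step-halving
#' (convergence when the step falls below `tol`, at most `max_iter`
#' iterations).
#'
#' @param pairs A [match_pairs()] result (or any tibble with `apo_id` and
#'   `npo_id`).
#' @param data Cohort tibble carrying the exposure column.
#' @param exposure Exposure column name; default `"dr_result"`.
#' @param positive Value coding an exposed subject; default
#'   `"criteria_not_met"`.
#' @param conf_level Confidence level for the Wald interval.
#' @param tol,max_iter Newton–Raphson controls.
#' @return A `cond_logit_fit` with the coefficient, its standard error and
#'   Wald interval, the odds ratio, the conditional log-likelihood, the
#'   Wald and likelihood-ratio p-values, and the discordant-pair counts
#'   `n10` (case exposed only) and `n01` (control exposed only). When one
#'   discordant count is zero the estimate is infinite and flagged with a
#'   warning; with no discordant pairs at all the fit errors.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 600, seed = 9))
#' labels <- build_cohorts(cohort)
#' model <- fit_propensity(cohort, labels)
#' pairs <- match_pairs(model, seed = 9)
#' fit_conditional_logit(pairs, cohort)
#' @export
fit_conditional_logit <- function(pairs, data, exposure = "dr_result",
                                  positive = "criteria_not_met",
                                  conf_level = 0.95,
                                  tol = 1e-10, max_iter = 50L) {
  check_columns(pairs, c("apo_id", "npo_id"), "fit_conditional_logit()")
  check_columns(data, c("subject_id", exposure), "fit_conditional_logit()")

  expo <- setNames(data[[exposure]], data$subject_id)
  x_case <- as.numeric(expo[pairs$apo_id] == positive)
  x_ctrl <- as.numeric(expo[pairs$npo_id] == positive)
  if (any(is.na(x_case)) || any(is.na(x_ctrl))) {
    abort("Every matched pair must have a known exposure for both members.")
  }
  d <- x_case - x_ctrl
  n10 <- sum(d == 1)
  n01 <- sum(d == -1)
  n_conc <- sum(d == 0)
  if (n10 + n01 == 0) {
    abort("No discordant pairs; the conditional estimate is undefined.")
  }

  ll <- function(b) sum(log(plogis(b * d[d != 0]))) + n_conc * log(0.5)

  if (n10 == 0 || n01 == 0) {
    warn(paste0(
      "All discordant pairs point the same way (n10 = ", n10,
      ", n01 = ", n01, "); the estimate is infinite."
    ))
    beta <- if (n10 == 0) -Inf else Inf
    return(new_cond_logit_fit(beta, NA_real_, NA_real_, n10, n01, n_conc,
                              conf_level, iterations = 0L,
                              loglik = if (n10 == 0) n_conc * log(0.5) +
                                n01 * 0 else n_conc * log(0.5)))
  }

  dd <- d[d != 0]
  beta <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- plogis(beta * dd)
    score <- sum(dd * (1 - p))
    info <- sum(dd^2 * p * (1 - p))
    step <- score / info
    # step-halving on log-likelihood decrease
    while (ll(beta + step) < ll(beta) && abs(step) > tol / 2) {
      step <- step / 2
    }
    beta <- beta + step
    if (abs(step) < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && abs(step) >= tol) {
    abort("Conditional logistic fit did not converge.")
  }
  p <- plogis(beta * dd)
  se_beta <- 1 / sqrt(sum(dd^2 * p * (1 - p)))
  new_cond_logit_fit(beta, se_beta, ll(beta), n10, n01, n_conc,
                     conf_level, iterations = iter,
                     lrt = 2 * (ll(beta) - ll(0)))
}

new_cond_logit_fit <- function(beta, se_beta, loglik, n10, n01, n_conc,
                               conf_level, iterations, lrt = NA_real_) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(beta + c(-1, 1) * z * se_beta)
  structure(
    list(
      beta = beta,
      se_beta = se_beta,
      loglik = loglik,
      odds_ratio = exp(beta),
      ci = ci,
      conf_level = conf_level,
      p_value = if (is.na(se_beta)) NA_real_ else
        2 * pnorm(-abs(beta / se_beta)),
      p_value_lrt = if (is.na(lrt)) NA_real_ else
        stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      n10 = n10,
      n01 = n01,
      n_concordant = n_conc,
      iterations = iterations
    ),
    class = "cond_logit_fit"
  )
}

#' @method print cond_logit_fit
#' @export
print.cond_logit_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Conditional logistic regression (1:1 matched pairs)\n",
      "  discordant pairs: n10 = %d, n01 = %d (concordant: %d)\n",
      "  coefficient %.3f (SE %.3f), OR %.2f (%.0f%% CI %.2f-%.2f), P %s\n"
    ),
    x$n10, x$n01, x$n_concordant, x$beta, x$se_beta, x$odds_ratio,
    100 * x$conf_level, x$ci[1], x$ci[2], format(x$p_value, digits = 3)
  ))
  invisible(x)
}

#' @method tidy cond_logit_fit
#' @export
tidy.cond_logit_fit <- function(x, ...) {
  tibble::tibble(
    term = "exposure",
    estimate = x$beta,
    std_error = x$se_beta,
    statistic = x$beta / x$se_beta,
    p_value = x$p_value,
    conf_low = log(x$ci[1]),
    conf_high = log(x$ci[2])
  )
}

#' @method glance cond_logit_fit
#' @export
glance.cond_logit_fit <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n10 + x$n01 + x$n_concordant,
    n10 = x$n10,
    n01 = x$n01,
    odds_ratio = x$odds_ratio,
    loglik = x$loglik,
    p_value = x$p_value,
    iterations = x$iterations
  )
}

#' Odds ratio and interval from a conditional-logistic fit
#'
#' Exponentiates the coefficient and its Wald bounds:
#' `OR = exp(beta)`, CI `exp(beta +/- z SE)`.
#'
#' @param fit A [fit_conditional_logit()] result.
#' @return A one-row tibble: `odds_ratio`, `conf_low`, `conf_high`.
#' @examples
#' # exponentiating a coefficient of 0.80 gives an odds ratio of 2.23
#' exp(0.80)
#' @export
odds_ratio <- function(fit) {
  if (!inherits(fit, "cond_logit_fit")) {
    abort("`fit` must be a cond_logit_fit.")
  }
  if (!is.finite(fit$beta)) {
    warn("Infinite coefficient; odds ratio is degenerate.")
  }
  tibble::tibble(
    odds_ratio = fit$odds_ratio,
    conf_low = fit$ci[1],
    conf_high = fit$ci[2]
  )
}
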