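# Propensity-score estimation, 1:1 caliper-constrained greedy matching on
# the logit scale, and covariate balance diagnostics.

#' Standardized mean difference between two samples
#'
#' Continuous: |mean_a - mean_b| / sqrt((var_a + var_b) / 2). Binary:
#' |p_a - p_b| / sqrt((p_a (1 - p_a) + p_b (1 - p_b)) / 2). An SMD below
#' 0.10 is conventionally taken as acceptable balance.
#'
#' @param values_a,values_b Numeric or logical vectors (binary values coded
#'   0/1 or logical).
#' @param kind `"continuous"` or `"binary"`.
#' @return Non-negative scalar; `0` when both arms are identical with zero
#'   variance, `Inf` (with a warning) when means differ but the pooled
#'   variance is zero.
#' @examples
#' smd(c(0.566), c(0.566), kind = "binary")
#' @export
smd <- function(values_a, values_b, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (kind == "continuous") {
    if (length(values_a) < 2 || length(values_b) < 2) {
      abort("Continuous SMD needs at least 2 observations per arm.")
    }
    num <- abs(mean(values_a) - mean(values_b))
    pooled <- (var(values_a) + var(values_b)) / 2
  } else {
    pa <- mean(values_a)
    pb <- mean(values_b)
    num <- abs(pa - pb)
    pooled <- (pa * (1 - pa) + pb * (1 - pb)) / 2
  }
  if (pooled == 0) {
    if (num == 0) return(0)
    warn("Zero pooled variance with unequal means; SMD is infinite.")
    return(Inf)
  }
  num / sqrt(pooled)
}

#' Fit the propensity model for adverse-outcome membership
#'
#' Maximum-likelihood logistic regression of cohort membership (APO coded 1,
#' NPO coded 0) on the sample-standardized matching covariates, by default
#' with all pairwise interaction terms. Fitted probabilities are clipped
#' away from 0 and 1 by `eps` before the logit transform.
#'
#' @param data Cohort tibble.
#' @param labels Output of [build_cohorts()]; only APO/NPO rows enter the
#'   fit.
#' @param covariates Covariate columns; default [pm_covariates()].
#' @param interactions Include all pairwise covariate interactions
#'   (default `TRUE`).
#' @param eps Clipping bound for fitted probabilities.
#' @return A `propensity_model` with the glm fit, per-subject scores and
#'   logit scores, discrimination (AUC) and calibration (Brier score)
#'   diagnostics, and the covariate data used, for balance reporting.
#' @export
fit_propensity <- function(data, labels, covariates = pm_covariates(),
                           interactions = TRUE, eps = 1e-8) {
  check_columns(data, c("subject_id", covariates), "fit_propensity()")
  df <- dplyr::inner_join(
    data,
    dplyr::filter(labels, .data$label %in% c("APO", "NPO")),
    by = "subject_id"
  )
  if (length(unique(df$label)) < 2) {
    abort("Need at least one subject in each of the APO and NPO cohorts.")
  }

  y <- as.integer(df$label == "APO")
  raw <- encode_covariates(df, covariates)
  z <- as.data.frame(scale(raw))
  # constant covariate -> scale() yields NaN; keep as zero column
  z[is.na(z)] <- 0

  rhs <- if (interactions && length(covariates) > 1) {
    paste0("(", paste(covariates, collapse = " + "), ")^2")
  } else {
    paste(covariates, collapse = " + ")
  }
  fml <- stats::as.formula(paste(".y ~", rhs))
  z$.y <- y
  fit <- glm(fml, family = binomial(), data = z)
  if (!fit$converged) {
    abort("Propensity logistic regression did not converge.")
  }
  p <- fitted(fit)
  if (max(abs(coef(fit)), na.rm = TRUE) > 15 &&
      (min(p) < 1e-10 || max(p) > 1 - 1e-10)) {
    abort(paste0(
      "Perfect or quasi-perfect separation in the propensity model: ",
      "fitted probabilities reach the boundary and coefficients diverge."
    ))
  }
  score <- pmin(pmax(p, eps), 1 - eps)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = score, quiet = TRUE,
    levels = c(0, 1), direction = "<"
  )))

  structure(
    list(
      fit = fit,
      scores = tibble::tibble(
        subject_id = df$subject_id,
        label = df$label,
        score = unname(score),
        logit = unname(qlogis(score))
      ),
      covariate_data = tibble::as_tibble(raw) |>
        dplyr::mutate(subject_id = df$subject_id, .before = 1),
      covariates = covariates,
      auc = auc,
      brier = mean((score - y)^2),
      eps = eps
    ),
    class = "propensity_model"
  )
}

# fetal_sex -> male indicator; everything else must already be numeric
encode_covariates <- function(df, covariates) {
  out <- lapply(covariates, function(cv) {
    x <- df[[cv]]
    if (cv == "fetal_sex" || is.character(x) || is.factor(x)) {
      as.numeric(x == "male")
    } else {
      as.numeric(x)
    }
  })
  names(out) <- covariates
  as.data.frame(out)
}

#' @method print propensity_model
#' @export
print.propensity_model <- function(x, ...) {
  n <- table(x$scores$label)
  cat(sprintf(
    "Propensity model: %d APO vs %d NPO\n  terms: %d   AUC: %.3f   Brier: %.4f\n",
    n[["APO"]], n[["NPO"]], length(coef(x$fit)), x$auc, x$brier
  ))
  invisible(x)
}

#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @method glance propensity_model
#' @export
glance.propensity_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_terms = length(coef(x$fit)),
    auc = x$auc,
    brier = x$brier,
    deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}

#' Greedy 1:1 caliper-constrained nearest-neighbour matching
#'
#' Matches each adverse-outcome (APO) record to its nearest still-available
#' normal-outcome (NPO) record on the logit of the propensity score, without
#' replacement, discarding candidate matches further apart than the caliper.
#' The caliper width is `caliper_multiplier` times the pooled standard
#' deviation of the logit scores (default multiplier 0.05). APO records are
#' processed in a seeded random order; nearest-neighbour queries run against
#' a sorted index of the control logits (binary search with outward scan,
#' the one-dimensional counterpart of a ball-tree). Exact distance ties are
#' broken toward the lexicographically smaller control id.
#'
#' @param model A [fit_propensity()] result.
#' @param caliper_multiplier Positive multiple of SD(logit score).
#' @param seed Integer seed for the processing order.
#' @return A `matched_pairs` tibble with columns `apo_id`, `npo_id`,
#'   `apo_logit`, `npo_logit`, `distance`, and attributes `caliper`,
#'   `seed`, `unmatched_apo`, `unmatched_npo`.
#' @export
match_pairs <- function(model, caliper_multiplier = 0.05, seed = 1L) {
  if (!inherits(model, "propensity_model")) {
    abort("`model` must be a propensity_model.")
  }
  if (!is.numeric(caliper_multiplier) || caliper_multiplier <= 0) {
    abort("`caliper_multiplier` must be positive.",
          class = "ctgperf_config_error")
  }
  scores <- model$scores
  caliper <- caliper_multiplier * sd(scores$logit)

  cases <- scores[scores$label == "APO", ]
  ctrls <- scores[scores$label == "NPO", ]

  case_order <- withr::with_seed(as.integer(seed),
                                 sample.int(nrow(cases)))

  # sorted control index; ties in logit ordered by id so the outward scan
  # meets the lower id first
  ord <- order(ctrls$logit, ctrls$subject_id)
  c_logit <- ctrls$logit[ord]
  c_id <- ctrls$subject_id[ord]
  alive <- rep(TRUE, length(c_logit))

  res_apo <- character(0)
  res_npo <- character(0)
  res_al <- numeric(0)
  res_nl <- numeric(0)

  for (i in case_order) {
    x <- cases$logit[i]
    j <- nearest_alive(c_logit, c_id, alive, x)
    if (is.na(j)) next
    d <- abs(c_logit[j] - x)
    if (d > caliper) next
    alive[j] <- FALSE
    res_apo <- c(res_apo, cases$subject_id[i])
    res_npo <- c(res_npo, c_id[j])
    res_al <- c(res_al, x)
    res_nl <- c(res_nl, c_logit[j])
  }

  pairs <- tibble::tibble(
    apo_id = res_apo, npo_id = res_npo,
    apo_logit = res_al, npo_logit = res_nl,
    distance = abs(res_al - res_nl)
  )
  if (nrow(pairs) == 0) {
    warn("No matchable pairs within the caliper.")
  }
  stopifnot(all(pairs$distance <= caliper))
  structure(
    pairs,
    class = c("matched_pairs", class(pairs)),
    caliper = caliper,
    caliper_multiplier = caliper_multiplier,
    seed = as.integer(seed),
    unmatched_apo = setdiff(cases$subject_id, pairs$apo_id),
    unmatched_npo = setdiff(ctrls$subject_id, pairs$npo_id)
  )
}

# index of nearest alive control to x in the sorted logit vector; ties
# broken toward the smaller control id
nearest_alive <- function(c_logit, c_id, alive, x) {
  n <- length(c_logit)
  if (!any(alive)) return(NA_integer_)
  pos <- findInterval(x, c_logit)
  l <- pos
  while (l >= 1 && !alive[l]) l <- l - 1
  r <- pos + 1
  while (r <= n && !alive[r]) r <- r + 1
  if (l < 1 && r > n) return(NA_integer_)
  if (l < 1) return(r)
  if (r > n) return(l)
  dl <- abs(c_logit[l] - x)
  dr <- abs(c_logit[r] - x)
  if (dl < dr) return(l)
  if (dr < dl) return(r)
  if (c_id[l] <= c_id[r]) l else r
}

#' Covariate balance diagnostics before and after matching
#'
#' Standardized mean differences for every matching covariate, computed on
#' the full APO-vs-NPO sample and on the matched subsample, alongside the
#' propensity model's AUC and Brier score.
#'
#' @param model A [fit_propensity()] result.
#' @param pairs A [match_pairs()] result.
#' @return A `balance_report` tibble with columns `covariate`, `kind`,
#'   `smd_before`, `smd_after`; model diagnostics are available via
#'   [glance()] and stored as attributes.
#' @export
balance_report <- function(model, pairs) {
  cov_data <- model$covariate_data
  labs <- model$scores
  kinds <- vapply(model$covariates, function(cv) {
    x <- cov_data[[cv]]
    if (all(x %in% c(0, 1))) "binary" else "continuous"
  }, character(1))

  apo_all <- cov_data[labs$label == "APO", ]
  npo_all <- cov_data[labs$label == "NPO", ]
  apo_m <- cov_data[match(pairs$apo_id, cov_data$subject_id), ]
  npo_m <- cov_data[match(pairs$npo_id, cov_data$subject_id), ]

  out <- tibble::tibble(
    covariate = model$covariates,
    kind = unname(kinds),
    smd_before = vapply(model$covariates, function(cv) {
      smd(apo_all[[cv]], npo_all[[cv]], kinds[[cv]])
    }, numeric(1)),
    smd_after = vapply(model$covariates, function(cv) {
      if (nrow(apo_m) == 0) return(NA_real_)
      smd(apo_m[[cv]], npo_m[[cv]], kinds[[cv]])
    }, numeric(1))
  )
  structure(
    out,
    class = c("balance_report", class(out)),
    auc = model$auc,
    brier = model$brier,
    n_matched = nrow(pairs)
  )
}

#' @method glance balance_report
#' @export
glance.balance_report <- function(x, ...) {
  tibble::tibble(
    n_matched = attr(x, "n_matched"),
    auc = attr(x, "auc"),
    brier = attr(x, "brier"),
    max_smd_before = max(x$smd_before),
    max_smd_after = max(x$smd_after),
    balanced = all(x$smd_after < 0.10)
  )
}
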