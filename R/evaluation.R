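#' Administrative censoring at a follow-up horizon
#'
#' Truncates follow-up at `horizon` months after the index surgery: any
#' record with longer observed time is set to the horizon with the event
#' indicator cleared (death beyond the horizon is not observed). The
#' default horizon of 24 months avoids immortal-time bias from differential
#' record completeness.
#'
#' @param cohort a [cohort_table()].
#' @param horizon months of follow-up retained (default 24).
#' @return the censored cohort.
#' @export
censor_at <- function(cohort, horizon = 24) {
  stopifnot(horizon > 0)
  over <- cohort$survival_months > horizon
  cohort$survival_months[over] <- horizon
  cohort$event[over] <- FALSE
  cohort
}

#' Six-month landmark survival labels
#'
#' Classifies each subject as alive at the landmark (followed at least that
#' long), dead before it (death observed earlier), or indeterminate
#' (censored before the landmark, so landmark status cannot be ascertained).
#'
#' @param times follow-up times in months (already censored at the horizon).
#' @param events logical death indicators.
#' @param landmark landmark time in months (default 6).
#' @return character vector of `"alive"`, `"dead"`, `"indeterminate"`.
#' @export
landmark_labels <- function(times, events, landmark = 6) {
  ifelse(times >= landmark, "alive",
         ifelse(events, "dead", "indeterminate"))
}

#' @rdname landmark_labels
#' @param cohort a [cohort_table()].
#' @export
label_6mo <- function(cohort, landmark = 6) {
  landmark_labels(cohort$survival_months, cohort$event, landmark)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (any(labels == "indeterminate")) {
      stop("indeterminate labels must be removed before classification")
    }
    labels <- labels == "alive"
  }
  as.logical(labels)
}

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected pairwise concordance probability: the
#' fraction of (positive, negative) pairs in which the positive subject
#' scores higher, ties counting one half. The curve is evaluated at every
#' midpoint between adjacent distinct scores, plus infinite sentinels, with
#' a subject called positive when its score strictly exceeds the threshold.
#'
#' @param scores numeric score vector (higher = more likely positive).
#' @param labels positive-class indicator: logical, 0/1, or the output of
#'   [landmark_labels()] with `"alive"` as the positive class.
#' @return a `roc_result`: `thresholds` (descending), `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks handle ties as half-concordant pairs
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  s <- sort(unique(scores))
  thresholds <- if (length(s) > 1) {
    c(Inf, rev((s[-1] + s[-length(s)]) / 2), -Inf)
  } else {
    c(Inf, -Inf)
  }
  sens <- vapply(thresholds, function(th) mean(scores[labels] > th), 0)
  spec <- vapply(thresholds, function(th) mean(scores[!labels] <= th), 0)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# Placement values: per-positive mean concordance against all negatives
# (V10) and per-negative against all positives (V01).
placement_values <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two scores measured on the same subjects. The
#' variance of the AUC difference is estimated from the covariance of the
#' placement values (DeLong, DeLong and Clarke-Pearson); this estimate is
#' identical to the grouped delete-one jackknife variance. The test is a
#' two-sided z-test.
#'
#' @param scores_a,scores_b the two score vectors, same subjects.
#' @param labels positive-class indicator (see [roc_auc()]).
#' @return list with `auc_a`, `auc_b`, `auc_diff`, `var_diff`, `z`,
#'   `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- auc_a - auc_b
  if (var_diff <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(auc_a = auc_a, auc_b = auc_b, auc_diff = diff,
       var_diff = var_diff, z = z, p_value = p)
}

#' Youden-optimal classification cutoff
#'
#' Scans the midpoints between adjacent distinct observed scores and
#' returns the cutoff maximizing Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward the smallest cutoff (which maximizes sensitivity,
#' the screening-oriented choice). If all scores are equal the single score
#' value is returned with J = 0.
#'
#' @param roc a `roc_result` from [roc_auc()], or a numeric score vector
#'   (then `labels` must be given).
#' @param labels positive-class indicator, used when `roc` is a score
#'   vector.
#' @return a `cutoff_result`: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(roc, labels = NULL) {
  if (!inherits(roc, "roc_result")) roc <- roc_auc(roc, labels)
  finite <- is.finite(roc$thresholds)
  if (any(finite)) {
    cand <- roc$thresholds[finite]
    sens <- roc$sensitivity[finite]
    spec <- roc$specificity[finite]
  } else {
    # degenerate: a single distinct score; use it as the sole candidate
    cand <- mean(c(utils::head(roc$thresholds, 1),
                   utils::tail(roc$thresholds, 1)))
    cand <- if (is.finite(cand)) cand else 0
    sens <- 0
    spec <- 1
  }
  j <- sens + spec - 1
  best_j <- max(j)
  best <- which(j >= best_j - 1e-12)
  pick <- best[which.min(cand[best])]
  structure(list(cutoff = cand[pick], sensitivity = sens[pick],
                 specificity = spec[pick], youden_j = j[pick]),
            class = "cutoff_result")
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' A subject is called positive when its score strictly exceeds the cutoff:
#' sensitivity = P(score > cutoff | positive), specificity =
#' P(score <= cutoff | negative).
#'
#' @param scores numeric score vector.
#' @param labels positive-class indicator (see [roc_auc()]).
#' @param cutoff classification threshold.
#' @return list with `sensitivity` and `specificity`.
#' @export
sens_spec_at <- function(scores, labels, cutoff) {
  labels <- as_binary_labels(labels)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("both classes must be present")
  }
  list(sensitivity = mean(scores[labels] > cutoff),
       specificity = mean(scores[!labels] <= cutoff))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with tied events
#' handled simultaneously and censored subjects leaving the risk set after
#' their censoring time.
#'
#' @param times follow-up times in months.
#' @param events logical death indicators.
#' @return a `km_curve` data frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at a time point
#'
#' Right-continuous step-function lookup on a Kaplan-Meier curve:
#' `S(t)` is 1 before the first observed time and the last estimate beyond
#' the final one.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t time(s) in months.
#' @return survival probability at each `t`.
#' @export
survival_rate_at <- function(curve, t) {
  stopifnot(all(t >= 0))
  idx <- findInterval(t, curve$time)
  c(1, curve$survival)[idx + 1]
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic on the pooled event
#' times of the two groups.
#'
#' @param times_a,events_a follow-up times and death indicators, group A.
#' @param times_b,events_b follow-up times and death indicators, group B.
#' @return list with `chisq` and `p_value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) > 0, length(times_b) > 0)
  if (sum(events_a) + sum(events_b) == 0) {
    stop("log-rank test undefined: no events in either group")
  }
  time <- c(times_a, times_b)
  event <- as.numeric(c(events_a, events_b))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' at most 25 iterations, convergence tolerance 1e-8), reporting the
#' odds ratio, Wald 95% confidence interval on the log-odds scale, and
#' Wald p-value for each predictor. Complete separation is flagged via the
#' `converged` field and a warning, with the fit still returned.
#'
#' @param design data frame or matrix of predictors (no intercept column;
#'   one is added).
#' @param outcome logical or 0/1 outcome with both classes present.
#' @return a `logistic_fit`: data frame `coefficients` with columns
#'   `term`, `estimate`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, plus a `converged` flag.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  outcome <- as_binary_labels(outcome)
  if (length(unique(outcome)) < 2) stop("outcome is constant")
  const <- vapply(design, function(x) length(unique(x)) < 2, TRUE)
  if (any(const)) {
    stop("constant predictor(s): ",
         paste(names(design)[const], collapse = ", "))
  }
  dat <- cbind(design, .y = as.numeric(outcome))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # IRLS can "converge" on a separated likelihood with the coefficients
  # diverging; treat boundary fitted probabilities or huge log-odds as
  # separation
  separated <- sep_warned ||
    any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  converged <- fit$converged && !separated
  if (!converged) {
    warning("logistic fit did not converge cleanly ",
            "(possible complete separation); estimates are unreliable")
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zcrit <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - zcrit * se)),
    ci_high = exp(unname(est + zcrit * se)),
    p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, converged = converged, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Chi-square test of a contingency table with the Yates rule: continuity
# correction applied to 2x2 tables when any expected count falls below 5.
chisq_with_yates <- function(tab, yates_threshold = 5) {
  expected <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$expected)
  yates <- all(dim(tab) == 2) && any(expected < yates_threshold)
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter), yates = yates)
}

#' Group-wise cohort summary with significance tests
#'
#' Compares patient characteristics across prognostic groups the way a
#' clinical Table 1 does: one-way ANOVA for continuous variables and the
#' chi-square test for categorical ones, with the Yates continuity
#' correction applied to 2x2 tables whenever an expected count is below 5.
#'
#' @param cohort a [cohort_table()].
#' @param group grouping factor, one value per record (e.g. the
#'   `rts_group` column of [score_cohort()] output).
#' @param continuous names of continuous columns to compare.
#' @param categorical names of categorical columns to compare.
#' @return data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, `yates`.
#' @export
summarize_cohort <- function(cohort, group,
                             continuous = c("age", "bmi"),
                             categorical = c("sex", "target_therapy",
                                             "chemotherapy",
                                             "hormone_therapy",
                                             "primary_site")) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  rows <- list()
  for (v in continuous) {
    fit <- stats::aov(cohort[[v]] ~ group)
    s <- summary(fit)[[1]]
    rows[[v]] <- data.frame(variable = v, test = "anova",
                            statistic = s[["F value"]][1],
                            p_value = s[["Pr(>F)"]][1], yates = FALSE,
                            stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(cohort[[v]], group)
    res <- chisq_with_yates(tab)
    rows[[v]] <- data.frame(variable = v, test = "chisq",
                            statistic = res$statistic,
                            p_value = res$p_value, yates = res$yates,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
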