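test_that("administrative censoring truncates follow-up at the horizon", {
  co <- cohort_table(rbind(
    make_record(id = "a", survival_months = 30, event = TRUE),
    make_record(id = "b", survival_months = 10, event = TRUE),
    make_record(id = "c", survival_months = 24, event = FALSE)))
  out <- censor_at(co, 24)
  expect_equal(out$survival_months, c(24, 10, 24))
  expect_equal(out$event, c(FALSE, TRUE, FALSE))
})

test_that("landmark labels separate alive, dead and indeterminate", {
  expect_equal(landmark_labels(c(7, 3, 3, 6), c(FALSE, TRUE, FALSE, FALSE)),
               c("alive", "dead", "indeterminate", "alive"))
  co <- cohort_table(make_record(survival_months = 3, event = FALSE))
  expect_equal(label_6mo(co), "indeterminate")
  expect_error(roc_auc(c(1, 2), c("alive", "indeterminate")),
               "indeterminate")
})

test_that("AUC equals tie-corrected pairwise concordance", {
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  # 4 pos-neg pairs: (2>1)+(3>1)+(2==2 -> 0.5)+(3>2) = 3.5/4
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auc, 0.875)
  expect_equal(brute_auc(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC curve is monotone with sentinel endpoints", {
  set.seed(31)
  s <- round(rnorm(40), 1)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  r <- roc_auc(s, y)
  expect_equal(r$thresholds[1], Inf)
  expect_equal(r$thresholds[length(r$thresholds)], -Inf)
  expect_true(all(diff(r$thresholds) < 0))
  expect_true(all(diff(r$sensitivity) >= 0))  # descending thresholds
  expect_true(all(diff(r$specificity) <= 0))
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$specificity[1], 1)
})

test_that("AUC is rank-based: invariant under increasing transforms", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    s <- sample(0:10, n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    a0 <- roc_auc(s, y)$auc
    expect_equal(roc_auc(exp(s / 3), y)$auc, a0)
    expect_equal(roc_auc(s + 100, y)$auc, a0)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    n <- sample(20:80, 1)
    s <- sample(seq(0, 15, 0.5), n, replace = TRUE)
    y <- rbinom(n, 1, 0.6)
    if (length(unique(y)) < 2) next
    ours <- roc_auc(s, y)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                             quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("paired AUC comparison: degenerate and cross-checked cases", {
  y <- rep(c(0, 1), c(6, 6))
  s <- c(1:6, 4:9)
  same <- compare_auc_paired(s, s, y)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)

  skip_if_not_installed("pROC")
  set.seed(41)
  sa <- rnorm(60)
  y2 <- rbinom(60, 1, plogis(sa))
  if (length(unique(y2)) < 2) y2[1:2] <- c(0, 1)
  sb <- sa + rnorm(60, sd = 2)
  ours <- compare_auc_paired(sa, sb, y2)
  theirs <- pROC::roc.test(pROC::roc(y2, sa, direction = "<", quiet = TRUE),
                           pROC::roc(y2, sb, direction = "<", quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p_value, as.numeric(theirs$p.value), tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(as.numeric(theirs$statistic)),
               tolerance = 1e-9)
})

test_that("informative score beats noise by DeLong and by permutation", {
  set.seed(53)
  n <- 200
  p <- plogis(rnorm(n, sd = 1.5))
  y <- rbinom(n, 1, p)
  noise <- rnorm(n)
  res <- compare_auc_paired(p, noise, y)
  expect_lt(res$p_value, 0.01)

  # permutation oracle: swap the two scores within subjects at random
  fast_auc <- function(s, y) {
    r <- rank(s); m <- sum(y)
    (sum(r[y == 1]) - m * (m + 1) / 2) / (m * (n - m))
  }
  obs <- fast_auc(p, y) - fast_auc(noise, y)
  perm <- replicate(10000, {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, noise, p)
    b <- ifelse(swap, p, noise)
    fast_auc(a, y) - fast_auc(b, y)
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / (1 + length(perm))
  expect_lt(p_perm, 0.01)
})

test_that("Youden cutoff matches the exhaustive midpoint scan", {
  # perfect separation: midpoint 2.5
  r <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)

  # all scores equal: J = 0 at the lone candidate
  r0 <- youden_cutoff(rep(3, 8), rep(c(0, 1), 4))
  expect_equal(r0$youden_j, 0)

  # 8-point constructed set against the brute-force scan
  s8 <- c(1, 2, 2, 3, 5, 5, 6, 9)
  y8 <- c(0, 0, 1, 0, 1, 0, 1, 1)
  ours <- youden_cutoff(s8, y8)
  oracle <- brute_youden(s8, y8)
  expect_equal(ours$cutoff, oracle$cutoff)
  expect_equal(ours$youden_j, oracle$j)

  # random instances, including tie-breaking toward the smallest cutoff
  set.seed(67)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    s <- sample(0:8, n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    ours <- youden_cutoff(s, y)
    oracle <- brute_youden(s, y)
    expect_equal(ours$cutoff, oracle$cutoff)
    expect_equal(ours$youden_j, oracle$j)
    at <- sens_spec_at(s, y, ours$cutoff)
    expect_equal(at$sensitivity, ours$sensitivity)
    expect_equal(at$specificity, ours$specificity)
  }
})

test_that("sensitivity/specificity at a cutoff match a hand tally", {
  s <- c(1, 2, 3, 4)
  y <- c(0, 0, 1, 1)
  expect_equal(sens_spec_at(s, y, 2.5), list(sensitivity = 1,
                                             specificity = 1))
  expect_equal(sens_spec_at(s, y, 0), list(sensitivity = 1,
                                           specificity = 0))
  # 10 subjects, cutoff 5: positives {6,7,3,5} -> 2 of 4 above;
  # negatives {1,4,5,8,2,9} -> 4 of 6 at or below
  s10 <- c(6, 7, 3, 5, 1, 4, 5, 8, 2, 9)
  y10 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  at <- sens_spec_at(s10, y10, 5)
  expect_equal(at$sensitivity, 2 / 4)
  expect_equal(at$specificity, 4 / 6)
  expect_error(sens_spec_at(s10, rep(1, 10), 5), "both classes")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  # no events: survival identically 1
  km0 <- km_estimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$survival == 1))

  # toy: deaths at 2 and (twice) 4, censored at 6
  km <- km_estimate(c(2, 4, 4, 6), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(survival_rate_at(km, 2), 3 / 4)
  expect_equal(survival_rate_at(km, 4), 1 / 4)  # (3/4) * (1/3)
  expect_equal(survival_rate_at(km, 5), 1 / 4)
  expect_equal(survival_rate_at(km, 6), 1 / 4)
  expect_equal(survival_rate_at(km, 0), 1)
  expect_equal(survival_rate_at(km, 100), 1 / 4)  # beyond last time

  # single subject dying at t
  km1 <- km_estimate(3, TRUE)
  expect_equal(survival_rate_at(km1, 3), 0)

  # with no censoring the curve is the empirical survival function
  set.seed(71)
  t <- round(rexp(40, 0.2), 2)
  kme <- km_estimate(t, rep(TRUE, 40))
  for (tt in c(0, 2, 5, 10)) {
    expect_equal(survival_rate_at(kme, tt), mean(t > tt))
  }
})

test_that("log-rank test matches hand-computed O-E tables", {
  # identical groups: statistic 0
  t0 <- c(1, 3, 5)
  z <- logrank_test(t0, c(TRUE, TRUE, TRUE), t0, c(TRUE, TRUE, TRUE))
  expect_equal(z$chisq, 0, tolerance = 1e-12)
  expect_equal(z$p_value, 1, tolerance = 1e-12)

  # 6-subject toy: A dies at 1,3,5; B dies at 2,4,6
  # per event time: E_A = nA/N, V = nA*nB/N^2 (single death each)
  ta <- c(1, 3, 5); tb <- c(2, 4, 6)
  O <- 3
  E <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2 + 0 / 1
  V <- 3 * 3 / 36 + 2 * 3 / 25 + 2 * 2 / 16 + 1 * 2 / 9 + 1 * 1 / 4 + 0
  hand <- (O - E)^2 / V
  res <- logrank_test(ta, rep(TRUE, 3), tb, rep(TRUE, 3))
  expect_equal(res$chisq, hand, tolerance = 1e-8)

  # symmetry under group swap
  swap <- logrank_test(tb, rep(TRUE, 3), ta, rep(TRUE, 3))
  expect_equal(swap$chisq, res$chisq, tolerance = 1e-12)

  expect_error(logrank_test(ta, rep(FALSE, 3), tb, rep(FALSE, 3)),
               "no events")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  x <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
  fit <- fit_logistic(data.frame(exposure = x), y)
  expect_true(fit$converged)
  row <- fit$coefficients[fit$coefficients$term == "exposure", ]
  expect_equal(row$odds_ratio, 6, tolerance = 1e-6)  # (40*30)/(10*20)
  expect_equal(row$estimate, log(6), tolerance = 1e-6)
  expect_equal(row$ci_low, exp(row$estimate - qnorm(0.975) * row$se))
  expect_true(row$ci_low < 6 && 6 < row$ci_high)
})

test_that("logistic fit is near-null for an independent predictor", {
  set.seed(79)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, 0.4)
  fit <- fit_logistic(data.frame(x = x), y)
  expect_lt(abs(fit$coefficients$estimate[fit$coefficients$term == "x"]),
            0.1)
})

test_that("degenerate logistic inputs are rejected or flagged", {
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10)),
               "constant")
  expect_error(fit_logistic(data.frame(x = rep(1, 10)),
                            rep(c(0, 1), 5)), "constant predictor")
  # complete separation: flagged, fit still returned
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(fit <- fit_logistic(data.frame(x = x), y),
                 "converge|separation")
  expect_false(fit$converged)
})

test_that("group summaries run ANOVA and chi-square with the Yates rule", {
  gen <- generate_cohort(cohort_config(n = 171, seed = 13))
  grp <- rts_group(rts_score(gen$cohort))
  out <- summarize_cohort(gen$cohort, grp)
  expect_true(all(c("age", "bmi", "sex") %in% out$variable))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1, na.rm = TRUE))
  expect_equal(out$test[out$variable == "age"], "anova")
  expect_equal(out$test[out$variable == "sex"], "chisq")

  # identical groups: F exactly 0
  co <- make_cohort(6)
  co$age <- rep(c(50, 60, 70), 2)
  out2 <- summarize_cohort(co, rep(c("x", "y"), each = 3),
                           continuous = "age", categorical = character())
  expect_equal(out2$statistic, 0)

  # 2x2 with a small expected count triggers the Yates flag
  co3 <- make_cohort(12)
  co3$sex <- rep(c("male", "female"), c(9, 3))
  out3 <- summarize_cohort(co3, rep(c("x", "y"), 6),
                           continuous = character(), categorical = "sex")
  expect_true(out3$yates)
  expect_error(summarize_cohort(co3, rep("x", 12)), "two groups")
})
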