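#' AUC surface over the (a, b) weight lattice
#'
#' The development objective of the adjusted score: for every candidate
#' weight pair, `ATS = RTS + a * target + b * z_bmi` is computed and its
#' AUC against the six-month landmark outcome is recorded. The search
#' population defaults to prognostic group 1 (RTS <= 8), where the revised
#' score is least accurate; subjects with indeterminate landmark status are
#' excluded.
#'
#' @param cohort a [cohort_table()], already censored at the follow-up
#'   horizon (see [censor_at()]).
#' @param ref a [bmi_reference()].
#' @param a_values,b_values candidate weights, ascending (defaults 1-10).
#' @param population `"group1"` (default) or `"all"`.
#' @param landmark landmark time in months (default 6).
#' @return an `auc_grid`: `a_values`, `b_values`, `auc` matrix (rows = a,
#'   columns = b), `population`, `n`.
#' @export
auc_grid <- function(cohort, ref, a_values = 1:10, b_values = 1:10,
                     population = c("group1", "all"), landmark = 6) {
  population <- match.arg(population)
  stopifnot(!is.unsorted(a_values), !is.unsorted(b_values))
  rts <- rts_score(cohort)
  keep <- if (population == "group1") rts_group(rts) == "g1" else
    rep(TRUE, nrow(cohort))
  lab <- label_6mo(cohort, landmark)
  keep <- keep & lab != "indeterminate"
  if (!any(keep)) stop("empty population after filtering")
  y <- lab[keep] == "alive"
  if (length(unique(y)) < 2) {
    stop("AUC undefined: single outcome class in the ", population,
         " population")
  }
  rts <- rts[keep]
  tgt <- as.numeric(cohort$target_therapy[keep])
  z <- z_bmi(cohort$bmi[keep], cohort$sex[keep], cohort$age[keep], ref)
  auc <- matrix(NA_real_, length(a_values), length(b_values),
                dimnames = list(a = a_values, b = b_values))
  for (i in seq_along(a_values)) {
    for (j in seq_along(b_values)) {
      auc[i, j] <- roc_auc(rts + a_values[i] * tgt + b_values[j] * z, y)$auc
    }
  }
  structure(list(a_values = a_values, b_values = b_values, auc = auc,
                 population = population, n = sum(keep)),
            class = "auc_grid")
}

#' Best weights from an AUC grid
#'
#' Argmax over the grid; ties are broken toward the smaller `a`, then the
#' smaller `b`, and the number of maximizing cells is reported.
#'
#' @param grid an `auc_grid` from [auc_grid()].
#' @return a `best_weights`: `weights` ([score_weights()]), `auc`,
#'   `tie_count`.
#' @export
select_best_weights <- function(grid) {
  stopifnot(inherits(grid, "auc_grid"), length(grid$auc) > 0)
  best <- max(grid$auc)
  hits <- which(grid$auc == best, arr.ind = TRUE)
  # row-major order of which() already favours small a; enforce a then b
  ord <- order(hits[, 1], hits[, 2])
  pick <- hits[ord[1], ]
  structure(list(weights = score_weights(grid$a_values[pick[1]],
                                         grid$b_values[pick[2]]),
                 auc = best, tie_count = nrow(hits)),
            class = "best_weights")
}

#' Write an AUC grid as TSV
#'
#' Rows are `a` values, columns `b` values, cells the AUC to three
#' decimals.
#'
#' @param grid an `auc_grid`.
#' @param path output file path.
#' @param comment optional provenance line written as a leading `#` comment.
#' @export
write_auc_grid <- function(grid, path, comment = NULL) {
  m <- matrix(sprintf("%.3f", grid$auc), nrow = length(grid$a_values))
  df <- data.frame(a = grid$a_values, m, check.names = FALSE)
  names(df) <- c("a", paste0("b=", grid$b_values))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-step six-month survival prediction
#'
#' Step 1 assigns the revised-score prognostic group. Groups 2 and 3
#' (RTS >= 9) are predicted to survive beyond six months outright — the
#' revised score is already about 90% accurate there. Step 2 re-examines
#' group 1 with the adjusted score: survival beyond six months is
#' predicted when ATS exceeds the cutoff.
#'
#' @param cohort a [cohort_table()].
#' @param ref a [bmi_reference()].
#' @param weights a [score_weights()].
#' @param ats_cutoff adjusted-score cutoff for group 1 (default 7.5).
#' @return data frame: `id`, `step1_group`, `ats` (NA outside group 1),
#'   `prediction`.
#' @export
two_step_predict <- function(cohort, ref, weights = score_weights(),
                             ats_cutoff = 7.5) {
  scored <- score_cohort(cohort, ref, weights, ats_cutoff)
  g1 <- scored$rts_group == "g1"
  data.frame(id = scored$id,
             step1_group = scored$rts_group,
             ats = ifelse(g1, scored$ats, NA_real_),
             prediction = ifelse(g1, scored$predicted_6mo, "over_6mo"),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param a_values,b_values weight-search lattice (defaults 1-10).
#' @param search_population `"group1"` (default) or `"all"`.
#' @param ats_cutoff `"auto"` (Youden-optimal on the reference cohort) or
#'   a number.
#' @param horizon_months administrative censoring horizon (default 24).
#' @param landmark_months survival landmark (default 6).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(a_values = 1:10, b_values = 1:10,
                            search_population = "group1",
                            ats_cutoff = "auto",
                            horizon_months = 24, landmark_months = 6) {
  stopifnot(search_population %in% c("group1", "all"),
            identical(ats_cutoff, "auto") ||
              (is.numeric(ats_cutoff) && is.finite(ats_cutoff)),
            horizon_months > 0, landmark_months > 0,
            landmark_months <= horizon_months)
  structure(list(a_values = a_values, b_values = b_values,
                 search_population = search_population,
                 ats_cutoff = ats_cutoff,
                 horizon_months = horizon_months,
                 landmark_months = landmark_months),
            class = "pipeline_config")
}

# AUC of RTS and of ATS plus their paired comparison in one population.
auc_block <- function(rts, ats, y) {
  cmp <- compare_auc_paired(ats, rts, y)
  list(n = length(y), auc_ats = cmp$auc_a, auc_rts = cmp$auc_b,
       auc_diff = cmp$auc_diff, z = cmp$z, p_value = cmp$p_value)
}

evaluate_split <- function(cohort, ref, weights, cutoff, landmark) {
  scored <- score_cohort(cohort, ref, weights, cutoff)
  lab <- label_6mo(cohort, landmark)
  det <- lab != "indeterminate"
  y <- lab[det] == "alive"
  g1 <- scored$rts_group[det] == "g1"
  out <- list(
    n = nrow(cohort),
    n_indeterminate = sum(!det),
    auc_all = auc_block(scored$rts[det], scored$ats[det], y),
    auc_group1 = if (sum(g1) > 1 && length(unique(y[g1])) == 2) {
      auc_block(scored$rts[det][g1], scored$ats[det][g1], y[g1])
    },
    metrics = c(list(cutoff = cutoff),
                sens_spec_at(scored$ats[det], y, cutoff))
  )
  # KM comparison of the ATS strata (all records, censored retained)
  hi <- scored$ats > cutoff
  if (any(hi) && any(!hi)) {
    km_hi <- km_estimate(cohort$survival_months[hi], cohort$event[hi])
    km_lo <- km_estimate(cohort$survival_months[!hi], cohort$event[!hi])
    lr <- tryCatch(
      logrank_test(cohort$survival_months[hi], cohort$event[hi],
                   cohort$survival_months[!hi], cohort$event[!hi]),
      error = function(e) NULL)
    out$km <- list(
      above_cutoff = list(n = sum(hi), curve = as.data.frame(km_hi),
                          s6 = survival_rate_at(km_hi, landmark)),
      below_cutoff = list(n = sum(!hi), curve = as.data.frame(km_lo),
                          s6 = survival_rate_at(km_lo, landmark)),
      logrank = lr)
  }
  out
}

#' Run the score-development pipeline
#'
#' Reproduces the full development sequence on a reference/validation
#' cohort pair: administrative censoring, six-month landmark labeling,
#' exhaustive (a, b) weight search in the reference search population,
#' best-weight selection, Youden cutoff selection on the reference cohort,
#' and frozen-weight evaluation of both cohorts — paired AUC comparison of
#' the adjusted versus revised score (cohort-wide and within group 1),
#' sensitivity/specificity at the cutoff, and Kaplan-Meier curves with a
#' log-rank test for the above-/below-cutoff strata.
#'
#' @param reference reference (development) [cohort_table()].
#' @param validation validation [cohort_table()], or `NULL`.
#' @param ref a [bmi_reference()] covering both cohorts.
#' @param config a [pipeline_config()].
#' @return an `ats_report` list; see the JSON written by [write_report()].
#' @export
run_development_pipeline <- function(reference, validation, ref,
                                     config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(validation) && nrow(validation) > 0 &&
      length(intersect(reference$id, validation$id)) > 0) {
    stop("reference and validation cohorts must be disjoint")
  }
  reference <- censor_at(reference, config$horizon_months)
  grid <- auc_grid(reference, ref, config$a_values, config$b_values,
                   config$search_population, config$landmark_months)
  best <- select_best_weights(grid)
  w <- best$weights

  scored_ref <- score_cohort(reference, ref, w)
  lab_ref <- label_6mo(reference, config$landmark_months)
  det <- lab_ref != "indeterminate"
  cutoff <- if (identical(config$ats_cutoff, "auto")) {
    youden_cutoff(scored_ref$ats[det], lab_ref[det] == "alive")$cutoff
  } else {
    config$ats_cutoff
  }

  report <- list(
    config = unclass(config),
    weights = list(a = w$a, b = w$b, auc = best$auc,
                   tie_count = best$tie_count,
                   search_population = grid$population,
                   n_search = grid$n),
    grid = list(a_values = grid$a_values, b_values = grid$b_values,
                auc = grid$auc),
    cutoff = cutoff,
    reference = evaluate_split(reference, ref, w, cutoff,
                               config$landmark_months),
    notes = paste("Weight search follows the AUC-grid maximum; the grid,",
                  "not prose approximations, is authoritative for the",
                  "selected (a, b) pair.")
  )
  if (is.null(validation) || nrow(validation) == 0) {
    report$validation <- NULL
    report$validation_absent <- TRUE
  } else {
    validation <- censor_at(validation, config$horizon_months)
    report$validation <- tryCatch(
      evaluate_split(validation, ref, w, cutoff, config$landmark_months),
      error = function(e) list(failed = conditionMessage(e)))
  }
  structure(report, class = "ats_report")
}

#' Write a pipeline report as JSON
#'
#' @param report an `ats_report` from [run_development_pipeline()], or any
#'   list-like evaluation report.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
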