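#' Score weights for the adjusted Tokuhashi score
#'
#' The adjusted score is `ATS = RTS + a * target_therapy + b * z_bmi`:
#' `a` points are added when the patient receives molecularly targeted
#' therapy and the sex- and age-standardized BMI Z-score enters with
#' multiplier `b`. The published weights are `a = 4`, `b = 1`.
#'
#' @param a points added for target-therapy use (>= 0).
#' @param b multiplier on the BMI Z-score (>= 0).
#' @return a `score_weights` object.
#' @export
score_weights <- function(a = 4, b = 1) {
  stopifnot(is.finite(a), is.finite(b), a >= 0, b >= 0)
  structure(list(a = a, b = b), class = "score_weights")
}

#' Revised Tokuhashi score (RTS)
#'
#' Sums the point values of the six rubric domains: general condition,
#' extraspinal metastatic foci, vertebral-body metastases, visceral
#' metastases, primary tumour site, and palsy. Five domains score 0-2 and
#' the primary site 0-5, so the total lies in 0-15 (15 = best prognosis).
#'
#' @param record a patient record: a list, one-row data frame, or
#'   [cohort_table()] (vectorized over rows).
#' @return integer score(s) in `[0, 15]`.
#' @export
rts_score <- function(record) {
  doms <- rts_domains()
  total <- 0L
  for (dom in names(doms)) {
    val <- record[[dom]]
    if (is.null(val) || any(is.na(val))) {
      stop("rubric domain missing: ", dom)
    }
    pts <- doms[[dom]][as.character(val)]
    if (any(is.na(pts))) {
      stop("unknown category for domain ", dom, ": ",
           paste(unique(val[is.na(pts)]), collapse = ", "))
    }
    total <- total + unname(pts)
  }
  total
}

#' Prognostic group from the revised Tokuhashi score
#'
#' Scores of 8 or less predict survival under 6 months (group `g1`),
#' 9-11 form the intermediate group `g2`, and 12 or more predict survival
#' of at least a year (group `g3`).
#'
#' @param rts integer score(s) in `[0, 15]`.
#' @return character vector of `"g1"`, `"g2"`, `"g3"`.
#' @export
rts_group <- function(rts) {
  if (any(is.na(rts)) || any(rts < 0 | rts > 15)) {
    stop("RTS must lie in [0, 15]")
  }
  ifelse(rts <= 8, "g1", ifelse(rts <= 11, "g2", "g3"))
}

#' Population-standardized BMI Z-score
#'
#' Standardizes a patient's BMI against the general-population mean and SD
#' for their sex and age band: `(bmi - mean) / sd`.
#'
#' @param bmi body-mass index, kg/m2 (vectorized).
#' @param sex `"male"` or `"female"` (recycled).
#' @param age age in years (recycled).
#' @param ref a [bmi_reference()] covering every (sex, age) supplied.
#' @return numeric Z-score(s).
#' @export
z_bmi <- function(bmi, sex, age, ref) {
  stopifnot(inherits(ref, "bmi_reference"))
  n <- max(length(bmi), length(sex), length(age))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- ref$sex == sex[i] & ref$age_min <= age[i] & ref$age_max >= age[i]
    if (sum(hit) != 1) {
      stop("BMI reference does not cover sex=", sex[i], " age=", age[i])
    }
    out[i] <- (bmi[i] - ref$mean[hit]) / ref$sd[hit]
  }
  out
}

#' Adjusted Tokuhashi score (ATS)
#'
#' `ATS = RTS + a * target_therapy + b * z`, with target-therapy use coded
#' 1 and no use 0. Because the Z-score is unbounded the result may fall
#' below 0 or exceed 15.
#'
#' @param rts revised Tokuhashi score(s).
#' @param target_therapy logical, target-therapy use.
#' @param z BMI Z-score(s) from [z_bmi()].
#' @param weights a [score_weights()] (default: the published `a=4, b=1`).
#' @return numeric adjusted score(s).
#' @export
ats_score <- function(rts, target_therapy, z, weights = score_weights()) {
  stopifnot(inherits(weights, "score_weights"))
  rts + weights$a * as.numeric(target_therapy) + weights$b * z
}

#' Six-month survival prediction from the adjusted score
#'
#' Predicts survival of at least six months when the score strictly exceeds
#' the cutoff. The recommended cutoff is 7.5; the half-integer makes the
#' strict/non-strict boundary choice immaterial for integer-valued scores.
#' An alternative convention places the boundary at 8 (scores above 8
#' predict survival beyond six months), matching the revised-score rule.
#'
#' @param ats adjusted score(s).
#' @param cutoff classification threshold (default 7.5).
#' @return character vector of `"over_6mo"` / `"under_6mo"`.
#' @export
classify_6mo <- function(ats, cutoff = 7.5) {
  stopifnot(is.finite(cutoff))
  ifelse(ats > cutoff, "over_6mo", "under_6mo")
}

#' Score every patient in a cohort
#'
#' Applies [rts_score()], [rts_group()], [z_bmi()], [ats_score()] and
#' [classify_6mo()] to each record.
#'
#' @param cohort a [cohort_table()].
#' @param ref a [bmi_reference()] covering all records.
#' @param weights a [score_weights()].
#' @param cutoff classification threshold for the 6-month prediction.
#' @return data frame with columns `id`, `rts`, `rts_group`, `z_bmi`,
#'   `ats`, `predicted_6mo`, in the input record order.
#' @export
score_cohort <- function(cohort, ref, weights = score_weights(),
                         cutoff = 7.5) {
  stopifnot(inherits(cohort, "cohort_table"))
  rts <- rts_score(cohort)
  z <- tryCatch(z_bmi(cohort$bmi, cohort$sex, cohort$age, ref),
                error = function(e) {
                  # rerun per record to name the offender
                  for (i in seq_len(nrow(cohort))) {
                    tryCatch(z_bmi(cohort$bmi[i], cohort$sex[i],
                                   cohort$age[i], ref),
                             error = function(e2) {
                               stop("record ", cohort$id[i], ": ",
                                    conditionMessage(e2), call. = FALSE)
                             })
                  }
                  stop(e)
                })
  ats <- ats_score(rts, cohort$target_therapy, z, weights)
  data.frame(id = cohort$id,
             rts = rts,
             rts_group = rts_group(rts),
             z_bmi = z,
             ats = ats,
             predicted_6mo = classify_6mo(ats, cutoff),
             stringsAsFactors = FALSE)
}

#' Write scored patients to CSV
#'
#' @param scored output of [score_cohort()].
#' @param path output file path.
#' @param comment optional provenance line written as a leading `#` comment.
#' @export
write_scored <- function(scored, path, comment = NULL) {
  out <- scored
  out$z_bmi <- sprintf("%.3f", out$z_bmi)
  out$ats <- sprintf("%.3f", out$ats)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
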