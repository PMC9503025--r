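# Domain vocabulary: the six rubric domains of the revised Tokuhashi score,
# each mapping a category token to its point value. Five domains score 0-2;
# the primary tumour site scores 0-5 (tier0 = lung/osteosarcoma/stomach/...,
# tier5 = thyroid/prostate/breast/carcinoid), making the maximum total 15.
rts_domains <- function() {
  list(
    general_condition = c(poor = 0L, moderate = 1L, good = 2L),
    extraspinal_foci  = c(three_plus = 0L, one_two = 1L, none = 2L),
    vertebral_mets    = c(three_plus = 0L, two = 1L, one = 2L),
    visceral_mets     = c(unremovable = 0L, removable = 1L, none = 2L),
    primary_site      = c(tier0 = 0L, tier1 = 1L, tier2 = 2L,
                          tier3 = 3L, tier4 = 4L, tier5 = 5L),
    palsy             = c(complete = 0L, incomplete = 1L, none = 2L)
  )
}

patient_columns <- function() {
  c("id", "age", "sex", "height", "weight", "bmi",
    "general_condition", "extraspinal_foci", "vertebral_mets",
    "visceral_mets", "primary_site", "palsy",
    "target_therapy", "chemotherapy", "hormone_therapy",
    "survival_months", "event")
}

#' Construct a validated cohort table
#'
#' A cohort table is a data frame of patient records: demographics, the six
#' Tokuhashi rubric domains, adjuvant-therapy flags, and follow-up
#' (`survival_months` from index surgery plus the death indicator `event`).
#' Validation enforces the record invariants: adult age, positive BMI
#' consistent with height/weight when both are recorded (within 0.1 kg/m2),
#' recognized category tokens in every rubric domain, non-negative follow-up,
#' and unique ids.
#'
#' @param records data frame with the columns listed in [patient_columns()].
#'   `height` and `weight` may be `NA` (BMI is the authoritative field);
#'   therapy flags and `event` are logical (or 0/1).
#' @param strict if `TRUE` (default) any invalid row aborts; if `FALSE`
#'   offending rows are dropped with a message giving the count.
#' @param provenance free-text note on where the records came from
#'   (file path or generator seed).
#' @return the validated records as a `cohort_table` (a data frame).
#' @export
cohort_table <- function(records, strict = TRUE, provenance = "in-memory") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(patient_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, patient_columns()]
  for (col in c("target_therapy", "chemotherapy", "hormone_therapy", "event")) {
    records[[col]] <- as_flag(records[[col]], col)
  }
  records$age <- as.integer(records$age)

  bad <- validate_patient_rows(records)
  if (any(bad != "")) {
    n_bad <- sum(bad != "")
    detail <- utils::head(paste0("row ", which(bad != ""), " (id ",
                                 records$id[bad != ""], "): ",
                                 bad[bad != ""]), 5)
    if (strict) {
      stop("invalid patient record(s):\n  ", paste(detail, collapse = "\n  "))
    }
    message("dropping ", n_bad, " invalid record(s)")
    records <- records[bad == "", , drop = FALSE]
  }
  if (anyDuplicated(records$id)) stop("patient ids must be unique")
  rownames(records) <- NULL
  structure(records, class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

# One message per offending row ("" = valid); first violation wins.
validate_patient_rows <- function(df) {
  msg <- character(nrow(df))
  flag <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    msg[msg == "" & cond] <<- text
  }
  flag(is.na(df$id) | df$id == "", "missing id")
  flag(is.na(df$age) | df$age < 18, "age below 18 (pediatric exclusion)")
  flag(!(df$sex %in% c("male", "female")), "unknown sex token")
  flag(is.na(df$bmi) | df$bmi <= 0, "bmi missing or non-positive")
  hw <- !is.na(df$height) & !is.na(df$weight)
  bmi_hw <- ifelse(hw, df$weight / (df$height / 100)^2, df$bmi)
  flag(hw & abs(df$bmi - bmi_hw) > 0.1, "bmi inconsistent with height/weight")
  for (dom in names(rts_domains())) {
    flag(!(df[[dom]] %in% names(rts_domains()[[dom]])),
         paste0("unknown ", dom, " token"))
  }
  flag(is.na(df$survival_months) | df$survival_months < 0,
       "negative or missing survival_months")
  flag(is.na(df$target_therapy) | is.na(df$chemotherapy) |
         is.na(df$hormone_therapy) | is.na(df$event),
       "missing therapy flag or event indicator")
  msg
}

as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c(1, "1", "TRUE", "true")] <- TRUE
  out[x %in% c(0, "0", "FALSE", "false")] <- FALSE
  if (any(is.na(out) & !is.na(x))) {
    stop("column ", name, ": boolean values must be coded 0/1")
  }
  out
}

#' Read a patient table from CSV
#'
#' The file dialect: lower-case header exactly as [patient_columns()],
#' booleans coded 0/1, empty cells for the optional `height`/`weight`.
#' Lines starting with `#` are treated as comments (provenance headers).
#'
#' @param path CSV file path.
#' @param strict abort on any invalid row (`TRUE`, default) or drop
#'   offending rows with a message (`FALSE`).
#' @return a [cohort_table()].
#' @export
read_patients <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("patient file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  missing_cols <- setdiff(patient_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("patient CSV ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("age", "height", "weight", "bmi", "survival_months")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  cohort_table(df, strict = strict, provenance = path)
}

#' Write a patient table to CSV
#'
#' Inverse of [read_patients()]: `read_patients(write_patients(x))` reproduces
#' `x` field for field. Booleans are written as 0/1 and missing
#' height/weight as empty cells.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @param comment optional provenance line written as a leading `#` comment.
#' @export
write_patients <- function(cohort, path, comment = NULL) {
  df <- as.data.frame(cohort)
  for (col in c("target_therapy", "chemotherapy", "hormone_therapy", "event")) {
    df[[col]] <- as.integer(df[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a BMI population reference
#'
#' Holds the mean and standard deviation of BMI in the general population
#' for each sex and age band, the constants behind the Z-BMI transform.
#' Bands are closed integer-year intervals; for each sex they must be
#' disjoint and jointly cover ages 18 to 120, and every SD must be positive.
#'
#' @param entries data frame with columns `sex`, `age_min`, `age_max`,
#'   `mean`, `sd`.
#' @return a `bmi_reference` (a data frame).
#' @export
bmi_reference <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("sex", "age_min", "age_max", "mean", "sd")
  if (!all(need %in% names(entries))) {
    stop("BMI reference needs columns: ", paste(need, collapse = ", "))
  }
  entries <- entries[, need]
  for (col in need[-1]) entries[[col]] <- as.numeric(entries[[col]])
  if (!all(entries$sex %in% c("male", "female"))) {
    stop("BMI reference sex must be 'male' or 'female'")
  }
  if (any(is.na(entries$sd)) || any(entries$sd <= 0)) {
    stop("BMI reference SD must be positive in every band")
  }
  for (s in unique(entries$sex)) {
    b <- entries[entries$sex == s, ]
    b <- b[order(b$age_min), ]
    if (any(b$age_max < b$age_min)) stop("empty age band for sex ", s)
    if (b$age_min[1] > 18) stop("BMI reference for ", s,
                                " does not cover age 18")
    if (nrow(b) > 1) {
      lo <- b$age_min[-1]
      hi <- b$age_max[-nrow(b)]
      if (any(lo <= hi)) {
        stop("overlapping age bands for sex ", s, " at age ",
             min(lo[lo <= hi]))
      }
      if (any(lo > hi + 1)) stop("age-band gap for sex ", s)
    }
    if (max(b$age_max) < 120) stop("BMI reference for ", s,
                                   " does not cover up to age 120")
  }
  structure(entries, class = c("bmi_reference", "data.frame"))
}

#' Read a BMI population reference from CSV
#'
#' @param path CSV with columns `sex,age_min,age_max,mean,sd`.
#' @return a validated [bmi_reference()].
#' @export
read_bmi_reference <- function(path) {
  if (!file.exists(path)) stop("BMI reference file not found: ", path)
  bmi_reference(utils::read.csv(path, stringsAsFactors = FALSE,
                                comment.char = "#"))
}

#' Write a BMI population reference to CSV
#'
#' @param ref a [bmi_reference()].
#' @param path output file path.
#' @param comment optional provenance line written as a leading `#` comment.
#' @export
write_bmi_reference <- function(ref, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(ref), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "patients (",
      sum(x$event), "deaths ) —", attr(x, "provenance"), "\n")
  NextMethod()
}
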