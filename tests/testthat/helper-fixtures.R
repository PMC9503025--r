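# Fixtures are built in code; oracles here are deliberately naive
# (brute-force loops) and independent of the package's implementations.

# Strip class and provenance so tables can be compared field for field.
as_plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

make_record <- function(...) {
  rec <- list(id = "p1", age = 60, sex = "male",
              height = NA_real_, weight = NA_real_, bmi = 23,
              general_condition = "moderate", extraspinal_foci = "one_two",
              vertebral_mets = "two", visceral_mets = "removable",
              primary_site = "tier2", palsy = "incomplete",
              target_therapy = FALSE, chemotherapy = TRUE,
              hormone_therapy = FALSE, survival_months = 10, event = TRUE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(n = 3, ...) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(id = sprintf("p%d", i), ...)
  }))
  cohort_table(rows, provenance = "test fixture")
}

flat_ref <- function(mean = 23, sd = 3) {
  bmi_reference(data.frame(sex = c("male", "female"),
                           age_min = 18, age_max = 120,
                           mean = mean, sd = sd))
}

# AUC as an explicit double loop over all positive-negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Grouped delete-one jackknife variance of auc(a) - auc(b), recomputing
# both AUCs from scratch with the brute-force oracle at every deletion.
jackknife_var_diff <- function(sa, sb, y) {
  y <- as.logical(y)
  theta <- function(sa, sb, y) brute_auc(sa, y) - brute_auc(sb, y)
  pos <- which(y)
  neg <- which(!y)
  tp <- vapply(pos, function(i) theta(sa[-i], sb[-i], y[-i]), 0)
  tn <- vapply(neg, function(j) theta(sa[-j], sb[-j], y[-j]), 0)
  (length(pos) - 1) / length(pos) * sum((tp - mean(tp))^2) +
    (length(neg) - 1) / length(neg) * sum((tn - mean(tn))^2)
}

# Exhaustive Youden scan over all midpoints between distinct scores.
brute_youden <- function(scores, labels) {
  y <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  best <- NULL
  for (cut in cand) {
    sens <- mean(scores[y] > cut)
    spec <- mean(scores[!y] <= cut)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutoff = cut, sens = sens, spec = spec, j = j)
    }
  }
  best
}
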