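#' Diagnostic accuracy at one cutoff
#'
#' Dichotomises the score at `cutoff` (positive iff score >= cutoff) and
#' returns the 2x2 counts with sensitivity, specificity, PPV and NPV plus
#' proportion confidence intervals (Wilson score interval by default).
#' A predictive value with an empty denominator (no test-positives or no
#' test-negatives) is reported as NA, not 0.
#'
#' @param scores numeric score per patient.
#' @param labels logical outcome per patient.
#' @param cutoff integer cutoff.
#' @param ci_method `"wilson"` (default), `"exact"` or `"wald"`.
#' @param conf confidence level (default 0.95).
#' @return one-row data frame with columns `cutoff`, `tp`, `fp`, `fn`,
#'   `tn`, and `sensitivity`, `specificity`, `ppv`, `npv` each with
#'   `_lo`/`_hi` CI bounds.
#' @export
accuracy_at_cutoff <- function(scores, labels, cutoff,
                               ci_method = "wilson", conf = 0.95) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    stop("labels contain a single class", call. = FALSE)
  }
  pos <- scores >= cutoff
  tp <- sum(pos & labels)
  fp <- sum(pos & !labels)
  fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels)
  metric <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(k / n, prop_ci(k, n, ci_method, conf))
  }
  sens <- metric(tp, tp + fn)
  spec <- metric(tn, tn + fp)
  ppv <- metric(tp, tp + fp)
  npv <- metric(tn, tn + fn)
  data.frame(cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = sens[1], sensitivity_lo = sens[2],
             sensitivity_hi = sens[3],
             specificity = spec[1], specificity_lo = spec[2],
             specificity_hi = spec[3],
             ppv = ppv[1], ppv_lo = ppv[2], ppv_hi = ppv[3],
             npv = npv[1], npv_lo = npv[2], npv_hi = npv[3])
}

#' Per-cutoff accuracy table with c-statistic and DeLong comparison
#'
#' Builds the published-table shape for one score and one outcome: the
#' c-statistic with its DeLong 95% CI, a paired DeLong p-value against a
#' reference score (the ED qSOFA by convention), and one accuracy row per
#' cutoff (1..3 for a single-stage qSOFA, 1..6 for the combined score).
#'
#' @param cohort scored, labeled cohort data frame.
#' @param score_col score column name (`"qsofa_pre"`, `"qsofa_ed"`,
#'   `"qsofa_combined"`).
#' @param outcome_col outcome column name (`"sepsis"`, `"septic_shock"`,
#'   `"in_hospital_mortality"`).
#' @param cutoffs integer cutoffs; default 1..3 or 1..6 by score range.
#'   May be empty (the AUC is still computed).
#' @param reference_col score to compare against with DeLong's test; NULL
#'   (or the score itself) suppresses the comparison.
#' @param ci_method proportion-CI method, see [accuracy_at_cutoff()].
#' @return object of class `accuracy_table`: `score`, `outcome`, `auc`
#'   (an `auc_estimate`), `delong_p`, and `metrics` (data frame, one row
#'   per cutoff).
#' @export
accuracy_table <- function(cohort, score_col, outcome_col,
                           cutoffs = NULL,
                           reference_col = "qsofa_ed",
                           ci_method = "wilson") {
  scores <- cohort[[score_col]]
  labels <- as.logical(cohort[[outcome_col]])
  if (is.null(cutoffs)) {
    cutoffs <- seq_len(if (max(scores) > 3) 6L else 3L)
  }
  auc <- roc_auc(scores, labels)
  delong_p <- NA_real_
  if (!is.null(reference_col) && reference_col != score_col) {
    delong_p <- delong_test(scores, cohort[[reference_col]], labels)$p
  }
  metrics <- do.call(rbind, lapply(cutoffs, function(ct) {
    accuracy_at_cutoff(scores, labels, ct, ci_method)
  }))
  structure(list(score = score_col, outcome = outcome_col, auc = auc,
                 delong_p = delong_p,
                 metrics = metrics %||% data.frame()),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("%s predicting %s\n", x$score, x$outcome))
  cat(sprintf("  c-statistic %.2f (95%% CI %.2f-%.2f)",
              x$auc$auc, x$auc$ci95[["lo"]], x$auc$ci95[["hi"]]))
  if (!is.na(x$delong_p)) cat(sprintf(", DeLong p vs reference %.3g", x$delong_p))
  cat("\n")
  if (nrow(x$metrics)) {
    fmt <- function(p, lo, hi) sprintf("%.2f (%.2f-%.2f)", p, lo, hi)
    m <- x$metrics
    out <- data.frame(
      cutoff = paste0(">= ", m$cutoff),
      sensitivity = fmt(m$sensitivity, m$sensitivity_lo, m$sensitivity_hi),
      specificity = fmt(m$specificity, m$specificity_lo, m$specificity_hi),
      ppv = fmt(m$ppv, m$ppv_lo, m$ppv_hi),
      npv = fmt(m$npv, m$npv_lo, m$npv_hi)
    )
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Score-transition table between stages
#'
#' Tabulates prehospital qSOFA (0-3) by ED qSOFA (0-3) by outcome — the
#' counts behind an alluvial view of score changes between stages.
#'
#' @param cohort scored, labeled cohort.
#' @param outcome_col outcome column name.
#' @return object of class `transition_table`: `counts` (a 4 x 4 x 2
#'   array, dimensions prehospital score, ED score, outcome) and `long`
#'   (the same counts as a long-format data frame).
#' @export
transition_table <- function(cohort, outcome_col = "sepsis") {
  counts <- table(
    pre = factor(cohort$qsofa_pre, levels = 0:3),
    ed = factor(cohort$qsofa_ed, levels = 0:3),
    outcome = factor(as.logical(cohort[[outcome_col]]),
                     levels = c(FALSE, TRUE))
  )
  long <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(long) <- c("pre_score", "ed_score", "outcome", "n")
  structure(list(counts = counts, long = long, outcome = outcome_col),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Score transitions (prehospital x ED) by %s; n = %d\n",
              x$outcome, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Patients captured by the combined score but missed by the ED score
#'
#' Counts outcome-positive patients who are positive on the combined
#' qSOFA (score >= `combined_cutoff`) yet negative on the ED qSOFA
#' (score < `ed_cutoff`) — the added screening capture of carrying the
#' prehospital score forward.
#'
#' @param cohort scored, labeled cohort.
#' @param outcome_col outcome column name.
#' @param ed_cutoff ED positivity cutoff (default 2).
#' @param combined_cutoff combined positivity cutoff (default 3).
#' @return list: `count`, `n_outcome_positive`, `fraction` (NA with a
#'   warning when there are no outcome-positive patients).
#' @export
added_capture <- function(cohort, outcome_col = "sepsis",
                          ed_cutoff = 2, combined_cutoff = 3) {
  pos <- as.logical(cohort[[outcome_col]])
  n_pos <- sum(pos)
  captured <- pos & cohort$qsofa_combined >= combined_cutoff &
    cohort$qsofa_ed < ed_cutoff
  count <- sum(captured)
  if (n_pos == 0) {
    warning("no outcome-positive patients; fraction undefined")
    fraction <- NA_real_
  } else {
    fraction <- count / n_pos
  }
  list(count = count, n_outcome_positive = n_pos, fraction = fraction)
}
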