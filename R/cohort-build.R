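#' Suspected-infection inclusion rule
#'
#' A record is a suspected-infection case if the chief complaint is fever,
#' the ED body temperature is at or above the fever threshold (inclusive),
#' or an infection was diagnosed at the ED.  A missing body temperature
#' simply fails the temperature clause.
#'
#' @param cohort data frame with columns `chief_complaint_fever`, `ed_bt`,
#'   `ed_infection_diagnosis` (and `pre_bt` if `bt_stage` involves the
#'   prehospital stage).
#' @param bt_threshold fever threshold in degrees Celsius (default 37.5).
#' @param bt_stage which stage's body temperature can satisfy the fever
#'   clause: `"ed"` (default), `"pre"`, or `"either"`.
#' @return logical vector, one element per record.
#' @export
flag_suspected_infection <- function(cohort, bt_threshold = 37.5,
                                     bt_stage = c("ed", "pre", "either")) {
  bt_stage <- match.arg(bt_stage)
  bt_hot <- function(x) !is.na(x) & x >= bt_threshold
  hot <- switch(bt_stage,
                ed = bt_hot(cohort$ed_bt),
                pre = bt_hot(cohort$pre_bt),
                either = bt_hot(cohort$ed_bt) | bt_hot(cohort$pre_bt))
  cohort$chief_complaint_fever | hot | cohort$ed_infection_diagnosis
}

vital_cols <- function(stage) {
  paste0(stage, "_", c("sbp", "dbp", "hr", "rr", "bt", "gcs", "spo2"))
}

#' Count missing vital-sign parameters at one stage
#'
#' Counts NA entries among the seven vital parameters (sBP, dBP, HR, RR,
#' BT, GCS, SpO2) at the given stage; a missing GCS counts as missing AMS.
#'
#' @param cohort data frame holding the stage vital columns.
#' @param stage `"pre"` or `"ed"`.
#' @return integer vector of counts in 0..7.
#' @export
count_missing_vitals <- function(cohort, stage) {
  if (!stage %in% c("pre", "ed")) {
    stop('`stage` must be "pre" or "ed"', call. = FALSE)
  }
  cols <- vital_cols(stage)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort lacks vital columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rowSums(is.na(as.matrix(cohort[cols])))
}

# Fixed exclusion precedence.  Only the attributed reason (not cohort
# membership) depends on this order.
exclusion_reasons <- c("age_under_18", "no_suspected_infection", "trauma",
                       "cardiac_arrest", "died_on_arrival",
                       "transferred_out", "insufficient_vitals")

#' Eligibility decision per record
#'
#' Applies the study gates in a fixed precedence order: age < 18, no
#' suspected infection, trauma, cardiac arrest, death on arrival, transfer
#' to another hospital, and six or more missing vital parameters (out of
#' seven) at either stage.  The first matching reason is attributed.
#'
#' @inheritParams flag_suspected_infection
#' @param min_age inclusive adult age boundary (default 18).
#' @param max_missing_vitals a stage with strictly more than this many
#'   missing vitals (default 5, i.e. six or more missing) is excluded.
#' @return character vector: `"eligible"` or the exclusion reason.
#' @export
apply_exclusions <- function(cohort, min_age = 18, max_missing_vitals = 5,
                             bt_threshold = 37.5, bt_stage = "ed") {
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  claim <- function(reason_vec, cond, r) {
    reason_vec[is.na(reason_vec) & cond] <- r
    reason_vec
  }
  reason <- claim(reason, cohort$age < min_age, "age_under_18")
  reason <- claim(reason,
                  !flag_suspected_infection(cohort, bt_threshold, bt_stage),
                  "no_suspected_infection")
  reason <- claim(reason, cohort$trauma, "trauma")
  reason <- claim(reason, cohort$cardiac_arrest, "cardiac_arrest")
  reason <- claim(reason, cohort$died_on_arrival, "died_on_arrival")
  reason <- claim(reason, cohort$transferred_out, "transferred_out")
  too_few <- count_missing_vitals(cohort, "pre") > max_missing_vitals |
    count_missing_vitals(cohort, "ed") > max_missing_vitals
  reason <- claim(reason, too_few, "insufficient_vitals")
  reason[is.na(reason)] <- "eligible"
  reason
}

#' Build the eligible cohort with a flow accounting
#'
#' Applies [apply_exclusions()] and returns the eligible records together
#' with a flow summary in which every input record is counted exactly once
#' (either as eligible or under its first matching exclusion reason).
#'
#' @inheritParams apply_exclusions
#' @return a list of class `cohort_build`: `cohort` (the eligible records),
#'   and `flow` with `n_input`, `n_excluded_by_reason` (named integer
#'   vector) and `n_eligible`.
#' @export
build_cohort <- function(cohort, min_age = 18, max_missing_vitals = 5,
                         bt_threshold = 37.5, bt_stage = "ed") {
  if (anyDuplicated(cohort$id)) {
    stop("duplicate patient ids in input", call. = FALSE)
  }
  decision <- apply_exclusions(cohort, min_age, max_missing_vitals,
                               bt_threshold, bt_stage)
  excl <- table(factor(decision, levels = exclusion_reasons))
  flow <- list(
    n_input = nrow(cohort),
    n_excluded_by_reason = stats::setNames(as.integer(excl),
                                           exclusion_reasons),
    n_eligible = sum(decision == "eligible")
  )
  stopifnot(flow$n_input == flow$n_eligible + sum(flow$n_excluded_by_reason))
  eligible <- cohort[decision == "eligible", , drop = FALSE]
  rownames(eligible) <- NULL
  structure(list(cohort = eligible, flow = flow), class = "cohort_build")
}

#' @export
print.cohort_build <- function(x, ...) {
  f <- x$flow
  cat(sprintf("Screened records: %d\n", f$n_input))
  for (r in names(f$n_excluded_by_reason)) {
    k <- f$n_excluded_by_reason[[r]]
    if (k > 0) cat(sprintf("  excluded, %s: %d\n", gsub("_", " ", r), k))
  }
  cat(sprintf("Eligible suspected-infection cohort: %d\n", f$n_eligible))
  invisible(x)
}
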