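#' qSOFA component thresholds
#'
#' The quick Sequential Organ Failure Assessment awards one point each for
#' hypotension (systolic BP at or below `sbp_max` mmHg), tachypnea
#' (respiratory rate at or above `rr_min` /min) and altered mental status
#' (GCS at or below `gcs_max`).  All boundaries are inclusive.
#'
#' @param sbp_max hypotension threshold, mmHg (default 100).
#' @param rr_min tachypnea threshold, breaths/min (default 22).
#' @param gcs_max altered-mental-status threshold on the GCS (default 14).
#' @return named list of thresholds.
#' @export
qsofa_thresholds <- function(sbp_max = 100, rr_min = 22, gcs_max = 14) {
  list(sbp_max = sbp_max, rr_min = rr_min, gcs_max = gcs_max)
}

#' Score qSOFA at one stage
#'
#' Computes the component indicators and the 0-3 total from fully observed
#' (post-imputation) vitals.  Missing values in any required vital are a
#' precondition error naming the field.
#'
#' @param sbp,rr,gcs numeric vectors of systolic BP (mmHg), respiratory
#'   rate (/min), and GCS (3-15).
#' @param thresholds see [qsofa_thresholds()].
#' @return data frame with logical columns `hypotension`, `tachypnea`,
#'   `ams` and integer `total`.
#' @export
score_qsofa <- function(sbp, rr, gcs, thresholds = qsofa_thresholds()) {
  for (nm in c("sbp", "rr", "gcs")) {
    x <- get(nm)
    if (anyNA(x)) {
      stop(sprintf("`%s` contains missing values; impute before scoring", nm),
           call. = FALSE)
    }
  }
  hypotension <- sbp <= thresholds$sbp_max
  tachypnea <- rr >= thresholds$rr_min
  ams <- gcs <= thresholds$gcs_max
  data.frame(hypotension = hypotension, tachypnea = tachypnea, ams = ams,
             total = as.integer(hypotension) + as.integer(tachypnea) +
               as.integer(ams))
}

#' Combine prehospital and ED qSOFA totals
#'
#' The combined qSOFA is the sum of the prehospital and ED totals
#' (range 0-6).
#'
#' @param pre_total,ed_total integer vectors of stage totals in 0..3.
#' @return data frame with `prehospital_total`, `ed_total`, `combined`.
#' @export
combine_qsofa <- function(pre_total, ed_total) {
  stopifnot(all(pre_total %in% 0:3), all(ed_total %in% 0:3))
  data.frame(prehospital_total = as.integer(pre_total),
             ed_total = as.integer(ed_total),
             combined = as.integer(pre_total + ed_total))
}

#' Dichotomise a score at a cutoff
#'
#' Positive if and only if the score is greater than or equal to the
#' cutoff.
#'
#' @param score integer score vector.
#' @param cutoff integer cutoff.
#' @param max_score admissible maximum (3 for a single-stage qSOFA, 6 for
#'   the combined score).
#' @return logical vector.
#' @export
classify_qsofa <- function(score, cutoff, max_score = 6) {
  if (any(score < 0 | score > max_score, na.rm = TRUE)) {
    stop(sprintf("score outside admissible range [0, %d]", max_score),
         call. = FALSE)
  }
  score >= cutoff
}

#' Attach qSOFA columns to a cohort
#'
#' Adds per-stage component booleans plus `qsofa_pre`, `qsofa_ed` and
#' `qsofa_combined`.  All 6 required vitals (sBP, RR, GCS at both stages)
#' must be complete; run the imputer first if they are not.
#'
#' @param cohort data frame with stage vital columns.
#' @param thresholds see [qsofa_thresholds()].
#' @return the cohort with the score columns appended.
#' @export
add_qsofa <- function(cohort, thresholds = qsofa_thresholds()) {
  pre <- score_qsofa(cohort$pre_sbp, cohort$pre_rr, cohort$pre_gcs, thresholds)
  ed <- score_qsofa(cohort$ed_sbp, cohort$ed_rr, cohort$ed_gcs, thresholds)
  cohort$pre_hypotension <- pre$hypotension
  cohort$pre_tachypnea <- pre$tachypnea
  cohort$pre_ams <- pre$ams
  cohort$ed_hypotension <- ed$hypotension
  cohort$ed_tachypnea <- ed$tachypnea
  cohort$ed_ams <- ed$ams
  cohort$qsofa_pre <- pre$total
  cohort$qsofa_ed <- ed$total
  cohort$qsofa_combined <- pre$total + ed$total
  cohort
}
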