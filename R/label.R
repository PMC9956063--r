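#' Thresholds of the clinical surveillance definition of sepsis
#'
#' Rule-based, chart-computable operationalization of Sepsis-3 for
#' retrospective data (the Rhee-style clinical surveillance definition):
#' presumed serious infection — a blood culture obtained plus at least
#' `min_antimicrobial_days` qualifying antimicrobial days — together with
#' at least one acute organ-dysfunction criterion within
#' `window_days` days of the culture day: vasopressor initiation,
#' mechanical-ventilation initiation, lactate at or above
#' `lactate_threshold` mmol/L, creatinine peak at least
#' `creatinine_ratio` times baseline (excluding end-stage renal disease),
#' bilirubin peak at or above `bilirubin_threshold` mg/dL and at least
#' `bilirubin_ratio` times baseline, or a platelet nadir below
#' `platelet_nadir` (10^3/uL) with at least a 50% decline from a baseline
#' of `platelet_baseline_min` or more.  Septic shock additionally requires
#' vasopressor initiation and lactate at or above `shock_lactate`
#' (a Sepsis-3-consistent default).  All boundaries are inclusive.
#'
#' @param min_antimicrobial_days default 4.
#' @param window_days organ-dysfunction window around the culture day
#'   (default 2, i.e. +/- 2 days).
#' @param lactate_threshold mmol/L, default 2.0.
#' @param creatinine_ratio default 2.
#' @param bilirubin_threshold mg/dL, default 2.0.
#' @param bilirubin_ratio default 2.
#' @param platelet_nadir 10^3/uL, default 100.
#' @param platelet_decline fractional decline required, default 0.5.
#' @param platelet_baseline_min default 100.
#' @param shock_lactate mmol/L, default 2.0.
#' @return named list of thresholds.
#' @export
surveillance_config <- function(min_antimicrobial_days = 4,
                                window_days = 2,
                                lactate_threshold = 2.0,
                                creatinine_ratio = 2,
                                bilirubin_threshold = 2.0,
                                bilirubin_ratio = 2,
                                platelet_nadir = 100,
                                platelet_decline = 0.5,
                                platelet_baseline_min = 100,
                                shock_lactate = 2.0) {
  list(min_antimicrobial_days = min_antimicrobial_days,
       window_days = window_days,
       lactate_threshold = lactate_threshold,
       creatinine_ratio = creatinine_ratio,
       bilirubin_threshold = bilirubin_threshold,
       bilirubin_ratio = bilirubin_ratio,
       platelet_nadir = platelet_nadir,
       platelet_decline = platelet_decline,
       platelet_baseline_min = platelet_baseline_min,
       shock_lactate = shock_lactate)
}

in_window <- function(day, bc_day, window) {
  !is.na(day) & !is.na(bc_day) & abs(day - bc_day) <= window
}

#' Label sepsis from ICU-course fields
#'
#' Vectorized over a cohort; records without an ICU course (`icu` FALSE or
#' NA) are labeled FALSE with no criteria.
#'
#' @param cohort data frame with the ICU-course columns produced by
#'   [generate_cohort()] (`icu`, `bc_day`, `abx_days`, `vaso`, `vaso_day`,
#'   `vent`, `vent_day`, `lactate_max`, `lactate_day`, `cr_base`,
#'   `cr_peak`, `bili_base`, `bili_peak`, `plt_base`, `plt_nadir`,
#'   `esrd`).
#' @param config see [surveillance_config()].
#' @return data frame with logical `sepsis` and character `criteria_met`
#'   (comma-separated rule identifiers).
#' @export
label_sepsis <- function(cohort, config = surveillance_config()) {
  num_cols <- c("abx_days", "lactate_max", "cr_base", "cr_peak",
                "bili_base", "bili_peak", "plt_base", "plt_nadir")
  for (cl in intersect(num_cols, names(cohort))) {
    if (any(cohort[[cl]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative values in `%s`", cl), call. = FALSE)
    }
  }
  has_course <- !is.na(cohort$icu) & cohort$icu
  infection <- has_course & !is.na(cohort$bc_day) &
    !is.na(cohort$abx_days) &
    cohort$abx_days >= config$min_antimicrobial_days

  tf <- function(x) !is.na(x) & x  # NA-safe logical
  w <- config$window_days
  crit <- list(
    vasopressor = tf(cohort$vaso) & in_window(cohort$vaso_day,
                                              cohort$bc_day, w),
    ventilation = tf(cohort$vent) & in_window(cohort$vent_day,
                                              cohort$bc_day, w),
    lactate = !is.na(cohort$lactate_max) &
      cohort$lactate_max >= config$lactate_threshold &
      in_window(cohort$lactate_day, cohort$bc_day, w),
    creatinine = !tf(cohort$esrd) & !is.na(cohort$cr_peak) &
      !is.na(cohort$cr_base) & cohort$cr_base > 0 &
      cohort$cr_peak >= config$creatinine_ratio * cohort$cr_base,
    bilirubin = !is.na(cohort$bili_peak) & !is.na(cohort$bili_base) &
      cohort$bili_peak >= config$bilirubin_threshold &
      cohort$bili_peak >= config$bilirubin_ratio * cohort$bili_base,
    platelets = !is.na(cohort$plt_nadir) & !is.na(cohort$plt_base) &
      cohort$plt_base >= config$platelet_baseline_min &
      cohort$plt_nadir < config$platelet_nadir &
      cohort$plt_nadir <= (1 - config$platelet_decline) * cohort$plt_base
  )
  any_dysfunction <- Reduce(`|`, crit)
  sepsis <- infection & any_dysfunction

  crit_mat <- do.call(cbind, crit)
  criteria_met <- vapply(seq_len(nrow(cohort)), function(i) {
    if (!sepsis[i]) return("")
    paste(c("infection", names(crit)[crit_mat[i, ]]), collapse = ",")
  }, character(1))
  data.frame(sepsis = sepsis, criteria_met = criteria_met,
             stringsAsFactors = FALSE)
}

#' Label septic shock
#'
#' Septic shock requires the sepsis label plus vasopressor initiation and
#' a peak lactate at or above the shock threshold.
#'
#' @inheritParams label_sepsis
#' @param sepsis logical vector of sepsis labels (computed if omitted).
#' @return logical vector.
#' @export
label_septic_shock <- function(cohort, config = surveillance_config(),
                               sepsis = NULL) {
  if (is.null(sepsis)) sepsis <- label_sepsis(cohort, config)$sepsis
  tf <- function(x) !is.na(x) & x
  sepsis & tf(cohort$vaso) & !is.na(cohort$lactate_max) &
    cohort$lactate_max >= config$shock_lactate
}

#' Label a cohort with all three outcomes
#'
#' Applies the surveillance definition for sepsis and septic shock and
#' passes the recorded disposition through as in-hospital mortality, with
#' a prevalence summary.
#'
#' @inheritParams label_sepsis
#' @return a list of class `labeled_cohort`: `cohort` with columns
#'   `sepsis`, `septic_shock`, `in_hospital_mortality`, `criteria_met`
#'   appended, and `summary` (counts and percentages per outcome).
#' @export
label_cohort <- function(cohort, config = surveillance_config()) {
  lab <- label_sepsis(cohort, config)
  cohort$sepsis <- lab$sepsis
  cohort$septic_shock <- label_septic_shock(cohort, config, lab$sepsis)
  cohort$in_hospital_mortality <- !is.na(cohort$died_in_hospital) &
    cohort$died_in_hospital
  cohort$criteria_met <- lab$criteria_met
  n <- nrow(cohort)
  counts <- c(sepsis = sum(cohort$sepsis),
              septic_shock = sum(cohort$septic_shock),
              in_hospital_mortality = sum(cohort$in_hospital_mortality))
  summary <- data.frame(
    outcome = names(counts),
    n = as.integer(counts),
    pct = if (n > 0) round(100 * counts / n) else rep(NA_real_, 3),
    row.names = NULL
  )
  structure(list(cohort = cohort, summary = summary),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("Labeled cohort: %d patients\n", nrow(x$cohort)))
  print(x$summary)
  invisible(x)
}
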