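#' Simulation configuration for synthetic suspected-infection cohorts
#'
#' `sim_config()` assembles and validates every parameter of the synthetic
#' cohort generator; `default_config()` returns the calibrated defaults.
#'
#' The defaults emulate the marginal structure of a real suspected-infection
#' ED cohort of ambulance-transported adults: outcome prevalences of 15%
#' sepsis, 6% septic shock and 9% in-hospital mortality; continuous vitals
#' drawn from truncated normal distributions located at the reference
#' cohort's medians with scale IQR/1.349; altered mental status (AMS,
#' GCS <= 14) marginal probabilities of 47% (prehospital) and 45% (ED); and
#' per-variable, per-stage missingness at the reference cohort's rates
#' (2%-33%).  Latent sepsis shifts each vital by `sepsis_shift` (scaled by
#' `shock_shift_mult` for septic shock), calibrated so that at the default
#' settings the combined qSOFA reaches a c-statistic of about 0.68 for
#' sepsis, with the prehospital and ED scores near 0.65 and 0.67.
#'
#' @param n_patients number of eligible patients to generate.
#' @param sepsis_prev,shock_prev,mortality_prev marginal outcome
#'   probabilities; septic shock is drawn as a subset of sepsis, so
#'   `shock_prev <= sepsis_prev` is required.
#' @param stage_correlation latent Gaussian-copula correlation in `[0, 1]`
#'   between a patient's prehospital and ED value of the same vital.
#' @param vital_params data frame with columns `stage`, `vital`, `median`,
#'   `iqr_lo`, `iqr_hi`, `lower`, `upper` for the six continuous vitals at
#'   each stage (the non-sepsis stratum location/scale).
#' @param sepsis_shift named list (`pre`, `ed`) of additive shifts applied
#'   to latent sepsis cases, one named entry per continuous vital.
#' @param shock_shift_mult multiplier on `sepsis_shift` (and on the AMS
#'   logit shift) for septic-shock cases.
#' @param ams_base named list (`pre`, `ed`): AMS probability for non-sepsis
#'   patients.
#' @param ams_shift named list (`pre`, `ed`): additive logit shift of the
#'   AMS probability for latent sepsis cases.
#' @param missingness_rates named list (`pre`, `ed`) of per-vital missing
#'   probabilities (keys `sbp`, `dbp`, `hr`, `rr`, `bt`, `gcs`, `spo2`).
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`; under MAR the
#'   missingness odds are multiplied by `mar_odds_factor` for patients with
#'   ED AMS, then rescaled to preserve the marginal rate.
#' @param mar_odds_factor odds multiplier used when `missing_mechanism`
#'   is `"MAR"`.
#' @param label_sensitivity,label_specificity fidelity with which the
#'   generated ICU-course fields encode the latent sepsis state: with
#'   probability `1 - label_sensitivity` a latent sepsis case receives a
#'   course that fails the surveillance rule, and with probability
#'   `1 - label_specificity` a non-sepsis ICU patient receives a
#'   qualifying course.  The defaults (1, 1) make the surveillance labeler
#'   recover the latent state exactly.
#' @param icu_admission_nonsepsis probability that a non-sepsis patient has
#'   an ICU course at all (all latent sepsis cases do).
#' @param oxygen_therapy_prev probability of oxygen therapy on ED arrival.
#' @param p_male probability of male sex.
#' @param age_median,age_iqr_lo,age_iqr_hi,age_min,age_max age distribution
#'   (truncated normal on the same median/IQR parameterisation).
#' @param exclusion_rates named numeric vector of injection rates for
#'   records that the cohort builder must exclude (names
#'   `age_under_18`, `no_suspected_infection`, `trauma`, `cardiac_arrest`,
#'   `died_on_arrival`, `transferred_out`); all zero by default so the
#'   default cohort is fully eligible.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#'
#' @return an object of class `sim_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_patients = 2407L,
                       sepsis_prev = 0.15,
                       shock_prev = 0.06,
                       mortality_prev = 0.09,
                       stage_correlation = 0.8,
                       vital_params = default_vital_params(),
                       sepsis_shift = default_sepsis_shift(),
                       shock_shift_mult = 1.6,
                       ams_base = list(pre = 0.445, ed = 0.42),
                       ams_shift = list(pre = 0.65, ed = 0.65),
                       missingness_rates = default_missingness_rates(),
                       missing_mechanism = c("MCAR", "MAR"),
                       mar_odds_factor = 2,
                       label_sensitivity = 1,
                       label_specificity = 1,
                       icu_admission_nonsepsis = 0.5,
                       oxygen_therapy_prev = 0.3,
                       p_male = 0.58,
                       age_median = 78, age_iqr_lo = 67, age_iqr_hi = 85,
                       age_min = 18, age_max = 105,
                       exclusion_rates = c(age_under_18 = 0,
                                           no_suspected_infection = 0,
                                           trauma = 0, cardiac_arrest = 0,
                                           died_on_arrival = 0,
                                           transferred_out = 0),
                       seed = 1L) {
  assert_count(n_patients, "n_patients")
  assert_prob(sepsis_prev, "sepsis_prev")
  assert_prob(shock_prev, "shock_prev")
  assert_prob(mortality_prev, "mortality_prev")
  assert_prob(stage_correlation, "stage_correlation")
  if (shock_prev > sepsis_prev) {
    stop("`shock_prev` cannot exceed `sepsis_prev` (shock is a subset of sepsis)",
         call. = FALSE)
  }
  missing_mechanism <- match.arg(missing_mechanism)
  for (st in c("pre", "ed")) {
    assert_prob(ams_base[[st]], paste0("ams_base$", st))
    for (v in names(missingness_rates[[st]])) {
      assert_prob(missingness_rates[[st]][[v]],
                  paste0("missingness_rates$", st, "$", v))
    }
  }
  assert_prob(label_sensitivity, "label_sensitivity")
  assert_prob(label_specificity, "label_specificity")
  for (nm in names(exclusion_rates)) assert_prob(exclusion_rates[[nm]], nm)
  need <- c("stage", "vital", "median", "iqr_lo", "iqr_hi", "lower", "upper")
  if (!all(need %in% names(vital_params))) {
    stop("`vital_params` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    sepsis_prev = sepsis_prev, shock_prev = shock_prev,
    mortality_prev = mortality_prev,
    stage_correlation = stage_correlation,
    vital_params = vital_params,
    sepsis_shift = sepsis_shift, shock_shift_mult = shock_shift_mult,
    ams_base = ams_base, ams_shift = ams_shift,
    missingness_rates = missingness_rates,
    missing_mechanism = missing_mechanism,
    mar_odds_factor = mar_odds_factor,
    label_sensitivity = label_sensitivity,
    label_specificity = label_specificity,
    icu_admission_nonsepsis = icu_admission_nonsepsis,
    oxygen_therapy_prev = oxygen_therapy_prev,
    p_male = p_male,
    age_median = age_median, age_iqr_lo = age_iqr_lo,
    age_iqr_hi = age_iqr_hi, age_min = age_min, age_max = age_max,
    exclusion_rates = exclusion_rates,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_config <- function() sim_config()

#' Default continuous-vital location/scale parameters
#'
#' Medians and IQRs of the six continuous vitals at each stage, matching
#' the reference suspected-infection cohort's marginals (SpO2, which the
#' reference summary does not tabulate, uses a clinically typical 96%
#' median).  `lower`/`upper` are physiologic truncation bounds.
#'
#' @return data frame, one row per (stage, vital).
#' @export
default_vital_params <- function() {
  rbind(
    data.frame(stage = "pre",
               vital = c("sbp", "dbp", "hr", "rr", "bt", "spo2"),
               median = c(138, 78, 100, 24, 37.5, 96),
               iqr_lo = c(118, 65, 85, 20, 36.8, 92),
               iqr_hi = c(160, 93, 115, 26, 38.5, 98),
               lower = c(40, 20, 20, 4, 33, 40),
               upper = c(260, 160, 220, 60, 43, 100)),
    data.frame(stage = "ed",
               vital = c("sbp", "dbp", "hr", "rr", "bt", "spo2"),
               median = c(138, 80, 97, 22, 37.7, 96),
               iqr_lo = c(117, 69, 84, 19, 37.0, 93),
               iqr_hi = c(159, 93, 112, 26, 38.5, 98),
               lower = c(40, 20, 20, 4, 33, 40),
               upper = c(260, 160, 220, 60, 43, 100))
  )
}

#' @rdname default_vital_params
#' @export
default_sepsis_shift <- function() {
  list(
    pre = c(sbp = -10, dbp = -6, hr = 5, rr = 1.8, bt = 0.2, spo2 = -1.3),
    ed  = c(sbp = -12.5, dbp = -6.5, hr = 5, rr = 2.2, bt = 0.2, spo2 = -1.8)
  )
}

#' Default per-vital, per-stage missingness rates
#'
#' Matches the reference cohort's reported proportions of missing vitals
#' (GCS carries the AMS missingness); SpO2, for which no rate is reported,
#' defaults to rates similar to the other continuous vitals.
#'
#' @return named list with elements `pre` and `ed`.
#' @export
default_missingness_rates <- function() {
  list(
    pre = c(sbp = 0.08, dbp = 0.09, hr = 0.02, rr = 0.11, bt = 0.08,
            gcs = 0.02, spo2 = 0.05),
    ed  = c(sbp = 0.04, dbp = 0.05, hr = 0.05, rr = 0.08, bt = 0.04,
            gcs = 0.33, spo2 = 0.04)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_patients: %d  seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  prevalences: sepsis %.3f, shock %.3f, mortality %.3f\n",
              x$sepsis_prev, x$shock_prev, x$mortality_prev))
  cat(sprintf("  stage correlation: %.2f  missingness: %s\n",
              x$stage_correlation, x$missing_mechanism))
  cat(sprintf("  labeler fidelity: sens %.2f / spec %.2f\n",
              x$label_sensitivity, x$label_specificity))
  invisible(x)
}
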