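#' Reference cohort summary counts
#'
#' Printed summary counts of the single-center suspected-infection cohort
#' that the simulator defaults are calibrated to: 2,407 eligible patients
#' out of 10,773 ambulance transports, outcome counts, the prehospital
#' qSOFA score distribution, and the added-capture count (sepsis patients
#' flagged by combined qSOFA >= 3 but missed by ED qSOFA >= 2).  Used for
#' internal consistency checks of the reported percentages.
#'
#' @return named list of integer counts.
#' @export
reference_cohort_counts <- function() {
  list(
    n_screened = 10773L,
    n_eligible = 2407L,
    male = 1393L,
    ams_ed = 1092L,
    ams_pre = 1129L,
    qsofa_pre_distribution = c(`0` = 515L, `1` = 996L, `2` = 746L,
                               `3` = 150L),
    sepsis = 369L,
    septic_shock = 133L,
    in_hospital_mortality = 217L,
    added_capture = 44L
  )
}
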