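# Independent oracles and fixture builders used across the suite.

# Exhaustive case-control pair counting definition of the c-statistic
# (ties counted one half).  Deliberately brute force.
auc_pair_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]
  y <- scores[!labels]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  total / (length(x) * length(y))
}

# Leave-one-out jackknife variance of the AUC.
auc_jackknife_var <- function(scores, labels) {
  n <- length(scores)
  loo <- vapply(seq_len(n), function(i) {
    qsofascreen::roc_auc(scores[-i], labels[-i])$auc
  }, numeric(1))
  (n - 1) / n * sum((loo - mean(loo))^2)
}

zero_missingness <- function() {
  list(pre = c(sbp = 0, dbp = 0, hr = 0, rr = 0, bt = 0, gcs = 0, spo2 = 0),
       ed = c(sbp = 0, dbp = 0, hr = 0, rr = 0, bt = 0, gcs = 0, spo2 = 0))
}

# Small complete synthetic cohort, scored-ready (no missing vitals).
complete_cohort <- function(n = 300, seed = 42, ...) {
  generate_cohort(sim_config(n_patients = n, seed = seed,
                             missingness_rates = zero_missingness(), ...))
}

# Minimal ICU-course record as a one-row data frame, with overrides.
course_record <- function(...) {
  base <- data.frame(
    icu = TRUE, bc_day = 0L, abx_days = 5L,
    vaso = FALSE, vaso_day = NA_integer_,
    vent = FALSE, vent_day = NA_integer_,
    lactate_max = 1.0, lactate_day = 0L,
    cr_base = 0.9, cr_peak = 1.0,
    bili_base = 0.5, bili_peak = 0.6,
    plt_base = 250, plt_nadir = 240,
    esrd = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
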