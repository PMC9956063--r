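#' Generate a synthetic suspected-infection cohort
#'
#' Draws `config$n_patients` patient records with the statistical structure
#' the downstream analysis assumes: latent sepsis / septic shock states,
#' prehospital and ED vitals correlated within patient through a Gaussian
#' copula, AMS as a two-part GCS mixture (15 vs. a 3-14 distribution),
#' ICU-course fields that encode the latent sepsis state for the
#' surveillance labeler, and per-cell missingness (MCAR by default, MAR on
#' ED AMS optionally).  Fully deterministic given the config (including its
#' seed).
#'
#' @param config a [sim_config()] object.
#' @return a data frame with one row per patient.  Columns: `id`, `age`,
#'   `male`; inclusion/exclusion flags (`chief_complaint_fever`,
#'   `ed_infection_diagnosis`, `trauma`, `cardiac_arrest`,
#'   `died_on_arrival`, `transferred_out`); stage vitals `pre_sbp`,
#'   `pre_dbp`, `pre_hr`, `pre_rr`, `pre_bt`, `pre_gcs`, `pre_spo2` and the
#'   `ed_*` counterparts (NA = missing); `oxygen_therapy`; ICU-course
#'   fields (`icu`, `bc_day`, `abx_days`, `vaso`, `vaso_day`, `vent`,
#'   `vent_day`, `lactate_max`, `lactate_day`, `cr_base`, `cr_peak`,
#'   `bili_base`, `bili_peak`, `plt_base`, `plt_nadir`, `esrd`);
#'   `died_in_hospital`; and the latent ground truth `sepsis_true`,
#'   `shock_true`.  The attribute `"injected_exclusions"` records how many
#'   records were given each exclusion reason.
#' @export
generate_cohort <- function(config = default_config()) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config` object", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_patients
  rho <- config$stage_correlation

  ## latent disease state: 0 none, 1 sepsis, 2 septic shock
  sepsis <- stats::runif(n) < config$sepsis_prev
  p_shock_given_sepsis <-
    if (config$sepsis_prev > 0) config$shock_prev / config$sepsis_prev else 0
  shock <- sepsis & stats::runif(n) < p_shock_given_sepsis
  sev <- ifelse(shock, config$shock_shift_mult, ifelse(sepsis, 1, 0))

  age <- qtrunc_norm(stats::runif(n), config$age_median,
                     (config$age_iqr_hi - config$age_iqr_lo) / 1.349,
                     config$age_min, config$age_max)
  age <- floor(age)
  male <- stats::runif(n) < config$p_male

  ## continuous vitals: Gaussian copula between stages, truncated-normal
  ## marginals located at the non-sepsis stratum plus a severity shift
  vp <- config$vital_params
  vitals <- list()
  for (v in c("sbp", "dbp", "hr", "rr", "bt", "spo2")) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    for (st in c("pre", "ed")) {
      row <- vp[vp$stage == st & vp$vital == v, ]
      sd <- (row$iqr_hi - row$iqr_lo) / 1.349
      mu <- row$median + config$sepsis_shift[[st]][[v]] * sev
      z <- if (st == "pre") z1 else z2
      x <- qtrunc_norm(stats::pnorm(z), mu, sd, row$lower, row$upper)
      digits <- if (v == "bt") 1L else 0L
      vitals[[paste0(st, "_", v)]] <- round(x, digits)
    }
  }

  ## AMS via a correlated latent threshold; GCS two-part mixture
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  gcs_weights <- (1:12)^1.5  # AMS GCS values 3..14, mass toward mild
  for (st in c("pre", "ed")) {
    p_ams <- stats::plogis(stats::qlogis(config$ams_base[[st]]) +
                             config$ams_shift[[st]] * sev)
    z <- if (st == "pre") z1 else z2
    ams <- stats::pnorm(z) < p_ams
    gcs <- ifelse(ams, sample(3:14, n, replace = TRUE, prob = gcs_weights), 15L)
    vitals[[paste0(st, "_gcs")]] <- as.integer(gcs)
  }

  oxygen_therapy <- stats::runif(n) <
    ifelse(sev > 0, pmin(1, config$oxygen_therapy_prev * 1.7),
           config$oxygen_therapy_prev)

  ## inclusion flags; every record carries a flag-based inclusion
  ## criterion (fever complaint or ED infection diagnosis) so that
  ## eligibility is robust to a later-masked body temperature, unless a
  ## "no suspected infection" exclusion is injected
  fever_cc <- stats::runif(n) < 0.5
  inf_dx <- stats::runif(n) < 0.7
  inf_dx[!fever_cc & !inf_dx] <- TRUE

  ## in-hospital mortality: relative risk 1 / 3.6 / 8 by disease state,
  ## baseline solved so the marginal equals mortality_prev
  rr_mort <- c(1, 5, 12)
  grp <- ifelse(shock, 3L, ifelse(sepsis, 2L, 1L))
  w <- (1 - config$sepsis_prev) * rr_mort[1] +
    (config$sepsis_prev - config$shock_prev) * rr_mort[2] +
    config$shock_prev * rr_mort[3]
  p0 <- config$mortality_prev / w
  died <- stats::runif(n) < pmin(1, p0 * rr_mort[grp])

  course <- generate_icu_course(n, sepsis, shock, config)

  cohort <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = age, male = male,
    chief_complaint_fever = fever_cc,
    ed_infection_diagnosis = inf_dx,
    trauma = FALSE, cardiac_arrest = FALSE,
    died_on_arrival = FALSE, transferred_out = FALSE,
    vitals,
    oxygen_therapy = oxygen_therapy,
    course,
    died_in_hospital = died,
    sepsis_true = sepsis, shock_true = shock,
    stringsAsFactors = FALSE
  )

  injected <- inject_exclusions(cohort, config)
  cohort <- injected$cohort
  cohort <- inject_missingness(cohort, config)
  attr(cohort, "injected_exclusions") <- injected$counts
  attr(cohort, "seed") <- config$seed
  cohort
}

# ICU-course fields whose surveillance label matches the latent state with
# the configured sensitivity/specificity.  Only ICU-admitted patients have
# a course (all latent sepsis cases; a fraction of the rest).
generate_icu_course <- function(n, sepsis, shock, config) {
  icu <- sepsis | stats::runif(n) < config$icu_admission_nonsepsis
  qualify <- rep(FALSE, n)
  qualify[sepsis] <- stats::runif(sum(sepsis)) < config$label_sensitivity
  fp <- icu & !sepsis
  qualify[fp] <- stats::runif(sum(fp)) < (1 - config$label_specificity)

  na_r <- rep(NA_real_, n); na_i <- rep(NA_integer_, n)
  na_l <- rep(NA, n)
  out <- data.frame(
    icu = icu, bc_day = na_i, abx_days = na_i,
    vaso = na_l, vaso_day = na_i, vent = na_l, vent_day = na_i,
    lactate_max = na_r, lactate_day = na_i,
    cr_base = na_r, cr_peak = na_r, bili_base = na_r, bili_peak = na_r,
    plt_base = na_r, plt_nadir = na_r, esrd = na_l
  )
  k <- which(icu)
  m <- length(k)
  if (m == 0) return(out)

  out$esrd[k] <- stats::runif(m) < 0.03
  out$bc_day[k] <- sample(0:1, m, replace = TRUE)
  out$cr_base[k] <- round(stats::runif(m, 0.6, 1.2), 2)
  out$bili_base[k] <- round(stats::runif(m, 0.3, 1.0), 2)
  out$plt_base[k] <- round(stats::runif(m, 150, 350))

  q <- which(qualify)          # course must satisfy the surveillance rule
  nq <- setdiff(k, q)          # course must fail it
  if (length(q)) {
    mq <- length(q)
    out$abx_days[q] <- sample(4:10, mq, replace = TRUE)
    out$lactate_day[q] <- out$bc_day[q] + sample(-1:1, mq, replace = TRUE)
    is_shk <- shock[q]
    # shock: vasopressor + lactate >= 2; sepsis without shock: lactate in
    # the dysfunction range but no vasopressor, so the shock rule stays off
    out$lactate_max[q] <- round(ifelse(is_shk, stats::runif(mq, 2.5, 8),
                                       stats::runif(mq, 2.0, 4.0)), 1)
    out$vaso[q] <- is_shk
    out$vaso_day[q] <- ifelse(is_shk,
                              out$bc_day[q] + sample(-1:1, mq, replace = TRUE),
                              NA_integer_)
    out$vent[q] <- stats::runif(mq) < ifelse(is_shk, 0.5, 0.2)
    out$vent_day[q] <- ifelse(out$vent[q],
                              out$bc_day[q] + sample(0:2, mq, replace = TRUE),
                              NA_integer_)
    # extra dysfunction variety: some cases also double creatinine
    dbl <- stats::runif(mq) < 0.3 & !out$esrd[q]
    out$cr_peak[q] <- round(out$cr_base[q] *
                              ifelse(dbl, stats::runif(mq, 2.0, 3.0),
                                     stats::runif(mq, 1.0, 1.6)), 2)
    out$bili_peak[q] <- round(out$bili_base[q] * stats::runif(mq, 1.0, 1.5), 2)
    out$plt_nadir[q] <- round(out$plt_base[q] * stats::runif(mq, 0.7, 1.0))
  }
  if (length(nq)) {
    mn <- length(nq)
    # fail the infection clause (short antimicrobial course) and show no
    # qualifying organ dysfunction
    no_bc <- stats::runif(mn) < 0.3
    out$bc_day[nq][no_bc] <- NA_integer_
    out$abx_days[nq] <- sample(0:3, mn, replace = TRUE)
    out$lactate_max[nq] <- round(stats::runif(mn, 0.5, 1.9), 1)
    out$lactate_day[nq] <- ifelse(is.na(out$bc_day[nq]), 0L, out$bc_day[nq])
    out$vaso[nq] <- FALSE
    out$vent[nq] <- FALSE
    out$cr_peak[nq] <- round(out$cr_base[nq] * stats::runif(mn, 1.0, 1.6), 2)
    out$bili_peak[nq] <- round(out$bili_base[nq] * stats::runif(mn, 1.0, 1.5), 2)
    out$plt_nadir[nq] <- round(out$plt_base[nq] * stats::runif(mn, 0.7, 1.0))
  }
  out
}

# Assign at most one injected exclusion reason per record (rates from
# config$exclusion_rates) and set the fields that trigger it.
inject_exclusions <- function(cohort, config) {
  rates <- config$exclusion_rates
  reasons <- names(rates)
  n <- nrow(cohort)
  u <- stats::runif(n)
  cum <- cumsum(rates)
  pick <- rep(NA_character_, n)
  lo <- 0
  for (i in seq_along(reasons)) {
    pick[u >= lo & u < cum[i]] <- reasons[i]
    lo <- cum[i]
  }
  for (r in reasons) {
    idx <- which(pick == r)
    if (!length(idx)) next
    switch(r,
      age_under_18 = { cohort$age[idx] <- sample(1:17, length(idx), TRUE) },
      no_suspected_infection = {
        cohort$chief_complaint_fever[idx] <- FALSE
        cohort$ed_infection_diagnosis[idx] <- FALSE
        cohort$ed_bt[idx] <- round(stats::runif(length(idx), 36.0, 37.4), 1)
      },
      trauma = { cohort$trauma[idx] <- TRUE },
      cardiac_arrest = { cohort$cardiac_arrest[idx] <- TRUE },
      died_on_arrival = { cohort$died_on_arrival[idx] <- TRUE },
      transferred_out = { cohort$transferred_out[idx] <- TRUE }
    )
  }
  counts <- table(factor(pick, levels = reasons))
  list(cohort = cohort, counts = as.integer(counts) |>
         stats::setNames(reasons))
}

# Mask vitals cell-wise. MCAR by default; under MAR the missingness odds
# are multiplied for patients with ED AMS and rescaled to keep the
# marginal rate.
inject_missingness <- function(cohort, config) {
  mar <- config$missing_mechanism == "MAR"
  w <- if (mar) {
    ifelse(!is.na(cohort$ed_gcs) & cohort$ed_gcs <= 14,
           config$mar_odds_factor, 1)
  } else rep(1, nrow(cohort))
  w <- w / mean(w)
  for (st in c("pre", "ed")) {
    for (v in names(config$missingness_rates[[st]])) {
      rate <- config$missingness_rates[[st]][[v]]
      if (rate <= 0) next
      col <- paste0(st, "_", v)
      miss <- stats::runif(nrow(cohort)) < pmin(1, rate * w)
      cohort[[col]][miss] <- NA
    }
  }
  cohort
}
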