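mk_record <- function(...) {
  base <- as.list(complete_cohort(n = 1, seed = 99))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("suspected-infection rule is an inclusive disjunction", {
  r <- mk_record(chief_complaint_fever = FALSE, ed_infection_diagnosis = FALSE,
                 ed_bt = 37.5)
  expect_true(flag_suspected_infection(r))        # inclusive BT boundary
  r$ed_bt <- 36.8
  expect_false(flag_suspected_infection(r))
  r$chief_complaint_fever <- TRUE
  r$ed_bt <- NA_real_
  expect_true(flag_suspected_infection(r))        # null BT fails only its clause
  r2 <- mk_record(chief_complaint_fever = FALSE, ed_infection_diagnosis = TRUE,
                  ed_bt = NA_real_)
  expect_true(flag_suspected_infection(r2))
  # the BT stage is configurable
  r3 <- mk_record(chief_complaint_fever = FALSE, ed_infection_diagnosis = FALSE,
                  ed_bt = 36.5, pre_bt = 38.2)
  expect_false(flag_suspected_infection(r3, bt_stage = "ed"))
  expect_true(flag_suspected_infection(r3, bt_stage = "either"))
})

test_that("missing-vital counting covers 0 through 7 and validates the stage", {
  r <- mk_record()
  expect_identical(count_missing_vitals(r, "pre"), 0)
  only_hr <- mk_record(pre_sbp = NA, pre_dbp = NA, pre_rr = NA, pre_bt = NA,
                       pre_gcs = NA, pre_spo2 = NA)
  expect_identical(count_missing_vitals(only_hr, "pre"), 6)
  empty <- mk_record(pre_sbp = NA, pre_dbp = NA, pre_hr = NA, pre_rr = NA,
                     pre_bt = NA, pre_gcs = NA, pre_spo2 = NA)
  expect_identical(count_missing_vitals(empty, "pre"), 7)
  expect_error(count_missing_vitals(r, "triage"), "stage")
})

test_that("exclusions attribute the first matching reason in fixed order", {
  r <- mk_record(trauma = TRUE, cardiac_arrest = TRUE)
  expect_identical(apply_exclusions(r), "trauma")
  expect_identical(apply_exclusions(mk_record(age = 17)), "age_under_18")
  expect_identical(apply_exclusions(mk_record(cardiac_arrest = TRUE)),
                   "cardiac_arrest")
  expect_identical(apply_exclusions(mk_record(died_on_arrival = TRUE)),
                   "died_on_arrival")
  expect_identical(apply_exclusions(mk_record(transferred_out = TRUE)),
                   "transferred_out")
  # six missing at one stage is enough, even with the other stage complete
  six_miss <- mk_record(pre_sbp = NA, pre_dbp = NA, pre_rr = NA, pre_bt = NA,
                        pre_gcs = NA, pre_spo2 = NA)
  expect_identical(apply_exclusions(six_miss), "insufficient_vitals")
  five_miss <- mk_record(pre_sbp = NA, pre_dbp = NA, pre_rr = NA, pre_bt = NA,
                         pre_gcs = NA)
  expect_identical(apply_exclusions(five_miss), "eligible")
})

test_that("flow accounting conserves every input record", {
  co <- generate_cohort(sim_config(
    n_patients = 600, seed = 31,
    exclusion_rates = c(age_under_18 = 0.05, no_suspected_infection = 0.08,
                        trauma = 0.04, cardiac_arrest = 0.02,
                        died_on_arrival = 0.01, transferred_out = 0.03)))
  built <- build_cohort(co)
  f <- built$flow
  expect_identical(f$n_input, 600L)
  expect_identical(f$n_input, f$n_eligible + sum(f$n_excluded_by_reason))
  # injected reasons are recovered exactly (the generator records them)
  inj <- attr(co, "injected_exclusions")
  for (r in c("age_under_18", "trauma", "cardiac_arrest", "died_on_arrival",
              "transferred_out")) {
    expect_identical(f$n_excluded_by_reason[[r]], inj[[r]],
                     label = paste("flow count for", r))
  }
  expect_identical(f$n_excluded_by_reason[["no_suspected_infection"]],
                   inj[["no_suspected_infection"]])
})

test_that("build_cohort is idempotent and handles the empty input", {
  co <- generate_cohort(sim_config(n_patients = 300, seed = 32))
  once <- build_cohort(co)
  twice <- build_cohort(once$cohort)
  expect_identical(twice$cohort, once$cohort)
  expect_identical(twice$flow$n_eligible, nrow(once$cohort))

  none <- co[0, ]
  empty <- build_cohort(none)
  expect_identical(empty$flow$n_input, 0L)
  expect_identical(empty$flow$n_eligible, 0L)
  expect_true(all(empty$flow$n_excluded_by_reason == 0L))

  dup <- co[c(1, 1), ]
  expect_error(build_cohort(dup), "duplicate")
})

test_that("the eligible set does not depend on attribution order", {
  co <- generate_cohort(sim_config(
    n_patients = 400, seed = 33,
    exclusion_rates = c(age_under_18 = 0.05, no_suspected_infection = 0.05,
                        trauma = 0.05, cardiac_arrest = 0.05,
                        died_on_arrival = 0.02, transferred_out = 0.05)))
  decision <- apply_exclusions(co)
  eligible <- decision == "eligible"
  # membership equals the conjunction of all gates, regardless of precedence
  gates <- co$age >= 18 & flag_suspected_infection(co) & !co$trauma &
    !co$cardiac_arrest & !co$died_on_arrival & !co$transferred_out &
    count_missing_vitals(co, "pre") <= 5 & count_missing_vitals(co, "ed") <= 5
  expect_identical(eligible, gates)
})
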