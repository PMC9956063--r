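#' Write / read a cohort as delimited text
#'
#' Cohorts travel as plain CSV with empty-string nulls; logical columns
#' are stored as TRUE/FALSE strings and restored on read.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  logical_cols <- c("male", "chief_complaint_fever", "ed_infection_diagnosis",
                    "trauma", "cardiac_arrest", "died_on_arrival",
                    "transferred_out", "oxygen_therapy", "icu", "vaso",
                    "vent", "esrd", "died_in_hospital", "sepsis_true",
                    "shock_true", "sepsis", "septic_shock",
                    "in_hospital_mortality")
  for (cl in intersect(logical_cols, names(df))) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  df
}

#' End-to-end run configuration
#'
#' Exactly one input source: either `simulate` (a [sim_config()]) or
#' `file` (a cohort CSV path).  A single master seed fans out
#' deterministically to the per-stage seeds so each stage is individually
#' reproducible.
#'
#' @param simulate a [sim_config()], or NULL when reading from file.
#' @param file cohort CSV path, or NULL when simulating.
#' @param imputation an [imputation_spec()]; its seed is overridden by
#'   the fan-out of `seed`.
#' @param surveillance a [surveillance_config()].
#' @param thresholds a [qsofa_thresholds()].
#' @param outcomes nonempty subset of `c("sepsis", "septic_shock",
#'   "in_hospital_mortality")`.
#' @param cutoffs named list of integer cutoffs per score.
#' @param ed_cutoff,combined_cutoff positivity rules for the
#'   added-capture statistic.
#' @param outdir output directory for the report bundle, or NULL to keep
#'   results in memory only.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulate = default_config(), file = NULL,
                       imputation = imputation_spec(),
                       surveillance = surveillance_config(),
                       thresholds = qsofa_thresholds(),
                       outcomes = c("sepsis", "septic_shock",
                                    "in_hospital_mortality"),
                       cutoffs = list(qsofa_pre = 1:3, qsofa_ed = 1:3,
                                      qsofa_combined = 1:6),
                       ed_cutoff = 2, combined_cutoff = 3,
                       outdir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(file)) {
    stop("exactly one of `simulate` and `file` must be given", call. = FALSE)
  }
  outcomes <- match.arg(outcomes, c("sepsis", "septic_shock",
                                    "in_hospital_mortality"),
                        several.ok = TRUE)
  if (!length(outcomes)) stop("`outcomes` must be nonempty", call. = FALSE)
  structure(list(simulate = simulate, file = file, imputation = imputation,
                 surveillance = surveillance, thresholds = thresholds,
                 outcomes = outcomes, cutoffs = cutoffs,
                 ed_cutoff = ed_cutoff, combined_cutoff = combined_cutoff,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Accepts a file holding (a subset of) the [run_config()] fields; list
#' entries `simulate`, `imputation`, `surveillance` and `thresholds` are
#' passed to their constructors as arguments.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$simulate)) {
    args$simulate <- do.call(sim_config, as.list(raw$simulate))
  }
  if (!is.null(raw$imputation)) {
    args$imputation <- do.call(imputation_spec, as.list(raw$imputation))
  }
  if (!is.null(raw$surveillance)) {
    args$surveillance <- do.call(surveillance_config, as.list(raw$surveillance))
  }
  if (!is.null(raw$thresholds)) {
    args$thresholds <- do.call(qsofa_thresholds, as.list(raw$thresholds))
  }
  do.call(run_config, args)
}

#' Run the full screening analysis
#'
#' Orchestrates generate/load -> cohort build -> outcome labeling ->
#' vital-sign imputation -> qSOFA scoring -> evaluation, and (optionally)
#' writes the report bundle to `config$outdir`: the cohort flow, the
#' labeled/scored cohort CSV, imputation diagnostics, one accuracy table
#' per requested outcome, the score-transition table, the added-capture
#' summary, and a manifest with the config, seed and package version.
#' Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param quiet suppress the flow log lines (default FALSE).
#' @return a list of class `qsofa_run`: `flow`, `cohort`,
#'   `imputation_diagnostics`, `score_distribution`, `accuracy` (one
#'   `accuracy_table` per score per outcome), `transition`,
#'   `added_capture`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a `run_config`", call. = FALSE)
  }
  raw <- if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- child_seed(config$seed, "simulate")
    generate_cohort(sim)
  } else {
    if (!file.exists(config$file)) {
      stop("input file not found: ", config$file, call. = FALSE)
    }
    read_cohort(config$file)
  }
  need <- c("id", "age", vital_cols("pre"), vital_cols("ed"))
  lacking <- setdiff(need, names(raw))
  if (length(lacking)) {
    stop("input schema mismatch; missing columns: ",
         paste(lacking, collapse = ", "), call. = FALSE)
  }

  built <- build_cohort(raw)
  if (!quiet) print(built)

  labeled <- label_cohort(built$cohort, config$surveillance)
  spec <- config$imputation
  spec$seed <- child_seed(config$seed, "impute")
  imp <- impute_vitals(labeled$cohort, spec)
  cohort <- add_qsofa(imp$cohort, config$thresholds)

  score_distribution <- lapply(
    c(qsofa_pre = "qsofa_pre", qsofa_ed = "qsofa_ed",
      qsofa_combined = "qsofa_combined"),
    function(cl) {
      lv <- if (cl == "qsofa_combined") 0:6 else 0:3
      as.integer(table(factor(cohort[[cl]], levels = lv)))
    })

  accuracy <- list()
  for (outc in config$outcomes) {
    for (sc in names(config$cutoffs)) {
      accuracy[[paste(sc, outc, sep = ".")]] <-
        accuracy_table(cohort, sc, outc, config$cutoffs[[sc]],
                       reference_col = "qsofa_ed")
    }
  }
  transition <- transition_table(cohort, config$outcomes[1])
  capture <- added_capture(cohort, config$outcomes[1],
                           config$ed_cutoff, config$combined_cutoff)

  manifest <- list(
    package = "qsofascreen",
    version = as.character(utils::packageVersion("qsofascreen")),
    seed = config$seed,
    input = if (is.null(config$file)) "simulate" else config$file,
    outcomes = config$outcomes,
    thresholds = config$thresholds,
    surveillance = config$surveillance,
    n_eligible = built$flow$n_eligible
  )
  result <- structure(list(
    flow = built$flow, cohort = cohort,
    imputation_diagnostics = imp$diagnostics,
    score_distribution = score_distribution,
    accuracy = accuracy, transition = transition,
    added_capture = capture, manifest = manifest
  ), class = "qsofa_run")
  if (!is.null(config$outdir)) write_bundle(result, config$outdir)
  result
}

# Serialize a pipeline result to config$outdir (CSV + JSON, text only).
write_bundle <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$flow, file.path(outdir, "cohort_flow.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_cohort(result$cohort, file.path(outdir, "cohort.csv"))
  jsonlite::write_json(result$imputation_diagnostics,
                       file.path(outdir, "imputation_diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(result$accuracy)) {
    at <- result$accuracy[[nm]]
    df <- at$metrics
    df$score <- at$score
    df$outcome <- at$outcome
    df$auc <- at$auc$auc
    df$auc_lo <- at$auc$ci95[["lo"]]
    df$auc_hi <- at$auc$ci95[["hi"]]
    df$delong_p_vs_reference <- at$delong_p
    utils::write.csv(df, file.path(outdir, paste0("accuracy_", nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(result$transition$long,
                   file.path(outdir, "transition_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$added_capture,
                       file.path(outdir, "added_capture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.qsofa_run <- function(x, ...) {
  cat(sprintf("qSOFA screening analysis: %d eligible patients\n",
              x$flow$n_eligible))
  for (nm in names(x$accuracy)) {
    at <- x$accuracy[[nm]]
    cat(sprintf("  %s ~ %s: AUC %.2f (%.2f-%.2f)\n", at$score, at$outcome,
                at$auc$auc, at$auc$ci95[["lo"]], at$auc$ci95[["hi"]]))
  }
  cat(sprintf("  added capture (%s): %d/%d (%.0f%%)\n",
              x$manifest$outcomes[1], x$added_capture$count,
              x$added_capture$n_outcome_positive,
              100 * x$added_capture$fraction))
  invisible(x)
}
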