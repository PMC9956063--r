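#' Specification of the random-forest vital-sign imputation
#'
#' Missing vitals are imputed by iterated conditional modelling: each vital
#' column with missing entries is regressed on all other predictors with a
#' random forest, and the cycle repeats until the normalized change between
#' successive imputations stops decreasing (or `max_iterations` is
#' reached), returning the last improving fill — the missForest stopping
#' rule.  Predictors are age, sex, all fourteen stage vitals, receipt of
#' oxygen therapy and, by default, the outcome labels (sepsis, septic
#' shock, in-hospital mortality): a retrospective analysis has the
#' outcomes in hand at imputation time, and including them is the
#' documented default; set `include_outcomes_as_predictors = FALSE` for
#' leakage-sensitive prospective use.
#'
#' @param n_trees trees per forest (default 100).
#' @param max_iterations maximum imputation cycles (default 10).
#' @param convergence_tol stop early once the normalized change falls at
#'   or below this value (default 0: run until the change increases).
#' @param include_outcomes_as_predictors logical, default TRUE.
#' @param n_datasets number of completed datasets to draw (default 1; the
#'   analysis consumes a single completed dataset, but several can be
#'   generated for sensitivity checks).
#' @param seed integer seed controlling all forests.
#' @return an object of class `imputation_spec`.
#' @export
imputation_spec <- function(n_trees = 100L, max_iterations = 10L,
                            convergence_tol = 0,
                            include_outcomes_as_predictors = TRUE,
                            n_datasets = 1L, seed = 1L) {
  assert_count(n_trees, "n_trees")
  assert_count(max_iterations, "max_iterations")
  assert_count(n_datasets, "n_datasets")
  if (convergence_tol < 0) stop("`convergence_tol` must be >= 0", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 include_outcomes_as_predictors =
                   isTRUE(include_outcomes_as_predictors),
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

imputable_vitals <- function() c(vital_cols("pre"), vital_cols("ed"))

#' Impute missing vital signs
#'
#' Fills every missing entry of the fourteen stage-vital columns by
#' iterated random-forest imputation (see [imputation_spec()]).  Observed
#' values are never modified; imputed continuous values are forest
#' predictions and therefore lie within the observed range of their
#' column; GCS is imputed on its ordinal scale, then rounded and clamped
#' to 3..15.  Deterministic given the spec's seed.
#'
#' @param cohort eligible cohort data frame (every record is expected to
#'   have at most five missing vitals per stage, as guaranteed by
#'   [build_cohort()]).
#' @param spec an [imputation_spec()].
#' @return a list of class `imputation_result`: `cohort` (completed;
#'   a list of data frames if `spec$n_datasets > 1`) and `diagnostics`
#'   (`n_imputed` per column, `iterations`, `change` trajectory).
#' @export
impute_vitals <- function(cohort, spec = imputation_spec()) {
  vitals <- imputable_vitals()
  missing_cols <- setdiff(vitals, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks vital columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (v in vitals) {
    if (!is.numeric(cohort[[v]])) {
      stop(sprintf("vital column `%s` is not numeric", v), call. = FALSE)
    }
    if (all(is.na(cohort[[v]]))) {
      stop(sprintf("vital column `%s` has no observed values and cannot be imputed", v),
           call. = FALSE)
    }
  }
  aux <- c("age", "male", "oxygen_therapy")
  outcomes <- c("sepsis", "septic_shock", "in_hospital_mortality")
  if (spec$include_outcomes_as_predictors) {
    lacking <- setdiff(outcomes, names(cohort))
    if (length(lacking)) {
      stop("outcome predictor columns missing (label the cohort first, or set ",
           "`include_outcomes_as_predictors = FALSE`): ",
           paste(lacking, collapse = ", "), call. = FALSE)
    }
    aux <- c(aux, outcomes)
  }
  aux <- intersect(aux, names(cohort))

  completed <- lapply(seq_len(spec$n_datasets), function(d) {
    run_one_imputation(cohort, vitals, aux, spec,
                       seed = child_seed(spec$seed, paste0("dataset", d)))
  })
  diagnostics <- lapply(completed, attr, "diagnostics")
  cohorts <- lapply(completed, function(x) { attr(x, "diagnostics") <- NULL; x })
  structure(list(
    cohort = if (spec$n_datasets == 1L) cohorts[[1L]] else cohorts,
    diagnostics = if (spec$n_datasets == 1L) diagnostics[[1L]] else diagnostics
  ), class = "imputation_result")
}

run_one_imputation <- function(cohort, vitals, aux, spec, seed) {
  n <- nrow(cohort)
  X <- as.data.frame(lapply(cohort[c(aux, vitals)], as.numeric))
  obs <- !is.na(X[vitals])
  n_missing <- colSums(!obs)
  target <- vitals[n_missing > 0]
  diag_base <- list(n_imputed = stats::setNames(as.integer(n_missing), vitals),
                    iterations = 0L, change = numeric(0))
  if (!length(target) || n == 0) {
    out <- cohort
    attr(out, "diagnostics") <- diag_base
    return(out)
  }
  # initial fill: column mean of the observed values
  for (v in target) {
    X[[v]][is.na(X[[v]])] <- mean(X[[v]], na.rm = TRUE)
  }
  # visit the least-missing columns first, as missForest does
  target <- target[order(n_missing[target])]

  best <- X
  prev_change <- Inf
  changes <- numeric(0)
  iters <- 0L
  for (iter in seq_len(spec$max_iterations)) {
    old <- X
    for (v in target) {
      rows_obs <- obs[, v]
      preds <- setdiff(names(X), v)
      fit <- ranger::ranger(
        x = X[rows_obs, preds, drop = FALSE],
        y = X[rows_obs, v],
        num.trees = spec$n_trees,
        seed = child_seed(seed, paste0(v, iter)),
        num.threads = 1L,
        verbose = FALSE
      )
      X[[v]][!rows_obs] <-
        stats::predict(fit, X[!rows_obs, preds, drop = FALSE])$predictions
    }
    num <- 0; den <- 0
    for (v in target) {
      m <- !obs[, v]
      num <- num + sum((X[[v]][m] - old[[v]][m])^2)
      den <- den + sum(X[[v]][m]^2)
    }
    change <- if (den > 0) num / den else 0
    changes <- c(changes, change)
    iters <- iter
    if (change > prev_change) {  # diverging: keep the previous fill
      X <- old
      break
    }
    best <- X
    prev_change <- change
    if (change <= spec$convergence_tol) break
  }

  out <- cohort
  for (v in vitals) {
    filled <- best[[v]]
    if (grepl("_gcs$", v)) {
      filled <- pmin(15, pmax(3, round(filled)))
    }
    m <- is.na(out[[v]])
    out[[v]][m] <- if (is.integer(out[[v]])) as.integer(round(filled[m])) else filled[m]
  }
  diag_base$iterations <- iters
  diag_base$change <- changes
  attr(out, "diagnostics") <- diag_base
  out
}

#' @export
print.imputation_result <- function(x, ...) {
  d <- x$diagnostics
  if (!is.null(d$n_imputed)) {
    cat(sprintf("Imputation finished in %d iteration(s); %d cell(s) filled\n",
                d$iterations, sum(d$n_imputed)))
  } else {
    cat(sprintf("%d completed datasets\n", length(x$cohort)))
  }
  invisible(x)
}
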