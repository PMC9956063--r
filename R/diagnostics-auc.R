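# Placement values ("structural components") of the Mann-Whitney AUC:
# V10[i] = Pr-hat(case i outranks a random control), ties counted 1/2.
delong_placements <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  if (m < 1 || n < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  V10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  V01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
}

#' C-statistic (ROC AUC) with DeLong variance
#'
#' The c-statistic is computed as the Mann-Whitney pair statistic
#' (probability that a random case outscores a random control, ties
#' counted one half), its variance by DeLong's structural-components
#' method, and the 95% CI as a normal interval clipped to `[0, 1]`.
#'
#' @param scores numeric score per patient (higher = more abnormal).
#' @param labels logical (or 0/1) outcome per patient.
#' @param conf confidence level (default 0.95).
#' @param logit_ci if TRUE, compute the CI on the logit scale and
#'   back-transform (useful near 0 or 1).
#' @return object of class `auc_estimate`: `auc`, `variance`, `ci95`
#'   (`lo`, `hi`), `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95, logit_ci = FALSE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("missing values in scores or labels", call. = FALSE)
  }
  if (all(labels) || !any(labels)) {
    stop("labels contain a single class; AUC is undefined", call. = FALSE)
  }
  pl <- delong_placements(scores, labels)
  variance <- if (pl$m >= 2 && pl$n >= 2) {
    stats::var(pl$V10) / pl$m + stats::var(pl$V01) / pl$n
  } else NA_real_
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(variance)) {
    c(NA_real_, NA_real_)
  } else if (logit_ci && pl$auc > 0 && pl$auc < 1) {
    lg <- stats::qlogis(pl$auc)
    se_lg <- sqrt(variance) / (pl$auc * (1 - pl$auc))
    stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
  } else {
    c(max(0, pl$auc - z * sqrt(variance)),
      min(1, pl$auc + z * sqrt(variance)))
  }
  structure(list(auc = pl$auc, variance = variance,
                 ci95 = c(lo = ci[1], hi = ci[2]),
                 n_cases = pl$m, n_controls = pl$n),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.2f (95%% CI %.2f-%.2f); %d cases / %d controls\n",
              x$auc, x$ci95[["lo"]], x$ci95[["hi"]],
              x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the c-statistics of two scores measured on the same patients,
#' using the DeLong covariance of the paired structural components.
#' Antisymmetric in its first two arguments; comparing a score against
#' itself yields z = 0, p = 1.
#'
#' @param scores_a,scores_b numeric scores on the same patients.
#' @param labels logical outcome per patient.
#' @return list of class `delong_test`: `z`, `p` (two-sided), `auc_a`,
#'   `auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores and labels must all have the same length", call. = FALSE)
  }
  a <- delong_placements(scores_a, labels)
  b <- delong_placements(scores_b, labels)
  if (a$m < 2 || a$n < 2) {
    stop("need at least two cases and two controls", call. = FALSE)
  }
  s10 <- stats::cov(cbind(a$V10, b$V10))
  s01 <- stats::cov(cbind(a$V01, b$V01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  if (v <= .Machine$double.eps) {
    if (abs(a$auc - b$auc) > .Machine$double.eps^0.5) {
      warning("zero DeLong variance with unequal AUCs; reporting p = 1")
    }
    z <- 0
    p <- 1
  } else {
    z <- (a$auc - b$auc) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(z = z, p = p, auc_a = a$auc, auc_b = b$auc),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.3f vs %.3f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}
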