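# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(x)
}

# Quantile of a normal truncated to [lower, upper]; p in [0, 1].
qtrunc_norm <- function(p, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# Wilson score interval for a binomial proportion. Returns c(lo, hi);
# NA for an empty denominator.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# Proportion CI dispatcher (Wilson default; exact = Clopper-Pearson; Wald).
prop_ci <- function(k, n, method = c("wilson", "exact", "wald"), conf = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  switch(method,
    wilson = wilson_ci(k, n, conf),
    exact = as.numeric(stats::binom.test(k, n, conf.level = conf)$conf.int),
    wald = {
      p <- k / n
      z <- stats::qnorm(1 - (1 - conf) / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    })
}

# Derive a reproducible child seed from a master seed and a stage label,
# kept well inside the 32-bit integer range.
child_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.numeric(seed) * 1009 + offs) %% 2147483399)
}
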