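# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string; used to key per-sample RNG streams so
# that adding samples to a design never perturbs existing ones.
.hashString <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a reproducible RNG seed from a master seed and an identifier
#'
#' Each simulated run owns an RNG stream keyed by \code{(seed, id)}, so
#' generated objects are invariant to the presence of other samples in the
#' same design.
#'
#' @param seed Integer master seed.
#' @param id Character identifier (e.g. a sample id or stage name).
#' @return An integer seed strictly below 2^31.
#' @export
deriveSeed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(id),
            length(id) == 1L)
  as.integer(((seed %% 2147483647) * 1000003 + .hashString(id)) %% 2147483647)
}

.assertScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Multiplicative log-normal noise with a given coefficient of variation on the
# linear scale (mean 1). cv = 0 returns exact ones.
.rlnormCV <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Two-sample pooled- or Welch-variance t-test returning a p-value with the
# degenerate conventions used across the package: zero variance in both arms
# with equal means gives p = 1; n < 2 in either arm gives NA with a warning.
.twoSampleP <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than 2 observations in an arm; p-value undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(y, x, var.equal = var_equal)$p.value
}
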