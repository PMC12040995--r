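# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seeds for per-network / per-stage streams.
# Kept below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483587) + 1L
}

# quantile with the linear-interpolation convention (type 7), fixed here so
# the role thresholds do not silently follow a changed global default.
percentile <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < tol)
}

mean_se <- function(x) {
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}
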