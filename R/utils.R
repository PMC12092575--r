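# Internal helpers shared across modules.

# Deterministic substream seed derived from a base seed and integer keys.
# Keeps every derived seed in [0, 2^31 - 2] so set.seed() always accepts it.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in keys) {
    s <- (s * 69069 + as.double(k) * 1013904223 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(ok, msg, class = "odynr_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

# Structured per-stage counters for dropped / flagged items. Stored as an
# attribute so pipelines can surface them in run manifests.
drop_log <- function(n, what) {
  if (n > 0) inform(sprintf("odynr: dropped/flagged %d %s", n, what))
  invisible(n)
}

# Midranks with ties, shared by the rank statistics.
midrank <- function(x) rank(x, ties.method = "average")

# Safe statistics over possibly-empty vectors: empty -> 0 (imputation rule
# used by the feature registry; absence is recoverable from the count
# features).
mean0 <- function(x) if (length(x) == 0) 0 else mean(x)
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
min0 <- function(x) if (length(x) == 0) 0 else min(x)
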