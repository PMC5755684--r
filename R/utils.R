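#' @keywords internal
"_PACKAGE"

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# chi-squared upper-tail p-value plus its log10, robust to underflow
chisq_p <- function(x, df) {
  p <- stats::pchisq(x, df = df, lower.tail = FALSE)
  lg <- stats::pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(p = p, log10p = lg)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps an experiment seed, a stream label and an index to a deterministic
#' integer below 2^31, so that any replicate of a seeded experiment can be
#' regenerated in isolation.
#'
#' @param seed integer experiment seed.
#' @param label character stream label (e.g. `"frequencies"`).
#' @param index integer replicate index (default 0).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + h) %% m
  s <- (s * 48271 + as.double(index) + 1) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
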