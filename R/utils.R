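# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b > a + 1e-12) stop("logdiffexp: negative difference")
  d <- b - a
  if (d >= 0) return(-Inf)
  a + log1p(-exp(d))
}

fold_maf <- function(freq) pmin(freq, 1 - freq)

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

# rank-based inverse normal with offset (r - 0.5)/n, ties averaged
int_values <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}
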