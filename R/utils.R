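# Internal helpers shared across modules.

# Percentile by linear interpolation of order statistics, position
# 1 + p * (n - 1).  This is stats::quantile() type 7; kept as a named
# wrapper so the convention is fixed in one place.
interp_percentile <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 1)
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Tail percentile by the Weibull plotting position p * (n + 1), linearly
# interpolated between order statistics and clamped to [1, n].  Used for
# percentile *cut points*: E[F(x_hat_p)] = p for interior positions
# (F(X_(k)) ~ Beta(k, n + 1 - k) has mean k / (n + 1)), so the expected
# fraction of fresh null samples above the estimated 95th percentile is
# exactly 5%.  The fixed-position convention 1 + p (n - 1) does not have
# this property at small n.
tail_percentile <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 1)
  s <- sort(x)
  n <- length(s)
  pos <- min(max(p * (n + 1), 1), n)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Round half away from zero (so 0.25 -> 0.3 at one decimal), matching
# the way assay reports print percentages.  base::round() rounds half to
# even and would print 12.25 as 12.2.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a scalar probability/fraction.
check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (!allow_zero && x == 0) || (!allow_one && x == 1)) {
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
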