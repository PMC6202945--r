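# Internal numeric helpers shared across feature extractors.

# Evaluate `expr` under a private RNG stream; global .Random.seed untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587) + 1L
}

skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

kurtosis <- function(x) {
  # excess kurtosis
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

iqr_ <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  unname(diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))
}

# Robust slope of y over index 1..n (least squares); NA if degenerate.
ls_slope <- function(y, x = seq_along(y)) {
  ok <- is.finite(y) & is.finite(x)
  if (sum(ok) < 3L) return(c(slope = NA_real_, intercept = NA_real_, tstat = NA_real_))
  x <- x[ok]; y <- y[ok]
  sx <- x - mean(x)
  ssx <- sum(sx^2)
  if (ssx == 0) return(c(slope = NA_real_, intercept = NA_real_, tstat = NA_real_))
  b <- sum(sx * y) / ssx
  a <- mean(y) - b * mean(x)
  r <- y - (a + b * x)
  df <- length(x) - 2L
  s2 <- sum(r^2) / df
  se <- sqrt(s2 / ssx)
  t <- if (se == 0) {
    if (b == 0) 0 else sign(b) * Inf
  } else b / se
  c(slope = b, intercept = a, tstat = t)
}

# Shannon entropy (nats) of a nonnegative weight vector, normalized to [0,1]
# by log(n_ref); n_ref defaults to the number of positive entries, but must
# be the total bin count for histogram entropies (PPE and friends).
norm_entropy <- function(w, n_ref = NULL) {
  w <- w[is.finite(w) & w > 0]
  if (is.null(n_ref)) n_ref <- length(w)
  if (length(w) < 1L || n_ref <= 1L) return(0)
  p <- w / sum(w)
  max(0, -sum(p * log(p)) / log(n_ref))
}

# 10 descriptive statistics used by several extractors
desc_stats10 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(rep(NA_real_, 10L))
  c(mean(x), sd(x), sqrt(mean(x^2)), iqr_(x), skewness(x), kurtosis(x),
    mean(abs(diff(sign(x - mean(x))) != 0)), diff(range(x)),
    mean(abs(x - mean(x))), NA_real_)  # slot 10 (autocorr at fixed lag) filled by caller
}

`%||%` <- function(a, b) if (is.null(a)) b else a
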