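# Internal numerical helpers shared across modules.

deg2rad <- function(x) x * pi / 180

# Signed angular difference wrapped to (-180, 180]. The tuning curve and the
# angular-similarity cosines are symmetric, so the half-open boundary only
# matters for reporting.
wrap_angle <- function(d) {
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Analytic signal via FFT; envelope = Mod(analytic_signal(x)).
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  if (anyNA(x)) stop("analytic_signal() requires a complete (non-NA) series")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Boxcar smoothing with edges padded to the first/last value. `n` is the
# kernel length in samples; even lengths place the extra tap forward in time,
# which cancels in latency differences.
smooth_boxcar <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1L) return(x)
  m <- length(x)
  if (m == 0L) return(x)
  fl <- (n - 1L) %/% 2L
  ce <- n - 1L - fl
  xp <- c(rep(x[1], fl), x, rep(x[m], ce))
  cs <- cumsum(xp)
  (cs[(n):(m + n - 1L)] - c(0, cs[seq_len(m - 1L)])) / n
}

# Symmetric Gaussian smoothing (sd in samples, truncated at +/- trunc sd),
# edges padded to the first/last value.
smooth_gaussian <- function(x, sd_samples, trunc = 3) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(trunc * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  m <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[m], half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + m)])
}

# Indices of strict local maxima; plateaus take their leftmost sample and
# boundary runs are never maxima. NA values break the series.
local_maxima <- function(x) {
  m <- length(x)
  if (m < 3L) return(integer(0))
  xx <- x
  xx[is.na(xx)] <- -Inf
  r <- rle(xx)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L] &
    is.finite(r$values[j])
  starts[j][is_max]
}

# Residuals of a linear fit over the index axis; NA values are ignored in the
# fit and preserved in the output.
detrend_linear <- function(x) {
  idx <- seq_along(x)
  ok <- is.finite(x)
  if (sum(ok) < 2L) return(x - mean(x[ok]))
  fit <- stats::lm.fit(cbind(1, idx[ok]), x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- fit$residuals
  x - (fit$coefficients[1] + fit$coefficients[2] * idx)
}

# Linear interpolation of interior NA runs (used before smoothing histograms
# whose log-transform produced gaps); leading/trailing NAs are kept.
fill_na_linear <- function(x) {
  ok <- which(is.finite(x))
  if (length(ok) < 2L) return(x)
  filled <- x
  inner <- seq(min(ok), max(ok))
  filled[inner] <- stats::approx(ok, x[ok], xout = inner)$y
  filled
}

`%||%` <- function(a, b) if (is.null(a)) b else a
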