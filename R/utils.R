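# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Band-limited resampling by Fourier zero-padding/truncation. Assumes the
# trace is treated as one period; appropriate for epoched sinusoidal data.
resampleTrace <- function(x, fromRate, toRate) {
  n <- length(x)
  m <- max(2L, as.integer(round(n * toRate / fromRate)))
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- floor(min(n, m) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    idx <- seq_len(half)
    Y[1 + idx] <- X[1 + idx]
    Y[m + 1 - idx] <- X[n + 1 - idx]
  }
  # split a shared Nyquist bin symmetrically when truncating an even length
  if (m < n && m %% 2 == 0) {
    nyq <- m / 2
    Y[1 + nyq] <- (X[1 + nyq] + X[n + 1 - nyq]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

# Box-average a trace sampled at `fromRate` into bins at `toRate`.
binToRate <- function(x, fromRate, toRate) {
  n <- length(x)
  dur <- n / fromRate
  m <- max(1L, as.integer(round(dur * toRate)))
  edges <- seq(0, dur, length.out = m + 1)
  t <- (seq_len(n) - 0.5) / fromRate
  idx <- pmin(m, findInterval(t, edges, rightmost.closed = TRUE))
  as.numeric(tapply(x, factor(idx, levels = seq_len(m)), mean))
}

# 'same' convolution of a trace with a kernel whose center index is given
# (defaults to the middle sample). Edges padded with the boundary values.
convolveSame <- function(x, k, center = ceiling(length(k) / 2)) {
  n <- length(x)
  nk <- length(k)
  xp <- c(rep(x[1], nk), x, rep(x[n], nk))
  out <- stats::convolve(xp, rev(k), type = "open")
  # full conv index of x[i] aligned with kernel center:
  start <- nk + center
  out[start:(start + n - 1)]
}

# Causal convolution: output[i] = sum_j k[j] * x[i - j + 1].
convolveCausal <- function(x, k) {
  stats::convolve(x, rev(k), type = "open")[seq_along(x)]
}

# Pearson correlation that returns NA (without error) on zero variance.
safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Shift a trace by `lag` samples toward later times (positive lag delays),
# padding with the edge value.
shiftTrace <- function(x, lag) {
  n <- length(x)
  lag <- as.integer(lag)
  if (lag == 0) return(x)
  if (lag > 0) c(rep(x[1], min(lag, n)), x)[seq_len(n)]
  else c(x, rep(x[n], min(-lag, n)))[(-lag + 1):(-lag + n)]
}

# Sample indices [t0, t1) in seconds relative to epoch onset.
windowIndex <- function(time, t0, t1) which(time >= t0 - 1e-9 & time < t1 - 1e-9)

# First-order exponential low-pass with time constant tau (s); alpha = 0
# (tau = Inf) passes nothing through, returning the initial state.
expLowpass <- function(x, tau, rate, init = 0) {
  if (!is.finite(tau)) return(rep(init, length(x)))
  dt <- 1 / rate
  alpha <- dt / (tau + dt)
  stats::filter(alpha * x, 1 - alpha, method = "recursive",
                init = init)[seq_along(x)]
}
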