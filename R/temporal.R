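# Frequency-domain response analysis: F1 power and phase, GCaMP6f
# attenuation correction, and the AR(1) model used for response-quality
# surrogates.

#' GCaMP6f impulse response kernel
#'
#' Difference-of-exponentials kernel (1 - exp(-t/rise)) * exp(-t/decay),
#' sampled at `rate` and peak-normalized. The default time constants are
#' in-vivo GCaMP6f values (rise 49.5 ms, decay 156 ms); an optional
#' temperature adjustment factor rescales both.
#'
#' @param riseTau,decayTau time constants (s).
#' @param rate sampling rate (Hz).
#' @param duration kernel support (s); a warning is raised below
#'   `5 * decayTau` (truncation).
#' @param tempFactor multiplier applied to both time constants.
#' @return list with `values` (non-negative, peak 1), `rate`, `time`,
#'   `riseTau`, `decayTau`; class `GCaMPKernel`.
#' @export
gcampKernel <- function(riseTau = 0.0495, decayTau = 0.156, rate = 189.4,
                        duration = 2, tempFactor = 1) {
  stopifnot(riseTau > 0, decayTau > 0, rate > 0, duration > 0)
  riseTau <- riseTau * tempFactor
  decayTau <- decayTau * tempFactor
  if (duration < 5 * decayTau)
    warning("kernel duration below 5 decay time constants; truncated tail")
  t <- seq(0, duration, by = 1 / rate)
  k <- (1 - exp(-t / riseTau)) * exp(-t / decayTau)
  structure(list(values = k / max(k), rate = rate, time = t,
                 riseTau = riseTau, decayTau = decayTau),
            class = "GCaMPKernel")
}

#' F1 power of a response trace
#'
#' The trace is resampled (band-limited, Fourier) to `upsampleRate` for
#' enhanced frequency resolution, Fourier transformed, and the power
#' |FFT(X)/N|^2 read out at the stimulus frequency: the single bin when
#' `f1 * duration` is an integer, otherwise the sum of the two nearest bins.
#'
#' @param trace response samples.
#' @param f1 stimulus (fundamental) frequency, Hz; must be below the
#'   acquisition Nyquist frequency.
#' @param rate acquisition rate (Hz).
#' @param upsampleRate analysis rate (Hz).
#' @return F1 power (one-sided bin convention: a sine of amplitude A has
#'   F1 power (A/2)^2).
#' @export
f1Power <- function(trace, f1, rate, upsampleRate = 189.4) {
  if (f1 >= rate / 2)
    stop("f1 must be below the Nyquist frequency of the acquisition rate")
  if (length(trace) < rate / f1)
    stop("trace shorter than one period of f1")
  x <- resampleTrace(trace, rate, upsampleRate)
  m <- length(x)
  dur <- length(trace) / rate
  P <- Mod(stats::fft(x) / m)^2
  fbin <- f1 * dur  # bin index (0-based) of f1
  if (abs(fbin - round(fbin)) < 1e-6) {
    P[1 + round(fbin)]
  } else {
    P[1 + floor(fbin)] + P[1 + ceiling(fbin)]
  }
}

#' Simulated GCaMP6f F1 power for sinusoidal modulation
#'
#' Convolves the GCaMP kernel with full-range sinusoids at the given
#' frequencies (1 s pads at the 0.5 mid-level are appended for stability),
#' runs the identical F1 pipeline on the simulated responses, and
#' peak-normalizes across frequencies.
#'
#' @param freqs modulation frequencies (Hz).
#' @param kernel a [gcampKernel()].
#' @param durS sinusoid duration (s).
#' @return normalized simulated F1 power per frequency (peak = 1).
#' @export
simulateGcampF1 <- function(freqs, kernel = gcampKernel(), durS = 2) {
  rate <- kernel$rate
  nPad <- round(rate)
  p <- vapply(freqs, function(f) {
    t <- (seq_len(round(durS * rate)) - 0.5) / rate
    stim <- c(rep(0.5, nPad), 0.5 + 0.5 * sin(2 * pi * f * t), rep(0.5, nPad))
    resp <- convolveCausal(stim, kernel$values)
    epoch <- resp[(nPad + 1):(nPad + round(durS * rate))]
    f1Power(epoch, f, rate, upsampleRate = rate)
  }, numeric(1))
  p / max(p)
}

#' Correct normalized F1 powers for GCaMP6f low-pass filtering
#'
#' Subtracts the peak-normalized simulated GCaMP6f F1 powers (same F1
#' pipeline) from the observed peak-normalized F1 powers.
#'
#' @param normalizedPowers observed F1 powers, peak-normalized, one per
#'   frequency.
#' @param freqs frequencies (Hz) matching `normalizedPowers`.
#' @param kernel a [gcampKernel()].
#' @param durS stimulus epoch duration (s).
#' @return corrected power per frequency (observed minus simulated).
#' @export
correctF1Power <- function(normalizedPowers, freqs, kernel = gcampKernel(),
                           durS = 2) {
  if (length(normalizedPowers) != length(freqs))
    stop("normalizedPowers and freqs must match")
  normalizedPowers - simulateGcampF1(freqs, kernel, durS)
}

#' F1 response phase
#'
#' Phase of the F1 component, averaged over trials (and the one or two
#' Fourier bins nearest f1) by converting each angle to a unit vector and
#' taking the angle of the vector sum. In this convention a pure sine at
#' the stimulus frequency reports -90 degrees.
#'
#' @param trials matrix (trials x samples) or a single trace.
#' @param f1 stimulus frequency (Hz).
#' @param rate acquisition rate (Hz).
#' @param upsampleRate analysis rate (Hz).
#' @return phase in degrees, in (-180, 180]; NA with a warning when the F1
#'   amplitude vanishes.
#' @export
f1Phase <- function(trials, f1, rate, upsampleRate = 189.4) {
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1)
  vecs <- complex(0)
  for (i in seq_len(nrow(trials))) {
    x <- resampleTrace(trials[i, ], rate, upsampleRate)
    m <- length(x)
    dur <- ncol(trials) / rate
    X <- stats::fft(x) / m
    fbin <- f1 * dur
    bins <- if (abs(fbin - round(fbin)) < 1e-6) 1 + round(fbin)
            else c(1 + floor(fbin), 1 + ceiling(fbin))
    z <- X[bins]
    ok <- Mod(z) > 1e-12
    if (!any(ok)) next
    # amplitude-weighted vector sum: each F1 component contributes its
    # full complex value, so near-empty neighbor bins cannot distort the
    # average
    vecs <- c(vecs, z[ok])
  }
  if (!length(vecs)) {
    warning("zero F1 amplitude; phase undefined")
    return(NA_real_)
  }
  ph <- Arg(sum(vecs)) * 180 / pi
  if (ph <= -180) ph <- ph + 360
  ph
}

#' Fit a first-order autoregressive noise model
#'
#' Ordinary least squares of x_t on x_(t-1) with an intercept; the AR
#' coefficient is the slope, and the innovation SD matches the residual
#' distribution. Used to simulate surrogate traces with the temporal
#' correlation of the recording noise but no stimulus drive.
#'
#' @param trace numeric vector, length >= 3.
#' @return list with `phi`, `noiseSd` (innovation SD), `intercept`; class
#'   `ARModel`. A warning is raised when |phi| >= 1 (non-stationary fit).
#' @export
ar1Fit <- function(trace) {
  n <- length(trace)
  if (n < 3) stop("need at least 3 samples to fit an AR(1) model")
  if (stats::sd(trace) == 0) stop("constant trace: AR coefficient undefined")
  X <- cbind(1, trace[-n])
  Y <- trace[-1]
  beta <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% beta
  phi <- beta[2]
  if (abs(phi) >= 1) warning("fitted AR(1) coefficient implies non-stationarity")
  structure(list(phi = phi, noiseSd = stats::sd(resid),
                 intercept = beta[1]), class = "ARModel")
}

#' Simulate from a fitted AR(1) model
#'
#' @param model an `ARModel` from [ar1Fit()].
#' @param n samples to generate.
#' @param seed integer seed.
#' @return numeric trace with the model's correlation structure.
#' @export
ar1Simulate <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "ARModel"))
  withSeed(seed, {
    init <- if (abs(model$phi) < 1)
      stats::rnorm(1, 0, model$noiseSd / sqrt(1 - model$phi^2)) else 0
    mu <- model$intercept / (1 - model$phi)
    mu + as.numeric(stats::filter(stats::rnorm(n, 0, model$noiseSd),
                                  model$phi, method = "recursive",
                                  init = init))
  })
}
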