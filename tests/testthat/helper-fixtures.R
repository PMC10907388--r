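# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small varying-size spot movie (7 sizes x 2 repeats, coarse pixels).
fixSpotMovie <- function() cached("spotMovie",
  generateSpotStimulus(pixelSize = 20, frameRate = 10, repeats = 2))

# Population of typed model cells on the spot movie.
fixPopulation <- function() cached("population",
  simulateTypePopulation(nPerType = 4, movie = fixSpotMovie(), seed = 2))

fixDepthProfiles <- function() cached("profiles", makeSyntheticDepthProfiles())

# Simulate one cell and return its spot-response map.
spotMapFromParams <- function(surroundWeight = 0.7, transienceTau = 2.5,
                              noiseSd = 0, seed = NULL, movie = fixSpotMovie()) {
  cell <- cellParams(surroundWeight = surroundWeight,
                     transienceTau = transienceTau, noiseSd = noiseSd)
  r <- simulateCellResponse(cell, movie, samplingRate = 9.5, seed = seed)
  spotResponseMap(epochTrace(r$values, r$rate, stimulusLog(movie)), 1)
}

# Rebuild a SpotResponseMap from a population response vector (7 sizes
# concatenated; epochs start 0.5 s before onset at 9.5 Hz).
mapFromVector <- function(vec, rate = 9.5, nSizes = 7,
                          sizes = c(20, 50, 100, 200, 400, 600, 800)) {
  len <- length(vec) / nSizes
  m <- matrix(vec, nrow = nSizes, byrow = TRUE)
  pk <- max(abs(m))
  if (pk > 0) m <- m / pk
  tt <- (seq_len(len) - 1) / rate - 0.5 + 0.5 / rate
  structure(list(sizes = sizes, time = tt, mean = m, trials = NULL,
                 rate = rate), class = "SpotResponseMap")
}

# Per-cell surround strength and transience from population vectors.
popFeatures <- function(pop) {
  t(vapply(seq_len(nrow(pop$responses)), function(i) {
    m <- mapFromVector(pop$responses[i, ])
    c(S = surroundStrength(m), T = transience(m))
  }, numeric(2)))
}

# Brute-force single-frequency DFT power oracle: |sum x e^{-2pi i f t} / N|^2
# on the raw samples (independent of the package's resampling pipeline).
dftPowerOracle <- function(x, f, rate) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  Mod(sum(x * exp(-2i * pi * f * t)) / n)^2
}
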