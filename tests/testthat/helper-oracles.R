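# Independent oracles used across the suite. All are deliberately naive:
# dense FFTs, exhaustive pair counts, brute-force threshold scans.

# Dominant frequency by zero-padded FFT (optionally within a band).
fftDominantFreq <- function(x, fs, band = NULL, pad = 8) {
  n <- length(x)
  m <- pad * n
  X <- Mod(stats::fft(c(x, numeric(m - n))))[1:(m %/% 2)]
  f <- (seq_len(m %/% 2) - 1) / m * fs
  if (!is.null(band)) {
    keep <- f >= band[1] & f <= band[2]
    f <- f[keep]; X <- X[keep]
  }
  f[which.max(X)]
}

# Peak of a short-time FFT magnitude: returns time (s) and frequency (Hz)
# of the strongest localised component.
stftPeak <- function(x, fs, winMs = 32, stepMs = 2) {
  w <- round(winMs * fs / 1000)
  step <- round(stepMs * fs / 1000)
  starts <- seq(1, length(x) - w + 1, by = step)
  best <- c(mag = -Inf, t = NA, f = NA)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  for (s in starts) {
    seg <- x[s:(s + w - 1)] * hann
    m <- 8 * w
    X <- Mod(stats::fft(c(seg, numeric(m - w))))[1:(m %/% 2)]
    j <- which.max(X)
    if (X[j] > best["mag"])
      best <- c(mag = X[j], t = (s + w / 2) / fs, f = (j - 1) / m * fs)
  }
  best
}

# Mean squared amplitude within a frequency band (periodogram sum).
bandPower <- function(x, fs, band) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= band[1] & f <= band[2]
  2 * sum(X[keep])
}

# AUC as the exhaustive pair-concordance (rank-sum) statistic.
bruteAuc <- function(gapScores, blockScores) {
  tot <- 0
  for (g in gapScores) for (b in blockScores)
    tot <- tot + (g > b) + 0.5 * (g == b)
  tot / (length(gapScores) * length(blockScores))
}

# Brute-force maximal Youden index over all candidate thresholds.
bruteYoudenJ <- function(scores, isGap) {
  best <- -Inf
  for (t in c(sort(unique(scores)), Inf)) {
    se <- mean(scores[isGap] >= t)
    sp <- mean(scores[!isGap] < t)
    best <- max(best, se + sp - 1)
  }
  best
}

# Noiseless synthetic test signal: far-field-like slow deflection plus a
# sharper high-frequency burst, parameters drawn from the ambient RNG.
randomBurstSignal <- function(fs = 2000, durS = 0.5) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  fLo <- runif(1, 40, 120); fHi <- runif(1, 180, 400)
  aLo <- runif(1, 0.1, 1.5); aHi <- runif(1, 0.05, 0.5)
  t0 <- durS / 2 + runif(1, -0.02, 0.02)
  aLo * exp(-(t - t0)^2 / (2 * 0.015^2)) * sin(2 * pi * fLo * (t - t0)) +
    aHi * exp(-(t - t0)^2 / (2 * 0.003^2)) * sin(2 * pi * fHi * (t - t0))
}

# One grid step (log spacing ratio) of the default frequency grid.
gridStep <- function(freqs = frequencyGrid()) freqs[2] / freqs[1]

# Nearest-bin distance helper: TRUE if f1 and f2 are within one grid bin.
withinOneBin <- function(f1, f2, freqs = frequencyGrid()) {
  r <- gridStep(freqs)
  max(f1, f2) / min(f1, f2) <= r * 1.0000001
}
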