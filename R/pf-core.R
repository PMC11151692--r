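## Continuous wavelet transform with a complex analytic Morlet-family
## wavelet, and the peak-frequency trace built on top of it.
##
## The mother wavelet is psi(t) = (pi*B)^(-1/2) exp(-t^2/B) exp(2i*pi*t),
## whose Fourier transform is exp(-pi^2 * B * (xi - 1)^2); daughters are
## L1-normalised, psi_a(t) = psi(t/a)/a with a = 1/f, so an amplitude-A
## sinusoid at any analysis frequency yields ridge magnitude A/2. The
## transform is evaluated per scale as a Fourier multiplier on the
## reflection-padded signal; negative-frequency bins are zeroed (analytic
## wavelet), which is what lets a magnitude ridge track an oscillation's
## frequency rather than its phase.

.pfEnv <- new.env(parent = emptyenv())

#' Log-spaced analysis frequency grid
#'
#' @param from,to band edges (Hz)
#' @param n number of grid points
#' @return strictly increasing numeric vector of length `n`
#' @examples
#' head(frequencyGrid())
#' @export
frequencyGrid <- function(from = 30, to = 500, n = 64) {
  if (from <= 0 || to <= from || n < 2)
    stop("need 0 < from < to and n >= 2")
  exp(seq(log(from), log(to), length.out = n))
}

## Gaussian envelope SD of the daughter wavelet at frequency f (seconds).
.waveletSigma <- function(f, bandwidth) sqrt(bandwidth / 2) / f

## Fourier multipliers for all grid frequencies (one column per frequency),
## cached on (fft length, fs, grid, bandwidth).
.waveletBank <- function(m, fs, freqs, bandwidth) {
  key <- paste0(m, ":", fs, ":", bandwidth, ":",
                paste(signif(freqs, 12), collapse = ","))
  bank <- .pfEnv[[key]]
  if (is.null(bank)) {
    xi <- (seq_len(m) - 1L) / m * fs          # FFT bin frequencies, 0..fs
    pos <- xi <= fs / 2                       # analytic: keep xi in [0, fs/2]
    bank <- matrix(0, m, length(freqs))
    for (j in seq_along(freqs))
      bank[pos, j] <- exp(-pi^2 * bandwidth * (xi[pos] / freqs[j] - 1)^2)
    .pfEnv[[key]] <- bank
  }
  bank
}

## Smallest 2^a * 3^b * 5^c >= n (fast mixed-radix FFT length).
.fastLen <- function(n) {
  best <- 2^ceiling(log2(n))
  p5 <- 1
  while (p5 < best) {
    p3 <- p5
    while (p3 < best) {
      m <- p3 * 2^max(0, ceiling(log2(n / p3)))
      if (m >= n && m < best) best <- m
      p3 <- p3 * 3
    }
    p5 <- p5 * 5
  }
  best
}

#' Continuous wavelet scalogram
#'
#' Magnitude of the analytic-Morlet continuous wavelet transform on a
#' log-spaced frequency grid, with L1-normalised scales (equal-amplitude
#' sinusoids at different frequencies give equal ridge magnitude) and
#' reflection padding at the record edges.
#'
#' @param signal numeric sample vector (mV), length >= 64
#' @param fs sampling rate (Hz)
#' @param freqs analysis frequencies (Hz), strictly increasing, below
#'   Nyquist; default [frequencyGrid()]
#' @param bandwidth dimensionless wavelet bandwidth parameter; larger values
#'   sharpen frequency resolution at the cost of time resolution
#' @return a [Scalogram-class]; its `edgeSamples` slot flags two envelope
#'   SDs of the widest wavelet at each record end as edge-unreliable
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 200 * seq(0, 0.25, by = 1 / fs))
#' scal <- cwtScalogram(x, fs)
#' @export
cwtScalogram <- function(signal, fs, freqs = frequencyGrid(), bandwidth = 1.5) {
  if (!is.numeric(signal) || !all(is.finite(signal)))
    stop("signal must be finite numeric")
  n <- length(signal)
  if (n < 64) stop("signal too short (need >= 64 samples)")
  if (any(diff(freqs) <= 0) || min(freqs) <= 0)
    stop("freqs must be positive and strictly increasing")
  if (max(freqs) >= fs / 2)
    stop("frequency grid exceeds the Nyquist limit fs/2")

  sigMax <- .waveletSigma(min(freqs), bandwidth)       # widest wavelet (s)
  pad <- min(n, as.integer(ceiling(4 * sigMax * fs)))
  xp <- c(signal[pad:1], signal, signal[n:(n - pad + 1L)])
  m <- .fastLen(length(xp))
  xp <- c(xp, numeric(m - length(xp)))

  bank <- .waveletBank(m, fs, freqs, bandwidth)
  X <- fft(xp)
  keep <- pad + seq_len(n)
  W <- stats::mvfft(bank * X, inverse = TRUE)   # column-wise recycling of X
  mags <- t(Mod(W[keep, , drop = FALSE])) / m

  edge <- as.integer(min(n, ceiling(2 * sigMax * fs)))
  new("Scalogram", magnitudes = mags, freqs = freqs, fs = fs,
      edgeSamples = edge)
}

#' Peak-frequency trace
#'
#' At each sample, the *highest-frequency signal component* whose scalogram
#' magnitude reaches the detection threshold
#' `max(relFrac * max|W|, absFloor)`; 0 where no component qualifies. A
#' component is a local maximum of the magnitude along the frequency axis,
#' so the trace reports the ridge frequency of the sharpest oscillation
#' present, not the upper skirt of a broad ridge. The threshold is relative
#' to the record's global scalogram maximum, so for noiseless signals with
#' `absFloor = 0` the trace is invariant under amplitude rescaling -- peak
#' frequency reflects deflection sharpness, not size. Edge-unreliable
#' samples are reported as 0.
#'
#' @param scal a [Scalogram-class]
#' @param relFrac relative threshold fraction, in (0, 1)
#' @param absFloor absolute magnitude floor (same units as the scalogram;
#'   0 disables it). Set it above the noise ridge to keep pure-noise
#'   segments silent.
#' @return a [PfTrace-class]
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 200 * seq(0, 0.25, by = 1 / fs))
#' tr <- peakFrequencyTrace(cwtScalogram(x, fs))
#' @export
peakFrequencyTrace <- function(scal, relFrac = 0.1, absFloor = 0) {
  stopifnot(is(scal, "Scalogram"))
  if (relFrac <= 0 || relFrac >= 1) stop("relFrac must lie in (0, 1)")
  if (absFloor < 0) stop("absFloor must be >= 0")
  mags <- scal@magnitudes
  n <- ncol(mags)
  nf <- nrow(mags)
  thr <- max(relFrac * max(mags), absFloor)
  # ridge bins: local maxima along the frequency axis
  ridge <- matrix(TRUE, nf, n)
  if (nf > 1L) {
    ridge[-nf, ] <- mags[-nf, ] >= mags[-1L, ]
    ridge[-1L, ] <- ridge[-1L, , drop = FALSE] & (mags[-1L, ] >= mags[-nf, ])
  }
  qual <- ridge & mags >= thr & mags > 0
  # highest qualifying grid row per sample
  idx <- integer(n)
  for (j in seq_len(nf))                # rows ordered low -> high frequency
    idx[qual[j, ]] <- j
  pf <- ifelse(idx > 0L, scal@freqs[pmax(idx, 1L)], 0)
  e <- scal@edgeSamples
  if (e > 0L) {
    pf[seq_len(min(e, n))] <- 0
    pf[seq.int(max(1L, n - e + 1L), n)] <- 0
  }
  new("PfTrace", pf = pf, freqs = scal@freqs, relFrac = relFrac,
      absFloor = absFloor, edgeSamples = scal@edgeSamples)
}

#' Scalar peak-frequency annotation of one electrogram
#'
#' The maximum of the peak-frequency trace over an annotation window -- the
#' highest frequency component detected anywhere in the window. Returns 0 Hz
#' when nothing clears the threshold there.
#'
#' @inheritParams cwtScalogram
#' @inheritParams peakFrequencyTrace
#' @param window half-open annotation window `c(startMs, endMs)` in ms from
#'   record start; `NULL` (default) annotates the whole record
#' @return peak frequency (Hz)
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 300 * seq(0, 0.25, by = 1 / fs))
#' annotatePf(x, fs)
#' @export
annotatePf <- function(signal, fs, freqs = frequencyGrid(),
                       relFrac = 0.1, absFloor = 0, bandwidth = 1.5,
                       window = NULL) {
  tr <- peakFrequencyTrace(cwtScalogram(signal, fs, freqs, bandwidth),
                           relFrac, absFloor)
  idx <- windowIndices(length(tr@pf), fs, window)
  max(tr@pf[idx])
}

#' Peak-to-peak voltage annotation of one electrogram
#'
#' @param signal numeric sample vector (mV)
#' @param fs sampling rate (Hz); needed only when `window` is given
#' @param window half-open `c(startMs, endMs)` window; `NULL` = whole record
#' @return peak-to-peak amplitude (mV)
#' @examples
#' annotateVoltage(sin(2 * pi * seq(0, 1, by = 1e-3)))  # 2 mV
#' @export
annotateVoltage <- function(signal, fs = NULL, window = NULL) {
  if (is.null(window)) return(peakToPeak(signal))
  if (is.null(fs)) stop("fs is required when a window is given")
  peakToPeak(signal[windowIndices(length(signal), fs, window)])
}

#' Noise-referenced absolute floor for peak-frequency detection
#'
#' Closed-form detection floor for records with additive white noise: `k`
#' times the expected scalogram magnitude (root mean square) of white noise
#' of standard deviation `noiseSd` at the top analysis frequency, where the
#' noise ridge is strongest. For an L1-normalised analytic Morlet the
#' expected squared magnitude at frequency f is
#' `noiseSd^2 * f / (fs * sqrt(2 * pi * bandwidth))`.
#'
#' @param noiseSd white-noise SD of the analysed (e.g. bipolar) signal (mV)
#' @param fs sampling rate (Hz)
#' @param fmax top analysis frequency (Hz)
#' @param bandwidth wavelet bandwidth parameter
#' @param k multiple of the noise rms (default 4)
#' @return absolute floor in scalogram units
#' @export
pfNoiseFloor <- function(noiseSd, fs, fmax = 500, bandwidth = 1.5, k = 4) {
  k * noiseSd * sqrt(fmax / (fs * sqrt(2 * pi * bandwidth)))
}
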