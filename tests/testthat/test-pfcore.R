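fs <- 2000
tAx <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
interior <- 200:800   # away from the edge-excluded zones at this grid

test_that("scalogram handles degenerate inputs and enforces preconditions", {
  z <- cwtScalogram(numeric(1000), fs)
  expect_true(all(z@magnitudes == 0))
  expect_true(all(pfValues(peakFrequencyTrace(z)) == 0))

  expect_error(cwtScalogram(numeric(10), fs), "too short")
  expect_error(cwtScalogram(numeric(1000), fs, freqs = c(100, 1100)), "Nyquist")
  expect_error(cwtScalogram(c(NA, numeric(999)), fs), "finite")
})

test_that("a pure sinusoid produces a ridge at its frequency at every interior sample", {
  x <- sin(2 * pi * 200 * tAx)
  scal <- cwtScalogram(x, fs)
  g <- scal@freqs
  ridge <- g[apply(scal@magnitudes[, interior], 2, which.max)]
  expect_true(all(vapply(ridge, withinOneBin, logical(1), f2 = 200)))

  # L1 normalisation: ridge magnitude is amplitude/2 at any frequency
  for (f0 in c(80, 200, 400)) {
    s0 <- cwtScalogram(sin(2 * pi * f0 * tAx), fs)
    expect_equal(max(s0@magnitudes), 0.5, tolerance = 0.02)
  }

  tr <- peakFrequencyTrace(scal)
  pfs <- unique(pfValues(tr)[interior])
  expect_length(pfs, 1L)
  expect_true(withinOneBin(pfs, 200))
})

test_that("a localised burst is found at the right time and frequency (STFT oracle)", {
  t0 <- 0.25
  x <- exp(-(tAx - t0)^2 / (2 * 0.003^2)) * sin(2 * pi * 300 * (tAx - t0))
  scal <- cwtScalogram(x, fs)
  peak <- arrayInd(which.max(scal@magnitudes), dim(scal@magnitudes))
  expect_lt(abs(tAx[peak[2]] - t0), 0.005)
  expect_true(withinOneBin(scal@freqs[peak[1]], 300))

  oracle <- stftPeak(x, fs)
  expect_lt(abs(tAx[peak[2]] - oracle["t"]), 0.01)
  expect_true(withinOneBin(scal@freqs[peak[1]], oracle["f"]))
})

test_that("a low-amplitude high-frequency component dominates the trace when thresholded in", {
  # 20x smaller amplitude than the 60 Hz background
  x <- sin(2 * pi * 60 * tAx) +
    0.05 * exp(-(tAx - 0.25)^2 / (2 * 0.003^2)) * sin(2 * pi * 300 * (tAx - 0.25))
  expect_true(withinOneBin(annotatePf(x, fs, relFrac = 0.01), 300))
  # with a high relative threshold only the large slow component survives
  expect_true(withinOneBin(annotatePf(x, fs, relFrac = 0.5), 60))
})

test_that("peak frequency is amplitude invariant for noiseless signals", {
  set.seed(101)
  for (k in 1:20) {
    x <- randomBurstSignal()
    ref <- annotatePf(x, fs)
    for (c0 in c(0.01, 0.1, 10))
      expect_identical(annotatePf(c0 * x, fs), ref)
  }
})

test_that("raising relFrac never raises the trace, and values live on the grid", {
  set.seed(55)
  g <- frequencyGrid()
  for (k in 1:5) {
    x <- randomBurstSignal()
    scal <- cwtScalogram(x, fs)
    prev <- peakFrequencyTrace(scal, relFrac = 0.05)
    for (rf in c(0.1, 0.2, 0.4, 0.8)) {
      cur <- peakFrequencyTrace(scal, relFrac = rf)
      expect_true(all(pfValues(cur) <= pfValues(prev)))
      nz <- pfValues(cur)[pfValues(cur) > 0]
      expect_true(all(nz %in% g))
      prev <- cur
    }
  }
})

test_that("scalogram ridge matches a dense-FFT dominant-frequency oracle for single tones", {
  set.seed(77)
  for (k in 1:50) {
    f0 <- runif(1, 50, 450)
    x <- runif(1, 0.05, 2) * sin(2 * pi * f0 * tAx)
    scal <- cwtScalogram(x, fs)
    ridge <- scal@freqs[which.max(scal@magnitudes[, 500])]
    oracle <- fftDominantFreq(x, fs)
    expect_true(withinOneBin(ridge, oracle))
  }
})

test_that("edge zones are excluded from the trace", {
  x <- sin(2 * pi * 200 * tAx)
  tr <- peakFrequencyTrace(cwtScalogram(x, fs))
  e <- tr@edgeSamples
  expect_gt(e, 0)
  expect_true(all(pfValues(tr)[1:e] == 0))
  expect_true(all(pfValues(tr)[(length(tAx) - e + 1):length(tAx)] == 0))
})

test_that("voltage annotation is peak-to-peak over the window", {
  expect_identical(annotateVoltage(rep(0.7, 100)), 0)
  # unit sinusoid over full cycles
  expect_equal(annotateVoltage(sin(2 * pi * 10 * tAx)), 2, tolerance = 1e-3)
  # windowed annotation sees only the window
  x <- c(numeric(500), rep(c(-1, 1), 250))
  expect_equal(annotateVoltage(x, fs, window = c(0, 200)), 0)
  expect_equal(annotateVoltage(x, fs, window = c(300, 500)), 2)
  expect_error(annotateVoltage(x, fs, window = c(200, 100)), "window")
  expect_error(annotatePf(x, fs, window = c(100, 100)), "window")
})

test_that("quiet windows above the noise floor annotate 0 Hz", {
  set.seed(3)
  x <- c(rnorm(500, 0, 0.005), sin(2 * pi * 250 * tAx[1:500]))
  floor <- pfNoiseFloor(0.005, fs, 500)
  # pre-activation noise window only
  expect_identical(annotatePf(x, fs, absFloor = floor, window = c(70, 180)), 0)
  # the sinusoid half still annotates
  expect_gt(annotatePf(x, fs, absFloor = floor), 180)
})
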