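fs <- 2000
tAx <- seq(0, 0.5 - 1 / fs, by = 1 / fs)

# Clique whose unipolar potentials realise a uniform time-varying field
# E(t) = (ax(t), ay(t)): phi_i(t) = -ax(t) x_i - ay(t) y_i.
fieldClique <- function(ax, ay, pitch = 2) {
  xy <- cliqueCoords(pitch)
  sig <- -outer(ax, xy[, "x"]) - outer(ay, xy[, "y"])
  cliqueRecording(sig, xy, fs, "field")
}

test_that("bipolar electrogram is the channel difference with validated indices", {
  xy <- cliqueCoords()
  sig <- cbind(sin(2 * pi * 5 * tAx), 0, 0.3, -0.1)
  rec <- cliqueRecording(sig, xy, fs)
  expect_equal(bipolarEgm(rec, c(1, 2)), sin(2 * pi * 5 * tAx))
  expect_equal(bipolarEgm(rec, c(3, 4)), rep(0.4, length(tAx)))
  expect_error(bipolarEgm(rec, c(2, 2)), "distinct")
  expect_error(bipolarEgm(rec, c(1, 9)), "indices")
})

test_that("field fit recovers a static linear potential exactly", {
  # phi_i = a * x_i  => E = (-a, 0)
  a <- 0.25
  xy <- cliqueCoords()
  sig <- matrix(rep(a * xy[, "x"], each = 100), nrow = 100)
  rec <- cliqueRecording(sig, xy, fs, "lin")
  loop <- efieldLoop(rec)
  expect_equal(loop@ex, rep(-a, 100))
  expect_equal(loop@ey, rep(0, 100))
})

test_that("common-mode input gives a zero loop and zero omnipolar voltage", {
  sig <- matrix(rep(sin(2 * pi * 40 * tAx), 4), ncol = 4)
  rec <- cliqueRecording(sig, cliqueCoords(), fs, "cm")
  loop <- efieldLoop(rec)
  expect_true(all(abs(loop@ex) < 1e-12))
  expect_true(all(abs(loop@ey) < 1e-12))
  expect_lt(omnipolarVoltage(loop), 1e-10)
  omni <- cliqueOmnipolar(rec)
  expect_lt(omni$vOmni, 1e-10)
  expect_lt(annotatePf(omni$egm, fs, absFloor = 1e-6), 1e-12)
})

test_that("degenerate geometry is rejected", {
  xy <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))   # collinear
  expect_error(cliqueRecording(matrix(0, 50, 4), xy, fs), "collinear")
  rec <- cliqueRecording(matrix(rnorm(400), 100, 4), cliqueCoords(), fs)
  expect_error(efieldLoop(rec, electrodes = c(1, 2)), "three")
})

test_that("a planar wave's dominant loop axis matches its propagation direction", {
  ang <- 30 * pi / 180
  v <- 0.5
  xy <- cliqueCoords()
  burst <- function(d) exp(-(tAx - 0.25 - d / 1000)^2 / (2 * 0.004^2))
  sig <- vapply(1:4, function(i) {
    d <- sum(c(cos(ang), sin(ang)) * xy[i, ]) / v
    burst(d)
  }, numeric(length(tAx)))
  rec <- cliqueRecording(sig, xy, fs, "wave")
  loop <- efieldLoop(rec)
  # brute-force orientation scan at 0.25 degrees
  th <- seq(0, pi - 1e-9, by = 0.25 * pi / 180)
  pp <- vapply(th, function(a) {
    p <- loop@ex * cos(a) + loop@ey * sin(a)
    max(p) - min(p)
  }, numeric(1))
  expect_lt(abs(th[which.max(pp)] - ang) * 180 / pi, 2)
})

test_that("omnipolar voltage has the closed-form value and rotational symmetry", {
  ax <- sin(2 * pi * 30 * tAx)
  rec <- fieldClique(ax, numeric(length(tAx)))
  loop <- efieldLoop(rec)
  expect_equal(omnipolarVoltage(loop, pitchMm = 2), 4, tolerance = 1e-6)
  expect_equal(max(abs(omnipolarEgm(loop, 2) - 2 * ax)), 0, tolerance = 1e-9)

  # rigid 30-degree rotation of the electrode coordinates
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rec30 <- cliqueRecording(signals(rec), coords(rec) %*% rot(pi / 6), fs)
  v0 <- cliqueOmnipolar(rec)$vOmni
  v30 <- cliqueOmnipolar(rec30)$vOmni
  expect_lt(abs(v30 - v0) / v0, 0.01)
})

test_that("omnipolar voltage dominates every pitch-normalised clique bipole", {
  cfg <- synthConfig(nSites = 100, gapPrevalence = 0.5, seed = 23)
  coh <- simulateCohort(cfg)
  pitch <- cfg@pitchMm
  for (rec in coh$recordings) {
    vOmni <- cliqueOmnipolar(rec)$vOmni
    for (pair in utils::combn(4, 2, simplify = FALSE)) {
      d <- sqrt(sum((coords(rec)[pair[1], ] - coords(rec)[pair[2], ])^2))
      vb <- peakToPeak(bipolarEgm(rec, pair)) * pitch / d
      expect_gte(vOmni, vb - 1e-9)
    }
  }
})

test_that("rotation leaves the omnipolar peak frequency within one grid bin", {
  rec <- simulateSite(synthConfig(), "gap", seed = 31)
  rot <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2)
  rec30 <- cliqueRecording(signals(rec), coords(rec) %*% rot, samplingRate(rec))
  floor <- pfNoiseFloor(sqrt(2) * 0.01, fs, 500)
  pf0 <- annotatePf(cliqueOmnipolar(rec)$egm, fs, absFloor = floor)
  pf30 <- annotatePf(cliqueOmnipolar(rec30)$egm, fs, absFloor = floor)
  expect_true(withinOneBin(pf0, pf30))
})

test_that("on gap sites the omnipolar peak frequency tracks the clique bipoles'", {
  floor <- pfNoiseFloor(sqrt(2) * 0.01, fs, 500)
  r <- gridStep()
  for (s in c(41, 42, 43, 44, 45)) {
    rec <- simulateSite(synthConfig(nfAmpRange = c(0.2, 0.5)), "gap", seed = s)
    pairs <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
    pfb <- vapply(pairs, function(p)
      annotatePf(bipolarEgm(rec, p), fs, absFloor = floor), numeric(1))
    pfo <- annotatePf(cliqueOmnipolar(rec)$egm, fs, absFloor = floor)
    # the omnipolar EGM is a combination of the clique bipoles: its peak
    # frequency stays within one grid bin of the bipolar PF span
    expect_gt(pfo, 0)
    expect_gte(pfo, min(pfb) / r * 0.9999)
    expect_lte(pfo, max(pfb) * r * 1.0001)
  }
})
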