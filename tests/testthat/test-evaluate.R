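test_that("contingency metrics match closed forms and refuse empty denominators", {
  m <- contingencyMetrics(contingencyTable(tp = 19, fp = 5, fn = 18, tn = 150))
  expect_equal(roundHalfUp(m, 1),
               c(se = 51.4, sp = 96.8, ppv = 79.2, npv = 89.3))

  t2 <- contingencyTable(tp = 1, fp = 1, fn = 0, tn = 0)
  expect_equal(unname(contingencyMetrics(t2, c("se", "ppv"))), c(100, 50))
  expect_equal(unname(contingencyMetrics(t2, "sp")), 0)  # 0/(0+1), defined
  expect_error(contingencyMetrics(t2, "npv"), "undefined")

  t3 <- contingencyTable(tp = 0, fp = 0, fn = 0, tn = 5)
  expect_equal(unname(contingencyMetrics(t3, c("sp", "npv"))), c(100, 100))
  expect_error(contingencyMetrics(t3, "se"), "undefined")
})

test_that("count reconstruction inverts printed percentages", {
  # perfect single row: tp = nGap, fp = 0 at the smallest block count
  sol <- reconstructCounts(
    data.frame(se = 100, sp = 100, ppv = 100, npv = 100), nGap = 2)
  expect_identical(sol$nBlock, 1L)
  expect_identical(sol$tables[[1]]@tp, 2L)
  expect_identical(sol$tables[[1]]@fp, 0L)

  # internally inconsistent row: ppv 50 needs fp > 0, contradicting sp 100
  expect_error(
    reconstructCounts(data.frame(se = 100, sp = 100, ppv = 50, npv = 100),
                      nGap = 1, nBlockMax = 200),
    "no consistent")

  # synthetic round trip: metrics of known counts reconstruct those counts
  truthTab <- contingencyTable(tp = 11, fp = 9, fn = 14, tn = 61)
  printed <- as.data.frame(as.list(roundHalfUp(contingencyMetrics(truthTab), 1)))
  sol2 <- reconstructCounts(printed, nGap = 25, nBlockMax = 200)
  rec <- sol2$tables[[1]]
  expect_equal(roundHalfUp(contingencyMetrics(rec), 1),
               roundHalfUp(contingencyMetrics(truthTab), 1))
})

test_that("ROC analysis reproduces closed-form AUCs and rejects degenerate input", {
  expect_equal(aucValue(rocAnalysis(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_equal(aucValue(rocAnalysis(rep(1, 6), rep(c(TRUE, FALSE), 3))), 0.5)
  # pair enumeration: gaps {1,3} vs blocks {2,4} -> 1 concordant of 4
  expect_equal(aucValue(rocAnalysis(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))), 0.25)
  expect_error(rocAnalysis(1:4, rep(TRUE, 4)), "both classes")
  expect_error(rocAnalysis(c(1, NA, 2), c(TRUE, FALSE, TRUE)), "finite")
})

test_that("AUC equals the brute-force pair-concordance statistic on random instances", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(6:50, 1)
    isGap <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n, mean = ifelse(isGap, 0.5, 0), sd = 1), 1)
    r <- rocAnalysis(scores, isGap)
    expect_equal(aucValue(r), bruteAuc(scores[isGap], scores[!isGap]))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (k in 1:10) {
    isGap <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(isGap)) < 2) next
    scores <- rnorm(40, ifelse(isGap, 1, 0))
    ours <- aucValue(rocAnalysis(scores, isGap))
    ref <- as.numeric(pROC::auc(pROC::roc(isGap, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Youden cutoff equals the brute-force optimum with the stated conventions", {
  # perfectly separated classes
  r <- rocAnalysis(c(200, 300, 50, 100), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youdenJ(r), 1)
  expect_gt(youdenCutoff(r), 100)
  expect_lt(youdenCutoff(r), 200)
  expect_equal(youdenCutoff(r), 150)  # midpoint convention

  # observed-threshold convention reports the raw score
  r2 <- rocAnalysis(c(200, 300, 50, 100), c(TRUE, TRUE, FALSE, FALSE),
                    interp = "observed")
  expect_equal(youdenCutoff(r2), 200)

  # degenerate one-score-per-class case
  r3 <- rocAnalysis(c(200, 50), c(TRUE, FALSE))
  expect_equal(youdenJ(r3), 1)
  expect_equal(youdenCutoff(r3), 125)

  set.seed(31)
  for (k in 1:20) {
    isGap <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 18, replace = TRUE))
    scores <- round(runif(20, 0, 10), 1)
    r <- rocAnalysis(scores, isGap)
    expect_equal(youdenJ(r), bruteYoudenJ(scores, isGap))
  }
})

test_that("phase-1 runner handles separable and uninformative configurations", {
  # oracle-separable scores injected -> all four AUCs are 1
  labels <- data.frame(site_id = sprintf("s%02d", 1:20),
                       truth = rep(c("gap", "block"), each = 10))
  ann <- data.frame(site_id = labels$site_id,
                    V_bi = ifelse(labels$truth == "gap", 2, 1),
                    V_omni = ifelse(labels$truth == "gap", 3, 1),
                    PF_bi = ifelse(labels$truth == "gap", 300, 100),
                    PF_omni = ifelse(labels$truth == "gap", 310, 90))
  p1 <- runPhase1(ann, labels)
  expect_equal(p1$summary$auc, rep(1, 4))
  expect_error(runPhase1(ann[, 1:3], labels), "modality")

  # equal-band equal-width activity with no propagation delay carries no
  # frequency information: PF discrimination collapses to chance
  cfg <- synthConfig(nSites = 80, seed = 3, nfFreqRange = c(80, 80),
                     ffFreqRange = c(80, 80), nfAmpRange = c(0.5, 1.5),
                     nfWidthMs = 15, ffJitter = 0.4,
                     conductionVelocity = 100, noiseSd = 0.005)
  coh <- simulateCohort(cfg)
  p <- runPhase1(annotateCohort(coh, noiseSd = 0.005), coh$labels)
  aucPf <- p$summary$auc[p$summary$modality == "PF_bi"]
  expect_gt(aucPf, 0.35)
  expect_lt(aucPf, 0.65)
})

test_that("phase-2 runner reproduces metrics from injected segment calls", {
  # calls identical to truth -> every metric 100
  truth <- data.frame(segment_id = 1:10,
                      truth = rep(c("gap", "block"), 5))
  calls <- data.frame(segment_id = 1:10, criterion = "PF_bi",
                      call = truth$truth)
  p <- runPhase2(calls, truth)
  expect_equal(unname(unlist(p$metrics[, c("se", "sp", "ppv", "npv")])),
               rep(100, 4))

  # all-block calls: se 0, sp 100, npv defined, ppv undefined is an error
  calls0 <- data.frame(segment_id = 1:10, criterion = "V_bi", call = "block")
  tab <- runPhase2(calls0, truth)$tables$V_bi
  expect_equal(unname(contingencyMetrics(tab, c("se", "sp"))), c(0, 100))
  expect_error(contingencyMetrics(tab, "ppv"), "undefined")

  expect_error(runPhase2(data.frame(segment_id = 1:3, criterion = "x",
                                    call = "gap"), truth), "segment sets")
})

test_that("reported proportions use one-decimal half-away-from-zero rounding", {
  expect_identical(proportionPct(26, 88), 29.5)
  expect_identical(roundHalfUp(c(16.25, -16.25, 2.349), 1), c(16.3, -16.3, 2.3))
  expect_identical(roundHalfUp(0.5, 0), 1)
  expect_error(proportionPct(1, 0), "denominator")
})
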