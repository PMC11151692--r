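#' @import methods
#' @importFrom stats rnorm runif fft quantile
NULL

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Free parameters of the synthetic electrogram simulator. Each mapping site
#' is a 2x2 electrode clique recording one activation: a broad, low-frequency
#' far-field deflection common to all electrodes, plus -- at conduction-gap
#' sites only -- a brief, high-frequency near-field deflection that crosses
#' the clique as a planar wavefront.
#'
#' @slot fs sampling rate (Hz)
#' @slot durationMs record length (ms)
#' @slot nfFreqRange near-field carrier band, c(low, high) (Hz)
#' @slot ffFreqRange far-field carrier band, c(low, high) (Hz)
#' @slot nfAmpRange near-field peak amplitude range (mV)
#' @slot ffAmpRange far-field peak amplitude range (mV)
#' @slot nfWidthMs Gaussian envelope SD of the near-field deflection (ms)
#' @slot ffWidthMs Gaussian envelope SD of the far-field deflection (ms)
#' @slot noiseSd additive white-noise SD (mV)
#' @slot gapPrevalence fraction of sites that are conduction gaps
#' @slot nSites number of sites in a cohort
#' @slot seed RNG seed used by [simulateCohort()]
#' @slot conductionVelocity planar wavefront speed (mm/ms)
#' @slot ffJitter per-electrode far-field amplitude jitter (fraction, < 0.05
#'   keeps the far-field effectively common-mode)
#' @slot pitchMm electrode pitch of the 2x2 clique (mm)
#' @slot sitesPerSegment sites mapped per PV-line segment
#' @export
setClass("SynthConfig",
  representation(
    fs = "numeric", durationMs = "numeric",
    nfFreqRange = "numeric", ffFreqRange = "numeric",
    nfAmpRange = "numeric", ffAmpRange = "numeric",
    nfWidthMs = "numeric", ffWidthMs = "numeric",
    noiseSd = "numeric", gapPrevalence = "numeric",
    nSites = "numeric", seed = "numeric",
    conductionVelocity = "numeric", ffJitter = "numeric",
    pitchMm = "numeric", sitesPerSegment = "numeric"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@fs) || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (!num1(object@durationMs) || object@durationMs <= 0)
    msg <- c(msg, "durationMs must be a positive scalar")
  for (nm in c("nfFreqRange", "ffFreqRange", "nfAmpRange", "ffAmpRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2] || any(r < 0))
      msg <- c(msg, sprintf("%s must be c(low, high) with 0 <= low <= high", nm))
  }
  if (length(object@nfFreqRange) == 2L && num1(object@fs) &&
      object@fs <= 2 * object@nfFreqRange[2])
    msg <- c(msg, "fs must exceed twice the near-field band top (Nyquist)")
  if (!num1(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!num1(object@gapPrevalence) || object@gapPrevalence < 0 || object@gapPrevalence > 1)
    msg <- c(msg, "gapPrevalence must lie in [0, 1]")
  if (!num1(object@nSites) || object@nSites < 1 || object@nSites != round(object@nSites))
    msg <- c(msg, "nSites must be a positive integer")
  if (!num1(object@conductionVelocity) || object@conductionVelocity <= 0)
    msg <- c(msg, "conductionVelocity must be positive")
  if (!num1(object@ffJitter) || object@ffJitter < 0 || object@ffJitter >= 1)
    msg <- c(msg, "ffJitter must lie in [0, 1)")
  if (!num1(object@pitchMm) || object@pitchMm <= 0)
    msg <- c(msg, "pitchMm must be positive")
  if (!num1(object@nfWidthMs) || object@nfWidthMs <= 0 ||
      !num1(object@ffWidthMs) || object@ffWidthMs <= 0)
    msg <- c(msg, "envelope widths must be positive")
  if (!num1(object@sitesPerSegment) || object@sitesPerSegment < 1)
    msg <- c(msg, "sitesPerSegment must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Create a simulator configuration
#'
#' Defaults describe a 500 ms sinus-rhythm acquisition at 2000 Hz with a
#' near-field band of 180--400 Hz well separated from a 40--120 Hz far-field
#' band, but overlapping amplitude distributions, so that voltage criteria
#' are fallible while frequency criteria are not.
#'
#' @param fs sampling rate (Hz)
#' @param durationMs record length (ms)
#' @param nfFreqRange,ffFreqRange near-/far-field carrier bands (Hz)
#' @param nfAmpRange,ffAmpRange near-/far-field peak amplitude ranges (mV)
#' @param nfWidthMs,ffWidthMs Gaussian envelope SDs (ms)
#' @param noiseSd additive white-noise SD (mV)
#' @param gapPrevalence fraction of gap sites in a cohort
#' @param nSites cohort size
#' @param seed RNG seed
#' @param conductionVelocity wavefront speed (mm/ms)
#' @param ffJitter per-electrode far-field amplitude jitter fraction
#' @param pitchMm electrode pitch (mm)
#' @param sitesPerSegment sites per PV segment (16 segments per cohort)
#' @return a validated [SynthConfig-class] object
#' @examples
#' cfg <- synthConfig(nSites = 8, seed = 1)
#' @export
synthConfig <- function(fs = 2000, durationMs = 500,
                        nfFreqRange = c(180, 400), ffFreqRange = c(40, 120),
                        nfAmpRange = c(0.03, 0.5), ffAmpRange = c(0.1, 1.5),
                        nfWidthMs = 3, ffWidthMs = 15,
                        noiseSd = 0.01, gapPrevalence = 0.25,
                        nSites = 192, seed = 1,
                        conductionVelocity = 0.5, ffJitter = 0.05,
                        pitchMm = 2, sitesPerSegment = 12) {
  new("SynthConfig",
    fs = fs, durationMs = durationMs,
    nfFreqRange = nfFreqRange, ffFreqRange = ffFreqRange,
    nfAmpRange = nfAmpRange, ffAmpRange = ffAmpRange,
    nfWidthMs = nfWidthMs, ffWidthMs = ffWidthMs,
    noiseSd = noiseSd, gapPrevalence = gapPrevalence,
    nSites = nSites, seed = seed,
    conductionVelocity = conductionVelocity, ffJitter = ffJitter,
    pitchMm = pitchMm, sitesPerSegment = sitesPerSegment)
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nSites, "sites @", object@fs, "Hz,",
      object@durationMs, "ms\n")
  cat("  NF", paste(object@nfFreqRange, collapse = "-"), "Hz,",
      paste(object@nfAmpRange, collapse = "-"), "mV | FF",
      paste(object@ffFreqRange, collapse = "-"), "Hz,",
      paste(object@ffAmpRange, collapse = "-"), "mV\n")
  cat("  gap prevalence", object@gapPrevalence, "| noise SD",
      object@noiseSd, "mV | seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CliqueRecording
## ---------------------------------------------------------------------------

#' Clique recording of unipolar electrograms
#'
#' Simultaneous unipolar signals from one electrode clique of a grid mapping
#' catheter, with the in-plane electrode coordinates needed to derive
#' bipolar and omnipolar electrograms.
#'
#' @slot signals numeric matrix, one column per electrode (mV)
#' @slot coords electrode positions, n_electrodes x 2 (mm)
#' @slot fs sampling rate (Hz)
#' @slot siteId site identifier
#' @export
setClass("CliqueRecording",
  representation(signals = "matrix", coords = "matrix",
                 fs = "numeric", siteId = "character"))

setValidity("CliqueRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signals) || !all(is.finite(object@signals)))
    msg <- c(msg, "signals must be a finite numeric matrix")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y in mm)")
  if (nrow(object@coords) != ncol(object@signals))
    msg <- c(msg, "one coordinate row per signal column required")
  if (nrow(object@coords) >= 3L) {
    cc <- sweep(object@coords, 2, colMeans(object@coords))
    if (qr(cc)$rank < 2L) msg <- c(msg, "electrode coordinates are collinear")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @param signals,coords,fs,siteId see [CliqueRecording-class]
#' @rdname CliqueRecording-class
#' @export
cliqueRecording <- function(signals, coords, fs, siteId = "site") {
  new("CliqueRecording", signals = as.matrix(signals),
      coords = as.matrix(coords), fs = fs, siteId = as.character(siteId))
}

#' Accessors for CliqueRecording
#'
#' @param x a [CliqueRecording-class]
#' @return `signals()` the sample matrix (mV); `coords()` the electrode
#'   positions (mm); `samplingRate()` the rate in Hz; `siteId()` the id.
#' @name clique-accessors
NULL

#' @rdname clique-accessors
#' @export
signals <- function(x) x@signals
#' @rdname clique-accessors
#' @export
coords <- function(x) x@coords
#' @rdname clique-accessors
#' @export
samplingRate <- function(x) x@fs
#' @rdname clique-accessors
#' @export
siteId <- function(x) x@siteId

setMethod("show", "CliqueRecording", function(object) {
  cat("CliqueRecording", object@siteId, ":", nrow(object@signals),
      "samples x", ncol(object@signals), "electrodes @", object@fs, "Hz\n")
})

## ---------------------------------------------------------------------------
## Scalogram / PfTrace
## ---------------------------------------------------------------------------

#' Wavelet scalogram
#'
#' Magnitude of the continuous wavelet transform, frequencies in rows and
#' samples in columns. Scales are L1-normalised so equal-amplitude sinusoids
#' at different frequencies produce equal ridge magnitude.
#'
#' @slot magnitudes n_freqs x n_samples non-negative matrix
#' @slot freqs analysis frequencies (Hz), strictly increasing
#' @slot fs sampling rate of the analysed signal (Hz)
#' @slot edgeSamples number of edge-unreliable samples at each record end
#'   (two SDs of the widest wavelet envelope)
#' @export
setClass("Scalogram",
  representation(magnitudes = "matrix", freqs = "numeric",
                 fs = "numeric", edgeSamples = "integer"))

setValidity("Scalogram", function(object) {
  msg <- character()
  if (!all(is.finite(object@magnitudes)) || any(object@magnitudes < 0))
    msg <- c(msg, "magnitudes must be finite and non-negative")
  if (nrow(object@magnitudes) != length(object@freqs))
    msg <- c(msg, "one row per analysis frequency required")
  if (any(diff(object@freqs) <= 0) || any(object@freqs <= 0))
    msg <- c(msg, "freqs must be positive and strictly increasing")
  if (object@freqs[length(object@freqs)] >= object@fs / 2)
    msg <- c(msg, "freqs must stay below Nyquist")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Scalogram", function(object) {
  cat("Scalogram:", nrow(object@magnitudes), "frequencies (",
      round(min(object@freqs), 1), "-", round(max(object@freqs), 1), "Hz ) x",
      ncol(object@magnitudes), "samples\n")
})

#' Peak-frequency trace
#'
#' Per-sample highest frequency whose scalogram magnitude clears the
#' detection threshold; 0 where nothing qualifies (including the
#' edge-excluded samples at the record boundaries).
#'
#' @slot pf per-sample peak frequency (Hz, 0 = none)
#' @slot freqs the analysis frequency grid the values are drawn from
#' @slot relFrac relative threshold fraction used
#' @slot absFloor absolute magnitude floor used
#' @slot edgeSamples edge-excluded samples at each end
#' @export
setClass("PfTrace",
  representation(pf = "numeric", freqs = "numeric", relFrac = "numeric",
                 absFloor = "numeric", edgeSamples = "integer"))

setValidity("PfTrace", function(object) {
  nz <- object@pf[object@pf != 0]
  if (length(nz) && !all(nz %in% object@freqs))
    return("every nonzero trace value must belong to the frequency grid")
  if (any(object@pf < 0)) return("trace values must be non-negative")
  TRUE
})

#' @rdname PfTrace-class
#' @param x a `PfTrace`
#' @return `pfValues()` returns the per-sample trace in Hz.
#' @export
pfValues <- function(x) x@pf

setMethod("show", "PfTrace", function(object) {
  act <- object@pf[object@pf > 0]
  cat("PfTrace:", length(object@pf), "samples;",
      length(act), "above threshold",
      if (length(act)) sprintf("(max %.1f Hz)", max(act)) else "", "\n")
})

## ---------------------------------------------------------------------------
## EFieldLoop
## ---------------------------------------------------------------------------

#' In-plane electric-field loop
#'
#' Time series of the two in-plane components of the local electric field
#' estimated from a clique's unipolar potentials, E = -grad(phi).
#'
#' @slot ex,ey field components (mV/mm)
#' @slot fs sampling rate (Hz)
#' @export
setClass("EFieldLoop",
  representation(ex = "numeric", ey = "numeric", fs = "numeric"))

setValidity("EFieldLoop", function(object) {
  if (length(object@ex) != length(object@ey))
    return("ex and ey must have equal length")
  if (!all(is.finite(object@ex)) || !all(is.finite(object@ey)))
    return("field components must be finite")
  TRUE
})

setMethod("show", "EFieldLoop", function(object) {
  cat("EFieldLoop:", length(object@ex), "samples, |E|max",
      sprintf("%.3f", max(sqrt(object@ex^2 + object@ey^2))), "mV/mm\n")
})

## ---------------------------------------------------------------------------
## ContingencyTable / RocResult / CriterionConfig
## ---------------------------------------------------------------------------

#' Diagnostic contingency table
#'
#' @slot tp,fp,fn,tn non-negative integer counts
#' @export
setClass("ContingencyTable",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer"))

setValidity("ContingencyTable", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    return("tp, fp, fn, tn must be single non-negative integers")
  TRUE
})

#' @param tp,fp,fn,tn counts
#' @rdname ContingencyTable-class
#' @export
contingencyTable <- function(tp, fp, fn, tn) {
  new("ContingencyTable", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: TP %d FP %d FN %d TN %d (n gap %d, n block %d)\n",
      object@tp, object@fp, object@fn, object@tn,
      object@tp + object@fn, object@fp + object@tn))
})

#' ROC analysis result
#'
#' Threshold sweep for a ">= threshold calls gap" criterion: sensitivity and
#' specificity at every candidate threshold, trapezoidal AUC, and the
#' Youden-optimal cutoff.
#'
#' @slot thresholds candidate thresholds, increasing (includes a +Inf
#'   sentinel where nothing is called positive)
#' @slot se,sp sensitivity and specificity (fractions) per threshold
#' @slot auc area under the ROC curve
#' @slot youdenCutoff reported optimal cutoff (midpoint convention by default)
#' @slot youdenJ maximal Youden index J = SE + SP - 1
#' @slot youdenThreshold the observed score at the optimum (before midpoint
#'   interpolation)
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", se = "numeric", sp = "numeric",
                 auc = "numeric", youdenCutoff = "numeric",
                 youdenJ = "numeric", youdenThreshold = "numeric"))

setValidity("RocResult", function(object) {
  msg <- character()
  if (length(object@se) != length(object@thresholds) ||
      length(object@sp) != length(object@thresholds))
    msg <- c(msg, "se/sp must align with thresholds")
  if (is.unsorted(object@thresholds)) msg <- c(msg, "thresholds must increase")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname RocResult-class
#' @param x a `RocResult`
#' @return `aucValue()` the area under the curve; `youdenCutoff()` the
#'   reported optimal cutoff; `youdenJ()` the maximal Youden index.
#' @export
aucValue <- function(x) x@auc
#' @rdname RocResult-class
#' @export
youdenCutoff <- function(x) x@youdenCutoff
#' @rdname RocResult-class
#' @export
youdenJ <- function(x) x@youdenJ

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.3f, Youden cutoff %.4g (J = %.3f)\n",
      object@auc, object@youdenCutoff, object@youdenJ))
})

#' Threshold criterion configuration
#'
#' A single gap-calling rule: a site is called *gap* when its annotation for
#' `modality` is greater than or equal to `cutoff` (ties call gap). High
#' residual voltage or high peak frequency on the ablation line both indicate
#' surviving conduction, so all four modalities share the ">= cutoff" sense.
#'
#' @slot modality one of `"V_bi"`, `"V_omni"`, `"PF_bi"`, `"PF_omni"`
#' @slot cutoff threshold in mV (voltage) or Hz (peak frequency)
#' @export
setClass("CriterionConfig",
  representation(modality = "character", cutoff = "numeric"))

setValidity("CriterionConfig", function(object) {
  if (!object@modality %in% c("V_bi", "V_omni", "PF_bi", "PF_omni"))
    return("modality must be one of V_bi, V_omni, PF_bi, PF_omni")
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) || object@cutoff <= 0)
    return("cutoff must be a positive scalar")
  TRUE
})

#' @param modality,cutoff see [CriterionConfig-class]
#' @rdname CriterionConfig-class
#' @export
criterionConfig <- function(modality, cutoff) {
  new("CriterionConfig", modality = modality, cutoff = cutoff)
}

setMethod("show", "CriterionConfig", function(object) {
  unit <- if (startsWith(object@modality, "V")) "mV" else "Hz"
  cat(sprintf("CriterionConfig: %s >= %.4g %s => gap\n",
      object@modality, object@cutoff, unit))
})

#' Reference clinical cutoffs
#'
#' The four Youden-optimal cutoffs established on first-pass conduction gaps
#' (phase-1 mapping data): 0.20 mV bipolar voltage, 0.32 mV omnipolar
#' voltage, 190.25 Hz bipolar peak frequency, 222.82 Hz omnipolar peak
#' frequency. These are configuration defaults for [classifySite()] and
#' [runPhase2()]; they are properties of the clinical mapping series, not of
#' the synthetic simulator.
#'
#' @return named list of four [CriterionConfig-class] objects
#' @examples
#' referenceCutoffs()$PF_bi
#' @export
referenceCutoffs <- function() {
  list(
    V_bi    = criterionConfig("V_bi", 0.20),
    V_omni  = criterionConfig("V_omni", 0.32),
    PF_bi   = criterionConfig("PF_bi", 190.25),
    PF_omni = criterionConfig("PF_omni", 222.82)
  )
}
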