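#' Annotate one mapping site in all four modalities
#'
#' Computes the per-site scalars used by the gap/block criteria:
#' \describe{
#'   \item{V_bi}{largest peak-to-peak voltage over the four adjacent
#'     (pitch-separated) bipoles of the clique -- the grid-catheter "best
#'     bipole" convention, so the annotation is not blind to wavefronts
#'     parallel to one bipole axis.}
#'   \item{PF_bi}{peak-frequency annotation of that best (displayed)
#'     bipole.}
#'   \item{V_omni}{omnipolar peak-to-peak voltage from [cliqueOmnipolar()].}
#'   \item{PF_omni}{peak-frequency annotation of the omnipolar electrogram.}
#' }
#'
#' @param rec a [CliqueRecording-class]
#' @param freqs analysis frequency grid (Hz)
#' @param relFrac relative scalogram threshold for the PF trace
#' @param absFloor absolute scalogram floor; see [pfNoiseFloor()]
#' @param bandwidth wavelet bandwidth parameter
#' @param window half-open annotation window `c(startMs, endMs)` or `NULL`
#'   for the whole record
#' @return named numeric: `V_bi`, `V_omni` (mV), `PF_bi`, `PF_omni` (Hz)
#' @examples
#' rec <- simulateSite(synthConfig(), "gap", seed = 5)
#' annotateSite(rec)
#' @export
annotateSite <- function(rec, freqs = frequencyGrid(), relFrac = 0.1,
                         absFloor = 0, bandwidth = 1.5, window = NULL) {
  stopifnot(is(rec, "CliqueRecording"))
  fs <- rec@fs
  bips <- lapply(.adjacentPairs, function(p) bipolarEgm(rec, p))
  vv <- vapply(bips, annotateVoltage, numeric(1), fs = fs, window = window)
  vBi <- max(vv)
  pfBi <- annotatePf(bips[[which.max(vv)]], fs, freqs, relFrac, absFloor,
                     bandwidth, window)
  omni <- cliqueOmnipolar(rec)
  vOmni <- annotateVoltage(omni$egm, fs, window)
  pfOmni <- annotatePf(omni$egm, fs, freqs, relFrac, absFloor,
                       bandwidth, window)
  c(V_bi = vBi, V_omni = vOmni, PF_bi = pfBi, PF_omni = pfOmni)
}

#' Annotate a simulated cohort
#'
#' Runs [annotateSite()] over every recording of a cohort from
#' [simulateCohort()]. Unless given explicitly, the absolute PF floor is the
#' noise-referenced detection floor of [pfNoiseFloor()] computed for the
#' bipolar noise level `sqrt(2) * noiseSd`, so pure-noise records annotate
#' 0 Hz rather than their top noise frequency.
#'
#' @param cohort list with `recordings` and `labels`, as returned by
#'   [simulateCohort()]
#' @param noiseSd unipolar white-noise SD of the recordings (mV), used for
#'   the default floor
#' @inheritParams annotateSite
#' @return data.frame: `site_id`, `V_bi`, `V_omni`, `PF_bi`, `PF_omni`
#' @examples
#' coh <- simulateCohort(synthConfig(nSites = 4, seed = 3))
#' annotateCohort(coh)
#' @export
annotateCohort <- function(cohort, freqs = frequencyGrid(), relFrac = 0.1,
                           absFloor = NULL, bandwidth = 1.5, window = NULL,
                           noiseSd = 0.01) {
  recs <- cohort$recordings
  if (is.null(recs) || !length(recs)) stop("cohort has no recordings")
  if (is.null(absFloor)) {
    fs <- recs[[1]]@fs
    absFloor <- pfNoiseFloor(sqrt(2) * noiseSd, fs, max(freqs), bandwidth)
  }
  rows <- lapply(recs, annotateSite, freqs = freqs, relFrac = relFrac,
                 absFloor = absFloor, bandwidth = bandwidth, window = window)
  ann <- do.call(rbind, rows)
  data.frame(site_id = vapply(recs, siteId, character(1)),
             as.data.frame(ann), row.names = NULL,
             stringsAsFactors = FALSE)
}
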