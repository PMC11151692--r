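#' Call gap versus block for one site annotation
#'
#' A site is called *gap* when the criterion's modality value is greater
#' than or equal to its cutoff; ties call gap (the clinically safer
#' direction -- a borderline site is flagged for inspection). High residual
#' voltage and high peak frequency on the ablation line both indicate
#' surviving conduction, so every modality uses the same ">=" sense.
#'
#' @param ann named numeric or one-row data.frame holding the modality
#'   value(s), e.g. the output of [annotateSite()]
#' @param crit a [CriterionConfig-class]
#' @return `"gap"` or `"block"`
#' @examples
#' classifySite(c(PF_bi = 250), referenceCutoffs()$PF_bi)
#' @export
classifySite <- function(ann, crit) {
  stopifnot(is(crit, "CriterionConfig"))
  validObject(crit)
  v <- if (!crit@modality %in% names(ann)) NULL
       else if (is.data.frame(ann)) ann[[crit@modality]][1]
       else unname(ann[crit@modality])
  if (is.null(v) || length(v) != 1L || is.na(v))
    stop("annotation has no value for modality ", crit@modality)
  if (!is.finite(v) || v < 0)
    stop("modality value must be finite and non-negative")
  if (v >= crit@cutoff) "gap" else "block"
}

#' Aggregate site calls to a PV-line segment call
#'
#' Existential aggregation: a segment is *gap* if any of its member sites is
#' called gap; only a segment whose sites are all block is called block.
#'
#' @param siteCalls character vector of `"gap"`/`"block"` site calls
#' @return `"gap"` or `"block"`
#' @examples
#' segmentCall(c("block", "gap", "block"))
#' @export
segmentCall <- function(siteCalls) {
  if (!length(siteCalls)) stop("segment has no sites")
  if (!all(siteCalls %in% c("gap", "block")))
    stop("site calls must be 'gap' or 'block'")
  if (any(siteCalls == "gap")) "gap" else "block"
}

#' Classify a cohort of annotations under one or more criteria
#'
#' Applies each criterion to every annotated site and aggregates to
#' segments with [segmentCall()].
#'
#' @param annotations data.frame from [annotateCohort()]
#' @param labels data.frame with `site_id` and `segment_id` (e.g. the
#'   cohort's `labels`)
#' @param criteria list of [CriterionConfig-class]; default
#'   [referenceCutoffs()]
#' @return list with `sites` (data.frame `site_id, segment_id, criterion,
#'   call`) and `segments` (data.frame `segment_id, criterion, call`)
#' @examples
#' coh <- simulateCohort(synthConfig(nSites = 8, seed = 3))
#' cls <- classifyCohort(annotateCohort(coh), coh$labels)
#' head(cls$segments)
#' @export
classifyCohort <- function(annotations, labels, criteria = referenceCutoffs()) {
  if (!all(annotations$site_id %in% labels$site_id))
    stop("annotations contain sites absent from labels")
  seg <- labels$segment_id[match(annotations$site_id, labels$site_id)]
  siteRows <- list()
  segRows <- list()
  for (nm in names(criteria)) {
    crit <- criteria[[nm]]
    calls <- vapply(seq_len(nrow(annotations)), function(i)
      classifySite(annotations[i, ], crit), character(1))
    siteRows[[nm]] <- data.frame(
      site_id = annotations$site_id, segment_id = seg,
      criterion = nm, call = calls, stringsAsFactors = FALSE)
    agg <- tapply(calls, seg, segmentCall)
    segRows[[nm]] <- data.frame(
      segment_id = as.integer(names(agg)), criterion = nm,
      call = as.character(agg), stringsAsFactors = FALSE)
  }
  list(sites = do.call(rbind, c(siteRows, make.row.names = FALSE)),
       segments = do.call(rbind, c(segRows, make.row.names = FALSE)))
}
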