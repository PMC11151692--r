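#' Diagnostic metrics from a contingency table
#'
#' Sensitivity, specificity, positive and negative predictive value, in
#' percent, unrounded (round only at the reporting layer with
#' [roundHalfUp()]). Requesting a metric whose denominator is zero is an
#' explicit error, never silently 0.
#'
#' @param tab a [ContingencyTable-class]
#' @param metrics which metrics to compute
#' @return named numeric vector of percentages
#' @examples
#' contingencyMetrics(contingencyTable(tp = 19, fp = 5, fn = 18, tn = 150))
#' @export
contingencyMetrics <- function(tab, metrics = c("se", "sp", "ppv", "npv")) {
  stopifnot(is(tab, "ContingencyTable"))
  validObject(tab)
  metrics <- match.arg(metrics, several.ok = TRUE)
  den <- c(se = tab@tp + tab@fn, sp = tab@tn + tab@fp,
           ppv = tab@tp + tab@fp, npv = tab@tn + tab@fn)
  num <- c(se = tab@tp, sp = tab@tn, ppv = tab@tp, npv = tab@tn)
  bad <- metrics[den[metrics] == 0L]
  if (length(bad))
    stop("metric(s) undefined (zero denominator): ", paste(bad, collapse = ", "))
  100 * num[metrics] / den[metrics]
}

#' Reconstruct contingency counts from printed percentages
#'
#' Given one or more criterion rows of printed one-decimal percentages
#' (SE, SP, PPV, NPV) that were all computed against the same ground truth
#' (`nGap` true positives' universe and a shared, unknown number of true
#' negatives), exhaustively enumerates integer contingency tables -- `tp`
#' over `0..nGap`, a shared `nBlock` over `1..nBlockMax`, `fp` over
#' `0..nBlock` -- whose four metrics simultaneously round (one decimal, half
#' away from zero) to the printed values for every row. Returns the
#' minimal-`nBlock` solution and asserts it is unique.
#'
#' @param metricRows data.frame or matrix with columns `se`, `sp`, `ppv`,
#'   `npv` (percent, as printed), one row per criterion
#' @param nGap number of true gap segments
#' @param nBlockMax upper bound of the shared block-segment count to search
#' @return list with `nBlock` and `tables` (one [ContingencyTable-class]
#'   per input row)
#' @examples
#' reconstructCounts(data.frame(se = 100, sp = 100, ppv = 100, npv = 100),
#'                   nGap = 2)
#' @export
reconstructCounts <- function(metricRows, nGap, nBlockMax = 1000) {
  metricRows <- as.data.frame(metricRows)
  stopifnot(all(c("se", "sp", "ppv", "npv") %in% names(metricRows)),
            nGap >= 1)
  tol <- 1e-9
  matches <- function(x, printed) abs(roundHalfUp(x, 1) - printed) < tol

  nRows <- nrow(metricRows)
  tpCands <- lapply(seq_len(nRows), function(r) {
    tp <- 0:nGap
    tp[matches(100 * tp / nGap, metricRows$se[r])]
  })
  if (any(!lengths(tpCands)))
    stop("no tp count reproduces a printed sensitivity for nGap = ", nGap)

  for (nb in seq_len(nBlockMax)) {
    rowSol <- vector("list", nRows)
    ok <- TRUE
    for (r in seq_len(nRows)) {
      fp <- 0:nb
      fp <- fp[matches(100 * (nb - fp) / nb, metricRows$sp[r])]
      sols <- list()
      for (tp in tpCands[[r]]) for (f in fp) {
        tn <- nb - f
        fn <- nGap - tp
        if (tp + f == 0L || tn + fn == 0L) next
        if (matches(100 * tp / (tp + f), metricRows$ppv[r]) &&
            matches(100 * tn / (tn + fn), metricRows$npv[r]))
          sols[[length(sols) + 1L]] <- c(tp = tp, fp = f)
      }
      if (!length(sols)) { ok <- FALSE; break }
      rowSol[[r]] <- sols
    }
    if (ok) {
      if (any(lengths(rowSol) > 1L))
        stop("minimal-nBlock solution is not unique at nBlock = ", nb)
      tables <- lapply(rowSol, function(s) {
        contingencyTable(tp = s[[1]]["tp"], fp = s[[1]]["fp"],
                         fn = nGap - s[[1]]["tp"], tn = nb - s[[1]]["fp"])
      })
      return(list(nBlock = nb, tables = tables))
    }
  }
  stop("no consistent integer contingency tables found for nBlock <= ",
       nBlockMax)
}

#' ROC analysis of a ">= threshold calls gap" criterion
#'
#' Sweeps the candidate thresholds (the unique observed scores plus a +Inf
#' sentinel under which nothing is called positive), computes sensitivity
#' and specificity at each, the trapezoidal AUC, and the Youden-optimal
#' cutoff. Youden ties break toward the threshold with the higher
#' specificity; the reported cutoff is by default the midpoint between the
#' optimal threshold and the next lower unique score (set
#' `interp = "observed"` to report the raw observed threshold).
#'
#' @param scores per-site annotation values (higher = more gap-like)
#' @param truth logical (TRUE = gap) or character `"gap"`/`"block"` per site
#' @param interp cutoff reporting convention, `"midpoint"` or `"observed"`
#' @return a [RocResult-class]
#' @examples
#' rocAnalysis(c(2, 3, 0, 1), c("gap", "gap", "block", "block"))
#' @export
rocAnalysis <- function(scores, truth, interp = c("midpoint", "observed")) {
  interp <- match.arg(interp)
  if (is.character(truth)) {
    if (!all(truth %in% c("gap", "block")))
      stop("character truth must be 'gap'/'block'")
    truth <- truth == "gap"
  }
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!any(truth) || all(truth)) stop("both classes must be present")

  g <- scores[truth]
  b <- scores[!truth]
  thr <- c(sort(unique(scores)), Inf)
  se <- vapply(thr, function(t) mean(g >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(b < t), numeric(1))

  fpr <- 1 - sp
  ord <- order(fpr, se)                  # (0,0) .. (1,1)
  xs <- c(fpr[ord], 1)
  ys <- c(se[ord], 1)
  auc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)

  j <- se + sp - 1
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[max(which(sp[best] == max(sp[best])))]  # ties -> higher sp
  tStar <- thr[best]
  cutoff <- tStar
  if (interp == "midpoint") {
    lower <- scores[scores < tStar]
    if (!is.finite(tStar)) cutoff <- max(scores)
    else if (length(lower)) cutoff <- (tStar + max(lower)) / 2
  } else if (!is.finite(tStar)) cutoff <- max(scores)

  new("RocResult", thresholds = thr, se = se, sp = sp, auc = auc,
      youdenCutoff = cutoff, youdenJ = max(j), youdenThreshold = tStar)
}

#' Phase-1 evaluation: per-modality ROC with Youden cutoffs
#'
#' Runs [rocAnalysis()] on each annotation modality against the site ground
#' truth -- the discrimination of first-pass conduction gaps from blocks --
#' and summarises AUC, optimal cutoff, and sensitivity/specificity at the
#' Youden point.
#'
#' @param annotations data.frame from [annotateCohort()]
#' @param labels data.frame with `site_id` and `truth`
#' @param modalities which annotation columns to evaluate
#' @param interp cutoff convention, see [rocAnalysis()]
#' @return list with `summary` (data.frame: modality, auc, cutoff, youdenJ,
#'   se, sp in percent) and `roc` (named list of [RocResult-class])
#' @export
runPhase1 <- function(annotations, labels,
                      modalities = c("V_bi", "V_omni", "PF_bi", "PF_omni"),
                      interp = "midpoint") {
  truth <- labels$truth[match(annotations$site_id, labels$site_id)]
  if (anyNA(truth)) stop("annotations contain sites absent from labels")
  if (!all(modalities %in% names(annotations)))
    stop("annotations lack modality column(s): ",
         paste(setdiff(modalities, names(annotations)), collapse = ", "))
  roc <- lapply(modalities, function(m)
    rocAnalysis(annotations[[m]], truth, interp))
  names(roc) <- modalities
  summary <- data.frame(
    modality = modalities,
    auc = vapply(roc, aucValue, numeric(1)),
    cutoff = vapply(roc, youdenCutoff, numeric(1)),
    youdenJ = vapply(roc, youdenJ, numeric(1)),
    se = vapply(roc, function(r) 100 * r@se[match(r@youdenThreshold, r@thresholds)],
                numeric(1)),
    sp = vapply(roc, function(r) 100 * r@sp[match(r@youdenThreshold, r@thresholds)],
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, roc = roc)
}

#' Phase-2 evaluation: segment-level contingency accuracy
#'
#' Compares per-criterion segment calls (dormant-gap detection during the
#' index procedure) against a segment-level ground truth (gaps found at
#' redo), building one contingency table per criterion and reporting
#' SE/SP/PPV/NPV.
#'
#' @param segmentCalls data.frame with `segment_id`, `criterion`, `call`
#'   (as from [classifyCohort()]`$segments`)
#' @param truthLabels data.frame with `segment_id`, `truth`
#'   (`"gap"`/`"block"`)
#' @return list with `tables` (named list of [ContingencyTable-class]) and
#'   `metrics` (data.frame: criterion, se, sp, ppv, npv in percent,
#'   unrounded; a metric with an empty denominator reports NA)
#' @export
runPhase2 <- function(segmentCalls, truthLabels) {
  crits <- unique(segmentCalls$criterion)
  tables <- list()
  rows <- list()
  for (cr in crits) {
    calls <- segmentCalls[segmentCalls$criterion == cr, ]
    if (!setequal(calls$segment_id, truthLabels$segment_id))
      stop("segment sets differ between calls and truth for criterion ", cr)
    truth <- truthLabels$truth[match(calls$segment_id, truthLabels$segment_id)]
    isGap <- truth == "gap"
    called <- calls$call == "gap"
    tab <- contingencyTable(
      tp = sum(called & isGap), fp = sum(called & !isGap),
      fn = sum(!called & isGap), tn = sum(!called & !isGap))
    tables[[cr]] <- tab
    m <- vapply(c("se", "sp", "ppv", "npv"), function(x)
      tryCatch(contingencyMetrics(tab, x), error = function(e) NA_real_),
      numeric(1))                       # undefined metrics report as NA
    rows[[cr]] <- data.frame(criterion = cr, se = m["se"], sp = m["sp"],
                             ppv = m["ppv"], npv = m["npv"],
                             stringsAsFactors = FALSE)
  }
  list(tables = tables,
       metrics = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Percentage of a count, reporting convention
#'
#' One-decimal percentage with half-away-from-zero rounding, the convention
#' used for all reported proportions (e.g. 26 recurrences in 88 patients
#' report as 29.5).
#'
#' @param k numerator count
#' @param n denominator count
#' @return percentage rounded to one decimal
#' @examples
#' proportionPct(26, 88)
#' @export
proportionPct <- function(k, n) {
  if (n <= 0) stop("denominator must be positive")
  roundHalfUp(100 * k / n, 1)
}

#' Reference phase-2 accuracy table
#'
#' The published segment-level accuracy of the four dormant-gap criteria
#' against gaps found at redo procedures (37 gap segments): printed
#' one-decimal percentages for SE, SP, PPV and NPV per criterion. Used as
#' the input to [reconstructCounts()], which recovers the integer
#' contingency tables behind these percentages.
#'
#' @return data.frame with columns `criterion`, `se`, `sp`, `ppv`, `npv`
#'   and attribute `nGap = 37`
#' @examples
#' referencePhase2Metrics()
#' @export
referencePhase2Metrics <- function() {
  out <- data.frame(
    criterion = c("V_bi", "V_omni", "PF_bi", "PF_omni"),
    se  = c(16.2, 10.8, 51.4, 54.1),
    sp  = c(96.1, 97.4, 96.8, 95.5),
    ppv = c(50.0, 50.0, 79.2, 74.1),
    npv = c(82.8, 82.1, 89.3, 89.7),
    stringsAsFactors = FALSE)
  attr(out, "nGap") <- 37L
  out
}

#' @importFrom utils head
NULL
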