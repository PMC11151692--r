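#' Round half away from zero
#'
#' Reporting-layer rounding used for all printed percentages: ties go away
#' from zero (so 96.15 -> 96.2), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1, the reporting convention)
#' @return rounded numeric vector
#' @examples
#' roundHalfUp(c(16.25, -16.25))  # 16.3 -16.3
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Peak-to-peak amplitude
#'
#' @param x numeric vector (mV)
#' @return max(x) - min(x); 0 for an empty vector
#' @export
peakToPeak <- function(x) {
  if (!length(x)) return(0)
  max(x) - min(x)
}

## Half-open [startMs, endMs) window -> sample indices (1-based, 0-based ms
## from record start). Errors on empty windows.
windowIndices <- function(n, fs, window) {
  if (is.null(window)) return(seq_len(n))
  if (length(window) != 2L || !all(is.finite(window)) || window[2] <= window[1])
    stop("window must be c(startMs, endMs) with startMs < endMs")
  i0 <- max(1L, as.integer(floor(window[1] * fs / 1000)) + 1L)
  i1 <- min(n, as.integer(ceiling(window[2] * fs / 1000)))
  if (i1 < i0) stop("window [", window[1], ", ", window[2],
                    ") ms contains no samples")
  i0:i1
}

## Deterministic sub-seed derivation, kept below 2^31.
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}
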