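#' Bipolar electrogram from a clique
#'
#' Sample-wise difference between two unipolar channels, the conventional
#' close-bipole recording. Subtraction cancels far-field components that are
#' common to both electrodes.
#'
#' @param rec a [CliqueRecording-class]
#' @param pair two distinct electrode indices; the result is
#'   `u[pair[1]] - u[pair[2]]`
#' @return numeric bipolar signal (mV)
#' @examples
#' rec <- simulateSite(synthConfig(), "gap", seed = 2)
#' b <- bipolarEgm(rec, c(1, 2))
#' @export
bipolarEgm <- function(rec, pair) {
  stopifnot(is(rec, "CliqueRecording"))
  k <- ncol(rec@signals)
  if (length(pair) != 2L || any(pair < 1) || any(pair > k))
    stop("pair must be two electrode indices in 1..", k)
  if (pair[1] == pair[2]) stop("bipole requires two distinct electrodes")
  rec@signals[, pair[1]] - rec@signals[, pair[2]]
}

## Adjacent (pitch-separated) bipole pairs of the 2x2 clique, plus the
## diagonals; used for "best bipole" annotation and dominance checks.
.adjacentPairs <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L))
.allPairs <- utils::combn(4L, 2L, simplify = FALSE)

#' Local electric-field loop of a clique
#'
#' Least-squares fit of the in-plane potential gradient at every sample from
#' all pairwise potential differences and electrode coordinate differences,
#' returning E = -grad(phi). With exactly three electrodes the planar fit
#' interpolates the potentials exactly; with four it is the least-squares
#' plane.
#'
#' @param rec a [CliqueRecording-class]
#' @param electrodes indices of the electrodes to fit over (default: all);
#'   at least three, non-collinear
#' @return an [EFieldLoop-class] (components in mV/mm)
#' @examples
#' rec <- simulateSite(synthConfig(), "gap", seed = 2)
#' loop <- efieldLoop(rec)
#' @export
efieldLoop <- function(rec, electrodes = NULL) {
  stopifnot(is(rec, "CliqueRecording"))
  if (is.null(electrodes)) electrodes <- seq_len(ncol(rec@signals))
  if (length(electrodes) < 3L)
    stop("need at least three electrodes for a planar field fit")
  pts <- rec@coords[electrodes, , drop = FALSE]
  prs <- utils::combn(length(electrodes), 2L)
  D <- t(pts[prs[1, ], , drop = FALSE] - pts[prs[2, ], , drop = FALSE])
  D <- t(D)                                     # n_pairs x 2
  DtD <- crossprod(D)
  if (abs(det(DtD)) < 1e-12 * sum(D^2)^2 || qr(D)$rank < 2L)
    stop("electrode geometry is collinear; gradient fit is singular")
  sig <- rec@signals[, electrodes, drop = FALSE]
  dPhi <- sig[, prs[1, ], drop = FALSE] - sig[, prs[2, ], drop = FALSE]
  G <- solve(DtD, crossprod(D, t(dPhi)))        # 2 x n gradient
  new("EFieldLoop", ex = -G[1, ], ey = -G[2, ], fs = rec@fs)
}

## Orientation sweep: peak-to-peak of the projected bipole-equivalent signal
## at each orientation. Returns the maximum and its orientation (ties break
## toward the smaller angle).
.omniSweep <- function(loop, pitchMm, thetaStepDeg = 1) {
  th <- seq(0, pi - 1e-9, by = thetaStepDeg * pi / 180)
  # orientation-major projection matrix: row = orientation, column = sample
  P <- pitchMm * (outer(cos(th), loop@ex) + outer(sin(th), loop@ey))
  i <- seq_along(th)
  pp <- P[cbind(i, max.col(P, "first"))] - P[cbind(i, max.col(-P, "first"))]
  j <- which.max(pp)                    # ties break toward smaller theta
  list(v = pp[j], theta = th[j], signal = P[j, ])
}

#' Omnipolar peak-to-peak voltage of a field loop
#'
#' Maximum over bipole orientations (discretised at `thetaStepDeg`) of the
#' peak-to-peak amplitude of the projected signal
#' `pitchMm * (ex * cos(theta) + ey * sin(theta))` -- the orientation-independent
#' voltage of the clique, expressed at physical electrode pitch so the
#' result is in mV and comparable to bipolar voltage cutoffs.
#'
#' @param loop an [EFieldLoop-class]
#' @param pitchMm electrode pitch used to scale the projection (mm)
#' @param thetaStepDeg orientation grid step (degrees)
#' @return omnipolar peak-to-peak voltage (mV)
#' @export
omnipolarVoltage <- function(loop, pitchMm = 2, thetaStepDeg = 1) {
  stopifnot(is(loop, "EFieldLoop"))
  .omniSweep(loop, pitchMm, thetaStepDeg)$v
}

#' Omnipolar electrogram of a field loop
#'
#' The projection of the E-field loop onto the orientation that maximises
#' peak-to-peak amplitude (the omnipolar voltage orientation), scaled to
#' physical pitch. This is the signal fed to [annotatePf()] for the
#' omnipolar peak-frequency modality.
#'
#' @inheritParams omnipolarVoltage
#' @return numeric signal (mV)
#' @export
omnipolarEgm <- function(loop, pitchMm = 2, thetaStepDeg = 1) {
  stopifnot(is(loop, "EFieldLoop"))
  .omniSweep(loop, pitchMm, thetaStepDeg)$signal
}

#' Omnipolar annotation of a full 2x2 clique
#'
#' Fits the E-field loop on each of the four 3-electrode (triangular)
#' sub-cliques and keeps the one with the largest omnipolar voltage. On
#' three electrodes the planar fit is exact, so every bipole inside the
#' winning triangle is exactly a projection of its loop; the omnipolar
#' voltage therefore dominates every pitch-normalised clique bipole.
#'
#' @param rec a [CliqueRecording-class] with four electrodes
#' @param thetaStepDeg orientation grid step (degrees)
#' @return list with `vOmni` (mV), `egm` (the maximal-orientation projected
#'   signal, mV), `theta` (radians), `electrodes` (winning triangle), and
#'   `loop` (its [EFieldLoop-class])
#' @examples
#' rec <- simulateSite(synthConfig(), "gap", seed = 2)
#' omni <- cliqueOmnipolar(rec)
#' omni$vOmni
#' @export
cliqueOmnipolar <- function(rec, thetaStepDeg = 1) {
  stopifnot(is(rec, "CliqueRecording"), ncol(rec@signals) == 4L)
  pitch <- .cliquePitch(rec)
  best <- NULL
  for (drop in 1:4) {
    el <- setdiff(1:4, drop)
    loop <- efieldLoop(rec, el)
    sw <- .omniSweep(loop, pitch, thetaStepDeg)
    if (is.null(best) || sw$v > best$vOmni)
      best <- list(vOmni = sw$v, egm = sw$signal, theta = sw$theta,
                   electrodes = el, loop = loop)
  }
  best
}

## Smallest inter-electrode distance = physical pitch of the clique.
.cliquePitch <- function(rec) {
  d <- as.matrix(stats::dist(rec@coords))
  min(d[upper.tri(d)])
}
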