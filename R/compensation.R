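## compensation: stalled-point detection, CNN interrogation, and the
## probability-weighted speed compensation that lets the contour escape
## lesion edges.

#' The speed-compensation term
#'
#' \deqn{\exp(|\lambda_1 + \lambda_2|^{1/2})
#'       \left(\frac{1 + p_2}{1 + p_1} - \frac12\right)}
#' where `p1` is the probability that the inspected point sits on the true
#' sinus boundary and `p2` that it sits on lesion.  The term is zero at
#' `(p1, p2) = (1, 0)` — a confirmed boundary point receives no push — and
#' maximal at `(0, 1)`; it is non-negative on the whole probability square
#' and strictly decreasing in `p1` along `p2 = 1 - p1`.
#'
#' @param probs numeric (p1, p2), each in [0, 1].
#' @param lambda1,lambda2 the energy weights.
#' @return scalar >= 0.
#' @examples
#' compensationTerm(c(0, 1), 1, 1)    # 1.5 * exp(sqrt(2))
#' compensationTerm(c(1, 0), 1, 1)    # exactly 0
#' @export
compensationTerm <- function(probs, lambda1, lambda2) {
  p1 <- probs[1]; p2 <- probs[2]
  if (any(c(p1, p2) < -1e-9) || any(c(p1, p2) > 1 + 1e-9))
    stop("class probabilities must lie in [0, 1]")
  exp(sqrt(abs(lambda1 + lambda2))) * ((1 + p2) / (1 + p1) - 0.5)
}

#' Decide what to do with a stalled point
#'
#' Implements the drop rule: when `|p1 - p2|` is at or below the ambiguity
#' margin the point is dropped (`"ambiguous"`, no compensation).  Otherwise
#' `p2 > p1` marks it `"compensated"` and `p1 > p2` marks it
#' `"confirmed_boundary"` — the point keeps its status for the rest of the
#' run.
#'
#' @param probs numeric (p1, p2).
#' @param cfg a [RunConfig] (uses `ambiguityMargin`).
#' @return one of `"ambiguous"`, `"compensated"`, `"confirmed_boundary"`.
#' @export
decidePoint <- function(probs, cfg) {
  if (any(!is.finite(probs))) stop("stalled point has no class probabilities")
  if (abs(probs[1] - probs[2]) <= cfg@ambiguityMargin) "ambiguous"
  else if (probs[2] > probs[1]) "compensated"
  else "confirmed_boundary"
}

#' Detect stalled contour points
#'
#' A contour point is stalled when the interface has not moved near it —
#' no pixel within 2 px has changed sides — for `stability_window`
#' consecutive iterations.  Before the window has elapsed nothing is
#' reported.  (Interface motion, not raw force magnitude, is the right
#' stall signal for the discrete evolution: at a settled boundary the
#' pixel-centre forces retain their restoring values while the contour
#' itself is perfectly stationary.)
#'
#' @param state an [EvolutionState] (its `speedHistory` ring buffer holds
#'   the recent interface-activity maps).
#' @param cfg a [RunConfig].
#' @return logical matrix marking stalled contour points.
#' @export
detectStalledPoints <- function(state, cfg) {
  .stalledFrom(state@speedHistory, state@runningMax, state@phi, cfg)
}

#' Classify the local region of a contour point
#'
#' Extracts the 10x10 patch centred on `location`, runs the preprocessing
#' pipeline (bilinear upsampling to 32x32, CLAHE) and the trained CNN in
#' inference mode (shadow weights, frozen batch-norm statistics, no
#' dropout); deterministic for a fixed model.
#'
#' @param model a trained [PatchCNN].
#' @param image the (normalized) image being segmented.
#' @param location integer (row, col), at least 5 px from every border.
#' @return numeric `(p1, p2)`: boundary and lesion probabilities summing
#'   to 1.
#' @export
classifyPoint <- function(model, image, location) {
  if (!model@trained) stop("classifyPoint requires a trained model")
  p <- extractPatch(image, location)
  pr <- predictCNN(model, p@enhanced)
  c(p1 = unname(pr[1]), p2 = unname(pr[2]))
}

#' Inject compensation into a speed field
#'
#' For every point with status `"compensated"` the non-negative term from
#' [compensationTerm()] is added to the data integrand over the point's
#' local region: every pixel within `arc_radius` of the point has its speed
#' decreased by `term * m0` where `m0` is the pixel's local Dirac mass
#' (`coupling = "ball"`), or by the bare term (`coupling = "direct"`).
#' The spatial spread matters: a single pixel's speed cannot move an
#' interface on its own — the whole local arc, including the pixels just
#' outside the contour, must feel the outward drive.  The sign is strictly
#' outward (interior-growing); points with any other status are untouched.
#'
#' @param speed data-speed matrix.
#' @param compAmount matrix of compensation terms (0 where none).
#' @param m0 matrix of local Dirac masses (from the speed-field moments).
#' @param cfg a [RunConfig].
#' @return the compensated speed matrix.
#' @export
applyCompensation <- function(speed, compAmount, m0, cfg) {
  if (!any(compAmount > 0)) return(speed)
  spread <- convDisk(compAmount, diskKernel(cfg@arcRadius))
  spread[abs(spread) < 1e-8] <- 0   # strip FFT dust outside the disks
  boost <- if (cfg@compensationCoupling == "ball") spread * m0
           else spread
  speed - boost
}
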