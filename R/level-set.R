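## level_set: signed-distance field, mollified Heaviside/Dirac, curvature,
## distance regularization (no reinitialization), narrow band, and the
## generic evolution update.
##
## Convention (fixed throughout): phi < 0 inside the evolving foreground,
## phi > 0 outside, the zero level set is the contour.  The mollified
## Heaviside is oriented so that heaviside(phi) counts the *interior*:
## H(-inf) -> 1, H(+inf) -> 0, H(0) = 0.5.  A *positive* speed increases phi
## and therefore shrinks the interior; expansion forces are negative.

#' Initialize the level set as the signed distance to a circle
#'
#' @param shape image size (rows, cols).
#' @param center circle centre (row, col).
#' @param radius circle radius in pixels (>= 2).
#' @return matrix `phi` with `phi(p) = |p - center| - radius` (negative
#'   inside), an exact signed distance function.
#' @export
initPhiCircle <- function(shape, center, radius) {
  if (radius < 2) stop("initial radius must be >= 2 px")
  if (center[1] - radius < 1 || center[2] - radius < 1 ||
      center[1] + radius > shape[1] || center[2] + radius > shape[2])
    stop("initial circle touches the image border")
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) - radius
}

#' Mollified Heaviside and Dirac
#'
#' The compact-support cosine pair used throughout distance-regularized
#' level-set practice:
#' \deqn{H_\epsilon(z) = \tfrac12\left(1 - \tfrac{z}{\epsilon}
#'       - \tfrac1\pi \sin(\pi z/\epsilon)\right),\quad |z| \le \epsilon,}
#' (1 for `z < -eps`, 0 for `z > eps`), oriented so that `heaviside(phi)`
#' counts the *interior* (`phi < 0`).  `dirac` is `|H'|`:
#' \deqn{\delta_\epsilon(z) = \frac{1}{2\epsilon}
#'       \left(1 + \cos(\pi z/\epsilon)\right), \quad |z| \le \epsilon,}
#' zero outside, peaking at `1/eps` on the contour and integrating to 1
#' along a transect.  The compact support matters: a heavy-tailed mollifier
#' keeps draining the field well away from the contour, which steepens the
#' profile and — combined with the distance regularizer — pushes the front
#' through weak boundaries.
#'
#' @param z value(s) of phi.
#' @param eps smoothing width (> 0).
#' @return values in [0, 1] (`heaviside`) or >= 0 (`dirac`).
#' @export
heaviside <- function(z, eps = 1.5) {
  if (eps <= 0) stop("heaviside smoothing width must be > 0")
  zc <- pmin(pmax(z, -eps), eps)
  0.5 * (1 - zc / eps - sin(pi * zc / eps) / pi)
}

#' @rdname heaviside
#' @export
dirac <- function(z, eps = 1.5) {
  if (eps <= 0) stop("dirac smoothing width must be > 0")
  ifelse(abs(z) <= eps, (1 + cos(pi * z / eps)) / (2 * eps), 0)
}

#' Narrow band of the level-set field
#'
#' @param phi level-set matrix.
#' @param width half-width in pixels.
#' @return logical matrix, `TRUE` where `|phi| <= width`.  An all-`FALSE`
#'   band (no foreground left) is the caller's termination signal.
#' @export
narrowBand <- function(phi, width) {
  if (width < 1) stop("band width must be >= 1")
  abs(phi) <= width
}

#' Mean curvature of the level-set contour
#'
#' Central-difference discretization of `div(grad phi / |grad phi|)` with
#' replicate border padding and the gradient magnitude floored at 1e-8.
#' For a convex foreground (interior-negative phi) the curvature is positive
#' on the contour; for a circle of radius r it is approximately 1/r.
#'
#' @param phi level-set matrix.
#' @return matrix of curvature values.
#' @export
curvatureField <- function(phi) {
  g <- gradCentral(phi)
  mag <- pmax(sqrt(g$dr^2 + g$dc^2), 1e-8)
  nr <- g$dr / mag
  nc <- g$dc / mag
  (shiftDown(nr) - shiftUp(nr)) / 2 + (shiftRight(nc) - shiftLeft(nc)) / 2
}

#' @rdname curvatureField
#' @param point integer (row, col), at least one pixel from the border.
#' @export
curvatureAt <- function(phi, point) {
  r <- point[1]; c0 <- point[2]
  win <- phi[max(1, r - 2):min(nrow(phi), r + 2),
             max(1, c0 - 2):min(ncol(phi), c0 + 2)]
  k <- curvatureField(win)
  k[min(r, 3), min(c0, 3)]
}

## Diffusion coefficient of the distance-regularization flow:
## dp(s) = p'(s)/s for the single-well potential p(s) = (s - 1)^2 / 2, with
## the backward-diffusion branch capped at -1 for stability.  The flow
## restores |grad phi| = 1 from both sides: shelves with |grad phi| << 1
## (which form just behind a moving front when the data flow drains the
## profile) are steepened back into a distance profile rather than being
## preserved as a second potential well would do.
.dwCoef <- function(s) {
  pmax((s - 1) / pmax(s, 1e-8), -1)
}

#' One distance-regularization step (evolution without reinitialization)
#'
#' Applies one explicit step of the double-well distance-regularization flow
#' `phi <- phi + dt * weight * div(dp(|grad phi|) grad phi)`, which restores
#' the signed-distance profile `|grad phi| = 1` near the contour without ever
#' recomputing distances.  An exact SDF is (up to discretization) a fixed
#' point.
#'
#' @param phi level-set matrix.
#' @param weight regularization weight (`weight * dt < 0.25` for stability).
#' @param dt time step.
#' @param mask optional logical matrix: update only these pixels.
#' @return the regularized field.
#' @export
distanceRegularize <- function(phi, weight = 0.2, dt = 1, mask = NULL) {
  if (weight * dt >= 0.25)
    stop("unstable distance regularization: weight * dt must be < 0.25")
  ## half-point flux discretization: flux at i+1/2 uses the one-sided
  ## difference, so single-pixel cliffs relax at full strength (a central
  ## divergence smears them over two cells and nearly cancels)
  dpr <- shiftDown(phi) - phi   # phi[i+1] - phi[i]
  dpc <- shiftRight(phi) - phi
  fr <- .dwCoef(abs(dpr)) * dpr
  fc <- .dwCoef(abs(dpc)) * dpc
  dphi <- (fr - shiftUp(fr)) + (fc - shiftLeft(fc))
  out <- if (is.null(mask)) phi + dt * weight * dphi
  else {
    tmp <- phi
    tmp[mask] <- tmp[mask] + dt * weight * dphi[mask]
    tmp
  }
  ## The regularizer conditions the field but must not move the interface:
  ## a pixel whose sign would flip under this step is pinned just on its
  ## old side.  Without this anchor the diffusion across the zero crossing
  ## advects the contour (slow systematic creep through weak boundaries).
  flip <- (sign(out) != sign(phi)) & (phi != 0)
  if (any(flip)) out[flip] <- sign(phi[flip]) * 1e-8
  out
}

#' Inner contour points of the zero level set
#'
#' Lattice sites with `phi <= 0` that have a 4-neighbour with `phi > 0`
#' (a one-pixel-thick contour on the interior side).
#'
#' @param phi level-set matrix.
#' @return logical matrix marking contour pixels; all-`FALSE` (with a
#'   warning when the foreground touches no background) signals a vanished
#'   or border-filling contour.
#' @export
contourPoints <- function(phi) {
  fg <- phi <= 0
  if (!any(fg)) return(matrix(FALSE, nrow(phi), ncol(phi)))
  bg <- !fg
  nb <- shiftUp(bg) | shiftDown(bg) | shiftLeft(bg) | shiftRight(bg)
  out <- fg & nb
  if (!any(out)) warning("foreground fills the image: contour at border")
  out
}

#' Create an evolution state
#'
#' @param phi initial signed-distance field (see [initPhiCircle()]).
#' @return an [EvolutionState] at iteration 0.
#' @export
newEvolutionState <- function(phi) {
  new("EvolutionState", phi = phi, iteration = 0L,
      energyTrace = numeric(0), speedHistory = list(),
      runningMax = 0)
}

#' One evolution step
#'
#' Updates the band pixels by
#' `phi <- phi + dt * eps * dirac(phi) * (speed + mu * curvature)` (the
#' Dirac factor is normalized to peak 1, so `dt = 0.45` bounds the
#' per-iteration displacement at the contour by 0.45 px), then applies one
#' distance-regularization step on the band plus a 3-px spatial margin,
#' excluding the inner part of the Dirac support so the regularizer cannot
#' advect the interface.  Pixels outside the dilated band are untouched.
#'
#' @param state an [EvolutionState].
#' @param speed matrix of data speeds (positive shrinks the interior);
#'   only band values are used and must be finite.
#' @param cfg a [RunConfig].
#' @param image optional image for the energy trace; when supplied the
#'   energy after the step is appended via [energyValue()].
#' @return the updated [EvolutionState].
#' @export
evolveStep <- function(state, speed, cfg, image = NULL) {
  phi <- state@phi
  band <- narrowBand(phi, cfg@bandWidth)
  if (!any(band)) stop("empty narrow band: contour vanished")
  sp <- speed[band]
  if (any(!is.finite(sp))) {
    bad <- which(band & !is.finite(speed), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite speed at point (%d, %d)", bad[1], bad[2]))
  }
  maskPrev <- phi <= 0
  dN <- dirac(phi, cfg@epsHeaviside) * cfg@epsHeaviside
  kap <- curvatureField(phi)
  total <- pmin(pmax(dN * (speed + cfg@mu * kap), -1), 1)  # CFL bound
  dt <- cfg@dt
  if (is.na(dt)) dt <- 0.45
  phi[band] <- phi[band] + dt * total[band]
  regMask <- dilateMask(band, 3) & abs(phi) > 0.67 * cfg@epsHeaviside
  phi <- distanceRegularize(phi, cfg@regWeight, 1, mask = regMask)

  hist <- state@speedHistory
  hist[[length(hist) + 1L]] <- dilateMask((phi <= 0) != maskPrev, 2)
  if (length(hist) > cfg@stabilityWindow)
    hist <- hist[seq.int(length(hist) - cfg@stabilityWindow + 1L,
                         length(hist))]
  runMax <- max(state@runningMax, abs(sp))

  e <- if (!is.null(image)) energyValue(image, phi, cfg) else NA_real_
  new("EvolutionState", phi = phi, iteration = state@iteration + 1L,
      energyTrace = c(state@energyTrace, e), speedHistory = hist,
      runningMax = runMax)
}

#' @rdname SegmentationRun-class
#' @param x a [SegmentationRun]
#' @export
segMask <- function(x) x@mask

#' @rdname SegmentationRun-class
#' @export
energyTrace <- function(x) x@energyTrace

#' @rdname SegmentationRun-class
#' @export
iterations <- function(x) x@iterations

#' @rdname SegmentationRun-class
#' @export
stalledLog <- function(x) x@stalledLog

#' @rdname SegmentationRun-class
#' @export
phiMatrix <- function(x) x@phi

setMethod("show", "SegmentationRun", function(object) {
  cat(sprintf("SegmentationRun: %d iterations (%s), foreground %d px\n",
              object@iterations, object@status, sum(object@mask)))
  if (nrow(object@stalledLog))
    cat(sprintf("  stalled-point decisions: %d (%s)\n",
                nrow(object@stalledLog),
                paste(names(table(object@stalledLog$decision)),
                      table(object@stalledLog$decision),
                      sep = "=", collapse = ", ")))
})
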