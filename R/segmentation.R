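## The segmentation driver: narrow-band localized level-set evolution with
## optional CNN speed compensation.

## Shared stalled-point predicate: a contour point is stalled when no pixel
## within 2 px of it has changed sides for `stability_window` consecutive
## iterations (the history holds dilated mask-flip maps).  Under the
## quantized narrow-band dynamics, mask flips are the interface motion; the
## raw |d phi| churns even at a perfectly stationary boundary.
.stalledFrom <- function(hist, runMax, phi, cfg) {
  shape <- dim(phi)
  if (length(hist) < cfg@stabilityWindow)
    return(matrix(FALSE, shape[1], shape[2]))
  quiet <- !Reduce(`|`, hist)
  quiet & suppressWarnings(contourPoints(phi))
}

#' Segment an image with the localizing region-based level set
#'
#' Runs the full evolution from a circular initial contour.  With
#' `compensation_enabled = FALSE` in `cfg` this is the fixed-parameter
#' localizing level set (FLS): the contour moves under the localized UM or
#' MS data speed plus curvature regularization, on a narrow band, with
#' distance regularization instead of reinitialization.  With compensation
#' enabled (and a trained [PatchCNN] supplied), contour points whose speed
#' has stayed near zero for `stability_window` iterations are classified
#' from their local 10x10 patch; points judged to sit on lesion receive a
#' sustained outward speed compensation, ambiguous calls
#' (`|p1 - p2| <= ambiguity_margin`) are dropped, and confirmed boundary
#' points keep their status for the rest of the run.
#'
#' The run stops when the interface has been stationary (no pixel changed
#' sides anywhere in the band) for `stability_window` consecutive
#' iterations and every stalled point has been adjudicated, at `max_iters`,
#' or when the foreground vanishes.
#'
#' @param image numeric matrix; normalized internally to [0, 1] if needed.
#' @param center initial circle centre (row, col).
#' @param radius initial circle radius (px).
#' @param cfg a [RunConfig].
#' @param model a trained [PatchCNN]; required when compensation is enabled.
#' @param stop_on_convergence stop once the interface has been stationary
#'   for the stability window (default); `FALSE` always runs `max_iters`
#'   iterations.
#' @param diagnostics record the band-mean `||grad phi| - 1|` after every
#'   iteration (slot `diagnostics$sdf_error`).
#' @param classifier_cache optional environment memoizing classifier calls
#'   by location for repeated runs on the same image (classification is
#'   deterministic, so the cache never changes results).
#' @return a [SegmentationRun].
#' @export
runSegmentation <- function(image, center, radius, cfg = runConfig(),
                            model = NULL, stop_on_convergence = TRUE,
                            diagnostics = FALSE, classifier_cache = NULL) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1) image <- normalizeImage(image)
  if (cfg@compensationEnabled &&
      (is.null(model) || !isTRUE(model@trained)))
    stop("speed compensation requires a trained patch classifier")
  nr <- nrow(image); nc <- ncol(image)
  phi <- initPhiCircle(c(nr, nc), center, radius)

  decision <- matrix(0L, nr, nc)   # 0 none, 1 compensated, 2 boundary, 3 ambiguous
  compAmount <- matrix(0, nr, nc)
  hist <- list()                    # recent dilated mask-flip maps
  runMax <- 0
  runMaxLocal <- matrix(0, nr, nc)  # per-pixel historical |data speed|
  maskPrev <- phi <= 0
  energy <- numeric(0)
  sdfErr <- numeric(0)
  logRows <- list()
  status <- "max_iters"
  bb <- NULL
  margin <- ceiling(cfg@ballRadius) + 4L
  momentCache <- new.env(parent = emptyenv())

  for (it in seq_len(cfg@maxIters)) {
    band <- abs(phi) <= cfg@bandWidth
    if (!any(band) || !any(phi <= 0)) { status <- "contour_vanished"; break }
    newbb <- quantizeBBox(maskBBox(band, margin), 8L, nr, nc)
    bb <- if (is.null(bb)) newbb else         # grow-only crop: keeps the
      c(min(bb[1], newbb[1]), max(bb[2], newbb[2]),   # energy trace comparable
        min(bb[3], newbb[3]), max(bb[4], newbb[4]))   # across iterations
    rs <- bb[1]:bb[2]; cs <- bb[3]:bb[4]
    Ic <- image[rs, cs]; phic <- phi[rs, cs]
    bandc <- band[rs, cs]

    parts <- speedFieldCrop(Ic, phic, cfg, cache = momentCache)
    g <- gradCentral(phic)
    energy[it] <- sum(parts$d * parts$Flocal) +
      cfg@mu * sum(parts$d * sqrt(g$dr^2 + g$dc^2))

    rml <- runMaxLocal[rs, cs]
    spLoc <- abs(parts$speed)
    spLoc[!bandc] <- 0
    rml <- pmax(rml, localMax5(spLoc))   # smooth per-pixel speed scale
    runMaxLocal[rs, cs] <- rml

    if (cfg@compensationEnabled) {
      stalled <- .stalledFrom(hist, runMax, phi, cfg) & decision == 0L
      if (any(stalled)) {
        pts <- which(stalled, arr.ind = TRUE)
        nearBorder <- pts[, 1] < 6L | pts[, 2] < 6L |
          pts[, 1] > nr - 4L | pts[, 2] > nc - 4L
        for (k in which(nearBorder)) {
          decision[pts[k, 1], pts[k, 2]] <- 3L
          logRows[[length(logRows) + 1L]] <- data.frame(
            iteration = it, row = pts[k, 1], col = pts[k, 2],
            p1 = NA_real_, p2 = NA_real_, decision = "ambiguous_border")
        }
        pts <- pts[!nearBorder, , drop = FALSE]
        if (nrow(pts) > 0) {
          keys <- paste(pts[, 1], pts[, 2])
          P <- matrix(NA_real_, nrow(pts), 2)
          if (!is.null(classifier_cache)) {
            hit <- vapply(keys, function(k)
              !is.null(classifier_cache[[k]]), logical(1))
            for (k in which(hit)) P[k, ] <- classifier_cache[[keys[k]]]
          } else hit <- rep(FALSE, nrow(pts))
          if (any(!hit)) {
            ## one batched forward pass for the uncached stalled points
            todo <- which(!hit)
            batch <- array(0, c(32L, 32L, length(todo)))
            for (k in seq_along(todo))
              batch[, , k] <- extractPatch(image, pts[todo[k], ])@enhanced
            Pn <- predictCNN(model, batch)
            for (k in seq_along(todo)) {
              P[todo[k], ] <- Pn[k, ]
              if (!is.null(classifier_cache))
                classifier_cache[[keys[todo[k]]]] <- Pn[k, ]
            }
          }
          for (k in seq_len(nrow(pts))) {
            probs <- c(p1 = P[k, 1], p2 = P[k, 2])
            dec <- decidePoint(probs, cfg)
            decision[pts[k, 1], pts[k, 2]] <-
              switch(dec, compensated = 1L, confirmed_boundary = 2L,
                     ambiguous = 3L)
            if (dec == "compensated")
              compAmount[pts[k, 1], pts[k, 2]] <-
                compensationTerm(probs, cfg@lambda1, cfg@lambda2)
            logRows[[length(logRows) + 1L]] <- data.frame(
              iteration = it, row = pts[k, 1], col = pts[k, 2],
              p1 = unname(probs[1]), p2 = unname(probs[2]), decision = dec)
          }
        }
      }
      ## compensation lapses permanently for points that leave the band
      gone <- compAmount > 0 & !band
      if (any(gone)) compAmount[gone] <- 0
    }

    speedc <- applyCompensation(parts$speed, compAmount[rs, cs],
                                parts$m0, cfg)
    ## Saturating speed control against the *pixel-local* historical peak:
    ## the raw localized force spans three orders of magnitude between arcs
    ## far from any boundary (weak but reliable signal) and arcs in contact
    ## with the wall (huge restoring forces).  Dividing by the local scale
    ## lets weak arcs advance briskly while wall arcs get proportional
    ## control that settles to a sub-pixel equilibrium.
    speedc <- speedc / (abs(speedc) + 0.2 * rml + 1e-12)
    kap <- curvatureField(phic)
    ## Thin-zone update: the compact Dirac (normalized to peak 1) confines
    ## the data motion to the +-eps ribbon around the zero crossing; the
    ## distance regularizer owns everything *outside* that ribbon and so
    ## can never advect the interface itself.
    dN <- parts$d * cfg@epsHeaviside
    total <- pmin(pmax(dN * (speedc + cfg@mu * kap), -1), 1)  # CFL bound
    dt <- cfg@dt
    if (is.na(dt)) dt <- 0.45
    phic[bandc] <- phic[bandc] + dt * total[bandc]
    ## the regularizer overlaps the outer half of the Dirac support (so the
    ## front never jams at the support edge) but stays away from the zero
    ## crossing itself (so it cannot advect the interface)
    regMask <- dilateMask(bandc, 3) & abs(phic) > 0.67 * cfg@epsHeaviside
    phic <- distanceRegularize(phic, cfg@regWeight, 1, mask = regMask)
    ## Every few iterations the field is redistanced exactly from the
    ## current mask (boundary pixels at +-0.5).  The zero level set is
    ## preserved bit-for-bit; what this buys is a always-live update ribbon
    ## and a clean distance profile, which the explicit banded update alone
    ## cannot maintain once the strong region forces compress it.  The
    ## interval leaves room for sub-pixel progress to accumulate into
    ## pixel flips between rebuilds.
    if (it %% 4L == 0L) {
      if (any(phic <= 0)) phic <- sdfFromMask(phic <= 0)
    }
    phi[rs, cs] <- phic
    if (diagnostics) {
      gph <- gradCentral(phic)
      smag <- sqrt(gph$dr^2 + gph$dc^2)
      sdfErr[it] <- mean(abs(smag[bandc] - 1))
    }
    maskNow <- phi <= 0
    flips <- dilateMask(maskNow != maskPrev, 2)
    maskPrev <- maskNow
    hist[[length(hist) + 1L]] <- flips
    if (length(hist) > cfg@stabilityWindow) hist <- hist[-1L]

    ## Convergence lock -- the stable-point rule applied globally: stop
    ## once no pixel has changed sides for the whole stability window (the
    ## interface is stationary), and, when compensation is on, every
    ## stalled point has been adjudicated (boundary / lesion / ambiguous).
    ## Stalled points maintain their status till convergence.
    if (length(hist) >= cfg@stabilityWindow &&
        !any(Reduce(`|`, hist))) {
      pendingCNN <- cfg@compensationEnabled &&
        any(.stalledFrom(hist, runMax, phi, cfg) & decision == 0L)
      if (!pendingCNN && stop_on_convergence) {
        status <- "converged"
        break
      }
    }
  }

  log <- if (length(logRows)) do.call(rbind, logRows)
    else data.frame(iteration = integer(0), row = integer(0),
                    col = integer(0), p1 = numeric(0), p2 = numeric(0),
                    decision = character(0))
  new("SegmentationRun", mask = phi <= 0, phi = phi,
      energyTrace = energy, iterations = length(energy),
      stalledLog = log, config = cfg, status = status,
      diagnostics = if (diagnostics) list(sdf_error = sdfErr) else list())
}
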