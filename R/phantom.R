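## synthetic_phantom: sinus-like phantom images with ground truth, the
## test-bed substitute for (private) clinical CT.
##
## A phantom is a dark, irregular elliptical air cavity enclosed by a bright
## bone wall inside mid-grey tissue.  Lesions are bright-but-heterogeneous
## blobs attached to (or floating near) the wall, clipped to the cavity; a
## smooth multiplicative bias field and Gaussian noise emulate CT intensity
## inhomogeneity.  The segmentation ground truth is the FULL cavity
## including lesion-occluded area: a contour that stops on a lesion edge is
## wrong, which is exactly the failure mode the compensation mechanism
## exists to fix.

#' Construct a phantom specification
#'
#' @param size image size (rows, cols).
#' @param cavity_center cavity centre (row, col); `NA` = image centre.
#' @param axes cavity ellipse semi-axes (px).
#' @param orientation ellipse orientation in radians; `NA` = drawn from the
#'   seed.
#' @param irregularity relative amplitude of the smooth radial perturbation.
#' @param cavity_mean,bone_mean,tissue_mean region mean intensities.
#' @param wall_thickness bone wall thickness (px).
#' @param n_lesions number of lesion blobs.
#' @param lesion_radius_range,lesion_mean_range lesion geometry/intensity.
#' @param lesion_texture sd of the smooth intra-lesion texture.
#' @param wall_attached_prob probability a lesion is wall-attached.
#' @param noise_sigma additive Gaussian noise sd.
#' @param bias_amplitude relative amplitude of the bias field.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(size = c(128L, 128L), cavity_center = NA,
                        axes = c(12.6, 12.2), orientation = NA,
                        irregularity = 0.02,
                        cavity_mean = 0.12, bone_mean = 0.85,
                        tissue_mean = 0.85, wall_thickness = 12,
                        n_lesions = 0L, lesion_radius_range = c(3, 6),
                        lesion_mean_range = c(0.55, 0.75),
                        lesion_texture = 0.08, wall_attached_prob = 0.8,
                        noise_sigma = 0.02, bias_amplitude = 0.1,
                        seed = 1L) {
  new("PhantomSpec", size = as.integer(size),
      cavityCenter = as.numeric(cavity_center), axes = axes,
      orientation = as.numeric(orientation), irregularity = irregularity,
      cavityMean = cavity_mean, boneMean = bone_mean,
      tissueMean = tissue_mean, wallThickness = wall_thickness,
      nLesions = as.integer(n_lesions),
      lesionRadiusRange = lesion_radius_range,
      lesionMeanRange = lesion_mean_range, lesionTexture = lesion_texture,
      wallAttachedProb = wall_attached_prob, noiseSigma = noise_sigma,
      biasAmplitude = bias_amplitude, seed = as.integer(seed))
}

## Smooth random radial perturbation, normalized to max |.| = 1.
.radialPerturb <- function(theta, nHarm = 3L) {
  a <- runif(nHarm, -1, 1)
  ph <- runif(nHarm, 0, 2 * pi)
  p <- Reduce(`+`, lapply(seq_len(nHarm), function(k)
    a[k] * cos((k + 1) * theta + ph[k])))
  m <- max(abs(p))
  if (m < 1e-12) p else p / m
}

#' Generate one phantom
#'
#' @param spec a [PhantomSpec].
#' @return a [PhantomSample] with the image in [0, 1], the full-cavity
#'   ground-truth mask and the lesion mask.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nr <- spec@size[1]; nc <- spec@size[2]
  withSeed(spec@seed, {
    orient <- if (is.na(spec@orientation)) runif(1, 0, pi)
              else spec@orientation
    ctr <- if (any(is.na(spec@cavityCenter))) c(nr, nc) / 2
           else spec@cavityCenter
    a <- spec@axes[1]; b <- spec@axes[2]
    rr <- matrix(seq_len(nr), nr, nc) - ctr[1]
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[2]
    x <- rr * cos(orient) + cc * sin(orient)
    y <- -rr * sin(orient) + cc * cos(orient)
    rho <- sqrt((x / a)^2 + (y / b)^2)
    theta <- atan2(y / b, x / a)
    Rb <- 1 + spec@irregularity * .radialPerturb(theta)
    cavity <- rho <= Rb
    bone <- dilateMask(cavity, spec@wallThickness) & !cavity

    img <- matrix(spec@tissueMean, nr, nc)
    img[bone] <- spec@boneMean
    img[cavity] <- spec@cavityMean

    lesion <- matrix(FALSE, nr, nc)
    n <- spec@nLesions
    if (n > 0) {
      texture <- as.matrix(EBImage::gblur(matrix(rnorm(nr * nc), nr, nc),
                                          sigma = 2.5))
      texture <- texture / max(sd(texture), 1e-9)
      baseAng <- runif(1, 0, 2 * pi)
      for (j in seq_len(n)) {
        rad <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
        lmean <- runif(1, spec@lesionMeanRange[1], spec@lesionMeanRange[2])
        attached <- runif(1) < spec@wallAttachedProb
        u <- baseAng + 2 * pi * (j - 1) / n + runif(1, -pi / (2 * n), pi / (2 * n))
        ## boundary point of the cavity at parameter angle u, pulled inward
        px <- a * cos(u); py <- b * sin(u)
        ell <- sqrt(px^2 + py^2)
        s <- if (attached) max(0, 1 - 0.35 * rad / ell)
             else runif(1, 0.15, 0.5)
        lc <- ctr + c(px * s * cos(orient) - py * s * sin(orient),
                      px * s * sin(orient) + py * s * cos(orient))
        dl <- sqrt((matrix(seq_len(nr), nr, nc) - lc[1])^2 +
                   (matrix(seq_len(nc), nr, nc, byrow = TRUE) - lc[2])^2)
        la <- atan2(cc - (lc[2] - ctr[2]), rr - (lc[1] - ctr[1]))
        blob <- dl <= rad * (1 + 0.15 * .radialPerturb(la))
        inside <- blob & cavity
        img[inside] <- clampUnit(lmean + spec@lesionTexture * texture[inside])
        lesion <- lesion | inside
      }
    }

    if (spec@biasAmplitude > 0) {
      f <- runif(4, 0.5, 1.6); p <- runif(4, 0, 2 * pi)
      w <- runif(2, 0.3, 1)
      bias <- w[1] * cos(2 * pi * f[1] * (rr / nr) + p[1]) *
                cos(2 * pi * f[2] * (cc / nc) + p[2]) +
              w[2] * cos(2 * pi * f[3] * (rr / nr) + p[3]) *
                cos(2 * pi * f[4] * (cc / nc) + p[4])
      bias <- 1 + spec@biasAmplitude * bias / max(abs(bias))
      img <- img * bias
    }
    if (spec@noiseSigma > 0)
      img <- img + rnorm(nr * nc, sd = spec@noiseSigma)
    img <- clampUnit(img)

    specOut <- spec
    specOut@orientation <- orient
    specOut@cavityCenter <- ctr
    new("PhantomSample", image = img, cavityMask = cavity,
        lesionMask = lesion, spec = specOut)
  })
}

#' Accessors for phantom samples
#' @param x a [PhantomSample]
#' @export
phantomImage <- function(x) x@image

#' @rdname phantomImage
#' @export
cavityMask <- function(x) x@cavityMask

#' @rdname phantomImage
#' @export
lesionMask <- function(x) x@lesionMask

#' @rdname phantomImage
#' @export
airMask <- function(x) x@cavityMask & !x@lesionMask

#' Deepest interior point of the open (air) cavity
#'
#' The pixel of the air region (cavity minus lesions) farthest from any
#' non-air pixel — the natural deterministic seed for an initial contour —
#' together with the largest circle radius that fits there.
#'
#' @param sample a [PhantomSample].
#' @return list with `center` (row, col) and `maxRadius`.
#' @export
seedPoint <- function(sample) {
  air <- airMask(sample)
  dtm <- t(as.matrix(EBImage::distmap(EBImage::Image(t(air * 1)))))
  loc <- which(dtm == max(dtm), arr.ind = TRUE)[1, ]
  list(center = as.integer(loc), maxRadius = max(dtm) - 1)
}

#' Sample labelled classifier patches from a phantom
#'
#' Lesion-class patches are centred on lesion boundary pixels facing the
#' air cavity; boundary-class patches on cavity-wall pixels at least 3 px
#' away from any lesion.  Patches closer than 5 px to the image border are
#' rejected.  Balanced classes; deterministic given the seed.
#'
#' @param sample a [PhantomSample].
#' @param n_per_class patches to draw per class.
#' @param seed integer seed.
#' @return a [PatchSet] (with a warning if a class ran out of pixels).
#' @export
sampleLabelledPatches <- function(sample, n_per_class, seed = 1L) {
  img <- sample@image
  nr <- nrow(img); nc <- ncol(img)
  air <- airMask(sample)
  nbAir <- shiftUp(air) | shiftDown(air) | shiftLeft(air) | shiftRight(air)
  lesionEdge <- sample@lesionMask & nbAir
  out <- !sample@cavityMask
  nbOut <- shiftUp(out) | shiftDown(out) | shiftLeft(out) | shiftRight(out)
  cavB <- sample@cavityMask & nbOut
  wallEdge <- cavB & (!dilateMask(sample@lesionMask, 3) | sample@lesionMask)
  okBorder <- matrix(FALSE, nr, nc)
  okBorder[6:(nr - 4), 6:(nc - 4)] <- TRUE
  pools <- list(lesion = which(lesionEdge & okBorder),
                boundary = which(wallEdge & okBorder))
  withSeed(seed, {
    patches <- list()
    for (cls in c("boundary", "lesion")) {
      pool <- pools[[cls]]
      if (length(pool) == 0L) {
        warning("no eligible ", cls, " pixels in this phantom")
        next
      }
      take <- if (length(pool) >= n_per_class)
        sample(pool, n_per_class)
      else {
        warning(sprintf("only %d %s pixels available (wanted %d)",
                        length(pool), cls, n_per_class))
        pool[sample.int(length(pool))]
      }
      for (idx in take) {
        loc <- c((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
        patches[[length(patches) + 1L]] <- extractPatch(img, loc, cls)
      }
    }
    patchSetFrom(patches)
  })
}

#' Pool labelled patches across a cohort
#'
#' Collects the eligible lesion-edge and cavity-wall pixels of every
#' phantom in the cohort into two pools and samples `n_per_class` patch
#' centres from each (without replacement while the pool lasts), then runs
#' the preprocessing pipeline.  Single phantoms expose only a few dozen
#' eligible pixels per class, so classifier-scale sets are harvested from
#' many phantoms.
#'
#' @param cohort list of [PhantomSample].
#' @param n_per_class patches per class.
#' @param seed integer seed.
#' @return a [PatchSet] with balanced classes.
#' @export
harvestPatches <- function(cohort, n_per_class, seed = 1L) {
  pools <- list(boundary = list(), lesion = list())
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    nr <- nrow(s@image); nc <- ncol(s@image)
    air <- airMask(s)
    nbAir <- shiftUp(air) | shiftDown(air) | shiftLeft(air) | shiftRight(air)
    lesionEdge <- s@lesionMask & nbAir
    out <- !s@cavityMask
    nbOut <- shiftUp(out) | shiftDown(out) | shiftLeft(out) | shiftRight(out)
    cavB <- s@cavityMask & nbOut
    ## the wall class covers both the open (air-facing) wall and the wall
    ## segments behind lesions -- the latter are where an escaping contour
    ## must recognise bone and stop
    wallEdge <- cavB & (!dilateMask(s@lesionMask, 3) | s@lesionMask)
    ok <- matrix(FALSE, nr, nc)
    ok[6:(nr - 4), 6:(nc - 4)] <- TRUE
    pools$lesion[[i]] <- which(lesionEdge & ok)
    pools$boundary[[i]] <- which(wallEdge & ok)
  }
  withSeed(seed, {
    patches <- list()
    for (cls in c("boundary", "lesion")) {
      tab <- do.call(rbind, lapply(seq_along(cohort), function(i)
        if (length(pools[[cls]][[i]]))
          cbind(i, pools[[cls]][[i]]) else NULL))
      if (is.null(tab) || nrow(tab) == 0L)
        stop("no eligible ", cls, " pixels in the cohort")
      take <- if (nrow(tab) >= n_per_class)
        tab[sample.int(nrow(tab), n_per_class), , drop = FALSE]
      else
        tab[sample.int(nrow(tab), n_per_class, replace = TRUE), ,
            drop = FALSE]
      for (k in seq_len(nrow(take))) {
        s <- cohort[[take[k, 1]]]
        nr <- nrow(s@image)
        idx <- take[k, 2]
        loc <- c((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
        patches[[length(patches) + 1L]] <-
          extractPatch(s@image, loc, cls)
      }
    }
    patchSetFrom(patches)
  })
}

#' Generate a cohort of phantoms
#'
#' Draws per-phantom specs from one of three regimes and one seed per sample
#' from the master seed:
#' * `"mixed"` — 0--3 lesions of mixed size, the general test bed;
#' * `"clean"` — lesion-free cavities (healthy sinus);
#' * `"stalling"` — two large, high-contrast wall-attached lesions blocking
#'   a substantial fraction of the wall, the regime in which the
#'   fixed-parameter level set demonstrably stalls.
#'
#' @param n number of phantoms (>= 1).
#' @param preset `"mixed"`, `"clean"` or `"stalling"`.
#' @param seed master seed.
#' @param overrides named list of [phantomSpec()] arguments overriding the
#'   preset for every sample.
#' @return list of [PhantomSample]; the specs (with resolved orientation and
#'   per-sample seeds) form the cohort manifest, see [cohortManifest()].
#' @export
generateCohort <- function(n, preset = c("mixed", "clean", "stalling"),
                           seed = 1L, overrides = list()) {
  if (n < 1) stop("cohort size must be >= 1")
  preset <- match.arg(preset)
  withSeed(seed, {
    seeds <- sample.int(2^30, n)
    lapply(seq_len(n), function(i) {
      args <- withSeed(seeds[i], switch(preset,
        clean = list(
          axes = c(runif(1, 12.3, 12.9), runif(1, 12.1, 12.5)),
          n_lesions = 0L),
        mixed = list(
          axes = c(runif(1, 12.3, 12.9), runif(1, 12.1, 12.5)),
          n_lesions = sample(0:3, 1),
          lesion_radius_range = c(3, 6)),
        stalling = list(
          axes = c(runif(1, 12.3, 12.9), runif(1, 12.1, 12.5)),
          n_lesions = 2L,
          lesion_radius_range = c(7, 9),
          lesion_mean_range = c(0.6, 0.75),
          wall_attached_prob = 1)))
      args$seed <- seeds[i] + 1L  # distinct stream from the arg draws
      args[names(overrides)] <- overrides
      generatePhantom(do.call(phantomSpec, args))
    })
  })
}

## Spec as a plain list (manifest row).
.specAsList <- function(spec) {
  list(size = spec@size, cavity_center = spec@cavityCenter,
       axes = spec@axes, orientation = spec@orientation,
       irregularity = spec@irregularity, cavity_mean = spec@cavityMean,
       bone_mean = spec@boneMean, tissue_mean = spec@tissueMean,
       wall_thickness = spec@wallThickness, n_lesions = spec@nLesions,
       lesion_radius_range = spec@lesionRadiusRange,
       lesion_mean_range = spec@lesionMeanRange,
       lesion_texture = spec@lesionTexture,
       wall_attached_prob = spec@wallAttachedProb,
       noise_sigma = spec@noiseSigma, bias_amplitude = spec@biasAmplitude,
       seed = spec@seed)
}

#' Cohort manifest
#'
#' @param samples list of [PhantomSample].
#' @return list of per-sample spec lists, suitable for JSON serialization.
#' @export
cohortManifest <- function(samples) {
  lapply(samples, function(s) .specAsList(s@spec))
}

#' Write a cohort to disk
#'
#' Writes `image_###.png`, `cavity_###.png`, `lesion_###.png` per sample
#' plus `manifest.json`.
#'
#' @param samples list of [PhantomSample].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    EBImage::writeImage(EBImage::Image(t(s@image)),
                        file.path(dir, sprintf("image_%03d.png", i)),
                        type = "png")
    writeMask(s@cavityMask, file.path(dir, sprintf("cavity_%03d.png", i)))
    writeMask(s@lesionMask, file.path(dir, sprintf("lesion_%03d.png", i)))
  }
  jsonlite::write_json(cohortManifest(samples),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf(
    "PhantomSample %dx%d: cavity %d px, %d lesion px (%d blobs), seed %d\n",
    nrow(object@image), ncol(object@image), sum(object@cavityMask),
    sum(object@lesionMask), object@spec@nLesions, object@spec@seed))
})
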