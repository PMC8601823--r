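## S4 classes for the central data objects.  Images, masks and level-set
## fields themselves are plain base matrices indexed [row, col] (1-based,
## pixel-centred); the classes below bundle them with metadata and enforce
## the invariants that matter.

#' Run configuration for level-set segmentation
#'
#' Holds every tunable of the localizing region-based evolution and of the
#' speed-compensation logic.  Construct with [runConfig()] (which fills
#' defaults) rather than `new()`.
#'
#' @slot energyModel `"UM"` (uniform modeling / Chan--Vese) or `"MS"`
#'   (mean separation).
#' @slot mu curvature regularization weight (default 0.05).
#' @slot lambda1,lambda2 weights of the interior / exterior residual terms
#'   of the local energy (defaults 1.0, 1.0).
#' @slot ballRadius radius (px) of the local disk `B(x, y)` over which
#'   region statistics are gathered around each contour point.
#' @slot arcRadius radius (px) of the smaller disk over which the
#'   Dirac-weighted residual is integrated into the point speed.  Keeping
#'   this below the statistics radius stops distant contour arcs from
#'   polluting the force at a point (with one shared radius, arcs up to a
#'   full ball away couple into the integral and can destabilize settled
#'   boundaries).
#' @slot bandWidth half-width (px) of the narrow band `|phi| <= bandWidth`.
#' @slot epsHeaviside smoothing width of the regularized Heaviside/Dirac pair.
#' @slot dt explicit time step; `NA` means CFL-style normalization
#'   (0.45 / max |update|) every iteration.
#' @slot maxIters iteration cap.
#' @slot stabilityTol fraction of the running maximum band speed below which
#'   a contour point counts as "near zero speed".
#' @slot stabilityWindow consecutive iterations of near-zero speed required
#'   to declare a point stalled.
#' @slot compensationEnabled logical; `FALSE` reproduces the fixed-parameter
#'   localizing level set (FLS) exactly.
#' @slot ambiguityMargin stalled points with `|p1 - p2|` at or below this
#'   margin are dropped as ambiguous (default 0.2).
#' @slot compensationCoupling `"ball"` multiplies the compensation term by
#'   the local Dirac mass of the ball (the inside-the-integral reading);
#'   `"direct"` adds the bare term to the point speed.
#' @slot regWeight weight of the distance-regularization (no
#'   reinitialization) step.
#' @slot stopTol,stopWindow legacy energy-plateau stopping parameters
#'   (the driver stops on the stable-point convergence lock).
#' @slot seed integer seed governing any randomness tied to a run.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    energyModel = "character",
    mu = "numeric", lambda1 = "numeric", lambda2 = "numeric",
    ballRadius = "numeric", arcRadius = "numeric", bandWidth = "numeric",
    epsHeaviside = "numeric", dt = "numeric",
    maxIters = "integer",
    stabilityTol = "numeric", stabilityWindow = "integer",
    compensationEnabled = "logical", ambiguityMargin = "numeric",
    compensationCoupling = "character",
    regWeight = "numeric", stopTol = "numeric", stopWindow = "integer",
    seed = "integer"))

setValidity("RunConfig", function(object) {
  bad <- character(0)
  if (!object@energyModel %in% c("UM", "MS"))
    bad <- c(bad, "energy_model must be 'UM' or 'MS'")
  if (object@mu < 0) bad <- c(bad, "mu must be >= 0")
  if (object@lambda1 <= 0) bad <- c(bad, "lambda1 must be > 0")
  if (object@lambda2 <= 0) bad <- c(bad, "lambda2 must be > 0")
  if (object@ballRadius < 1) bad <- c(bad, "ball_radius must be >= 1")
  if (object@arcRadius < 0.5) bad <- c(bad, "arc_radius must be >= 0.5")
  if (object@bandWidth < 1) bad <- c(bad, "band_width must be >= 1")
  if (object@epsHeaviside <= 0) bad <- c(bad, "epsilon_heaviside must be > 0")
  if (object@ambiguityMargin <= 0 || object@ambiguityMargin >= 1)
    bad <- c(bad, "ambiguity_margin must be in (0, 1)")
  if (!object@compensationCoupling %in% c("ball", "direct"))
    bad <- c(bad, "compensation_coupling must be 'ball' or 'direct'")
  if (object@maxIters < 1) bad <- c(bad, "max_iters must be >= 1")
  if (object@stabilityWindow < 1) bad <- c(bad, "stability_window must be >= 1")
  if (length(bad)) paste(bad, collapse = "; ") else TRUE
})

#' A single labelled image patch
#'
#' @slot raw the 10x10 window sampled around a contour point.
#' @slot enhanced the 32x32 CLAHE-enhanced, bilinearly upsampled patch that
#'   is actually fed to the classifier; values in [0, 1].
#' @slot center (row, col) of the patch centre in the source image.
#' @slot label `"boundary"`, `"lesion"`, or `NA` when unlabelled.
#' @exportClass Patch
setClass("Patch",
  representation(raw = "matrix", enhanced = "matrix",
                 center = "integer", label = "character"))

setValidity("Patch", function(object) {
  if (!all(dim(object@raw) == c(10L, 10L))) return("raw must be 10x10")
  if (!all(dim(object@enhanced) == c(32L, 32L))) return("enhanced must be 32x32")
  rng <- range(object@enhanced)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("enhanced must lie in [0,1]")
  if (length(object@center) != 2L) return("center must be (row, col)")
  TRUE
})

#' A set of labelled patches for classifier training
#'
#' @slot enhanced 32 x 32 x n array of preprocessed patches in [0, 1].
#' @slot raw 10 x 10 x n array of the raw windows (may have 0 slices for
#'   augmented patches whose raw source is synthetic).
#' @slot labels character vector of length n, values in
#'   `c("boundary", "lesion")`.
#' @slot centers n x 2 integer matrix of source-image centres (NA rows for
#'   augmented patches).
#' @exportClass PatchSet
setClass("PatchSet",
  representation(enhanced = "array", raw = "array",
                 labels = "character", centers = "matrix"))

setValidity("PatchSet", function(object) {
  d <- dim(object@enhanced)
  if (length(d) != 3L || d[1] != 32L || d[2] != 32L)
    return("enhanced must be a 32 x 32 x n array")
  n <- d[3]
  if (length(object@labels) != n) return("labels length must match patch count")
  if (!all(object@labels %in% c("boundary", "lesion")))
    return("labels must be 'boundary' or 'lesion'")
  rng <- range(object@enhanced)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("enhanced values must lie in [0, 1]")
  if (nrow(object@centers) != n) return("centers must have one row per patch")
  TRUE
})

#' Parameters of the synthetic sinus phantom generator
#'
#' Describes one phantom: a dark, irregular elliptical air cavity enclosed by
#' a bright bone wall, surrounded by mid-grey soft tissue, with zero or more
#' bright heterogeneous lesion blobs attached to (or floating near) the wall,
#' plus Gaussian noise and a smooth multiplicative bias field.
#'
#' @slot size image size (rows, cols).
#' @slot cavityCenter cavity centre (row, col); `NA` means image centre.
#' @slot axes ellipse semi-axes (px) of the cavity.
#' @slot orientation ellipse orientation (radians).
#' @slot irregularity relative amplitude of the smooth radial perturbation of
#'   the cavity boundary.
#' @slot cavityMean,boneMean,tissueMean mean intensities of cavity air, bone
#'   wall and surrounding tissue (on [0, 1]).
#' @slot wallThickness bone wall thickness (px).
#' @slot nLesions number of lesion blobs.
#' @slot lesionRadiusRange min/max lesion blob radius (px).
#' @slot lesionMeanRange min/max lesion mean intensity.
#' @slot lesionTexture sd of the smooth intra-lesion texture field.
#' @slot wallAttachedProb probability that a lesion is attached to the wall.
#' @slot noiseSigma sd of additive Gaussian noise.
#' @slot biasAmplitude relative amplitude of the low-frequency multiplicative
#'   bias field.
#' @slot seed integer seed; the phantom is a deterministic function of the
#'   spec including the seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    size = "integer", cavityCenter = "numeric", axes = "numeric",
    orientation = "numeric", irregularity = "numeric",
    cavityMean = "numeric", boneMean = "numeric", tissueMean = "numeric",
    wallThickness = "numeric", nLesions = "integer",
    lesionRadiusRange = "numeric", lesionMeanRange = "numeric",
    lesionTexture = "numeric", wallAttachedProb = "numeric",
    noiseSigma = "numeric", biasAmplitude = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  bad <- character(0)
  if (any(object@size < 32L)) bad <- c(bad, "image size must be >= 32")
  if (any(object@axes <= 2)) bad <- c(bad, "cavity semi-axes must be > 2")
  ctr <- object@cavityCenter
  if (!any(is.na(ctr))) {
    margin <- max(object@axes) * (1 + object@irregularity) +
      object@wallThickness
    if (ctr[1] - margin < 8 || ctr[2] - margin < 8 ||
        ctr[1] + margin > object@size[1] - 8 ||
        ctr[2] + margin > object@size[2] - 8)
      bad <- c(bad, "cavity (plus wall) must lie >= 8 px inside the image")
  }
  if (object@cavityMean >= min(object@lesionMeanRange))
    bad <- c(bad, "cavity_mean must be below the lesion intensity range")
  if (max(object@lesionMeanRange) > object@boneMean + 0.15)
    bad <- c(bad, "lesion intensities must not exceed bone_mean by > 0.15")
  if (object@nLesions > 0 &&
      max(object@lesionRadiusRange) >= min(object@axes))
    bad <- c(bad, "lesion radius must be smaller than the cavity semi-axes")
  if (length(bad)) paste(bad, collapse = "; ") else TRUE
})

#' A generated phantom with ground truth
#'
#' The segmentation ground truth is `cavityMask`: the full sinus cavity
#' region *including* the area occluded by lesions, because the point of the
#' method is that the contour must pass through lesion edges and reach the
#' wall.  `lesionMask` is kept separately for patch labelling; the air (dark)
#' region is `cavityMask & !lesionMask`.
#'
#' @slot image the intensity image in [0, 1].
#' @slot cavityMask logical matrix, full cavity ground truth.
#' @slot lesionMask logical matrix, lesion blobs clipped to the cavity.
#' @slot spec the [PhantomSpec] the sample was generated from.
#' @exportClass PhantomSample
setClass("PhantomSample",
  representation(image = "matrix", cavityMask = "matrix",
                 lesionMask = "matrix", spec = "PhantomSpec"))

setValidity("PhantomSample", function(object) {
  if (!all(dim(object@image) == dim(object@cavityMask)) ||
      !all(dim(object@image) == dim(object@lesionMask)))
    return("image and masks must share one shape")
  if (!any(object@cavityMask)) return("cavity mask must be non-empty")
  if (any(object@lesionMask & !object@cavityMask))
    return("lesion mask must lie inside the cavity")
  TRUE
})

#' Level-set evolution state
#'
#' Bundles the signed-distance field with the bookkeeping one evolution step
#' needs: the energy trace and the recent per-pixel speed magnitudes used to
#' detect stalled contour points.
#'
#' @slot phi signed distance field; `phi < 0` inside the evolving region.
#' @slot iteration iterations taken so far.
#' @slot energyTrace energy value after each iteration.
#' @slot speedHistory list (ring buffer) of the last `stabilityWindow`
#'   interface-activity maps: logical matrices marking pixels within 2 px
#'   of a side change of the zero level set in that iteration.
#' @slot runningMax historical maximum of the band speed magnitude.
#' @exportClass EvolutionState
setClass("EvolutionState",
  representation(phi = "matrix", iteration = "integer",
                 energyTrace = "numeric", speedHistory = "list",
                 runningMax = "numeric"))

setValidity("EvolutionState", function(object) {
  if (any(!is.finite(object@phi))) return("phi must be finite everywhere")
  if (length(object@energyTrace) != object@iteration)
    return("energy trace length must equal the iteration count")
  TRUE
})

#' Result of one segmentation run
#'
#' @slot mask final foreground mask (`phi <= 0`).
#' @slot phi final signed distance field.
#' @slot energyTrace energy after each iteration.
#' @slot iterations number of iterations performed.
#' @slot stalledLog data.frame logging every stalled-point decision:
#'   iteration, row, col, p1, p2, decision.
#' @slot config the [RunConfig] used.
#' @slot status one of `"converged"`, `"max_iters"`, `"contour_vanished"`.
#' @slot diagnostics optional per-iteration diagnostics (see
#'   [runSegmentation()]).
#' @exportClass SegmentationRun
setClass("SegmentationRun",
  representation(mask = "matrix", phi = "matrix", energyTrace = "numeric",
                 iterations = "integer", stalledLog = "data.frame",
                 config = "RunConfig", status = "character",
                 diagnostics = "list"))

#' Architecture of the two-class patch CNN
#'
#' Two convolutional blocks (5x5 convolution, batch normalization, leaky
#' ReLU, 2x2 max pooling) followed by three fully connected layers
#' (`fc1`, `fc2`, 2) and a softmax.  The flattened output of block 2 must
#' equal the first FC layer's input size.
#'
#' @slot inputSize patch side length (32).
#' @slot d1,d2 convolution depths of blocks 1 and 2.
#' @slot s2 stride of the second convolution.
#' @slot fc1,fc2 unit counts of the first two fully connected layers.
#' @slot alpha leaky-ReLU negative slope.
#' @slot flatten flattened size feeding fc1; must match the computed value.
#' @exportClass CNNSpec
setClass("CNNSpec",
  representation(inputSize = "integer", d1 = "integer", d2 = "integer",
                 s2 = "integer", fc1 = "integer", fc2 = "integer",
                 alpha = "numeric", flatten = "integer"))

setValidity("CNNSpec", function(object) {
  want <- cnnFlattenSize(object@inputSize, object@s2, object@d2)
  if (object@flatten != want)
    return(sprintf(
      "flatten size %d does not match the architecture (computed %d)",
      object@flatten, want))
  if (object@inputSize %% 4L != 0L)
    return("input size must be divisible by 4 (two 2x2 poolings)")
  TRUE
})

#' The patch classifier model
#'
#' Weights, batch-normalization running statistics and moving-average
#' (shadow) weights of the two-class CNN.  Inference ([predictCNN()]) uses
#' the shadow weights and the frozen BN statistics; training updates the raw
#' weights.
#'
#' @slot spec the [CNNSpec].
#' @slot weights named list of parameter tensors.
#' @slot shadow moving-average copies of the weights.
#' @slot bn running means/variances for the two BN layers, plus their shadow
#'   copies.
#' @slot step training steps taken.
#' @slot trained logical; predictions require a trained (or loaded) model.
#' @slot classes class label order; fixed as `c("boundary", "lesion")` so
#'   that `p1` is always the sinus-boundary probability.
#' @exportClass PatchCNN
setClass("PatchCNN",
  representation(spec = "CNNSpec", weights = "list", shadow = "list",
                 bn = "list", step = "integer", trained = "logical",
                 classes = "character"))

setValidity("PatchCNN", function(object) {
  if (!identical(object@classes, c("boundary", "lesion")))
    return("class order must be c('boundary', 'lesion')")
  TRUE
})
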