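## imaging_io: images, masks and run configurations on disk.

#' Read a grayscale image
#'
#' Reads a PNG or TIFF image into a base matrix indexed `[row, col]` with
#' values on the scale stored in the file (0--1 for 8/16-bit images as
#' decoded by EBImage).  Multi-channel images are collapsed to grayscale by
#' averaging the channels.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix (rows x cols) of pixel intensities.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeMask(matrix(TRUE, 32, 32), f)
#' img <- readImageGray(f)
#' dim(img)
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)  # channel average
  m <- t(a)  # EBImage stores x (columns) first; we index [row, col]
  if (nrow(m) < 1L || ncol(m) < 1L) stop("zero-area image: ", path)
  if (any(!is.finite(m))) stop("non-finite pixels in image: ", path)
  m
}

#' Write / read a binary mask as a lossless PNG
#'
#' Masks are written 0/255 grayscale; the round-trip is bit-exact.
#'
#' @param mask logical matrix.
#' @param path output (input) PNG path.
#' @return `writeMask` returns `path` invisibly; `readMask` returns a
#'   logical matrix.
#' @export
writeMask <- function(mask, path) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  storage.mode(mask) <- "logical"
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write mask to: ", path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  readImageGray(path) > 0.5
}

#' Construct a run configuration
#'
#' Returns a validated [RunConfig] with the defaults used throughout:
#' `mu = 0.05`, `lambda1 = lambda2 = 1` (the energy weights), an ambiguity
#' margin of 0.2 for dropping confused classifier calls, a narrow band of
#' half-width 8 px, and a local-ball radius of 11 px.
#'
#' @param energy_model `"UM"` or `"MS"`.
#' @param mu curvature regularization weight.
#' @param lambda1,lambda2 local energy weights.
#' @param ball_radius local statistics region radius (px).
#' @param arc_radius local force-integration radius (px).
#' @param band_width narrow-band half-width (px).
#' @param epsilon_heaviside Heaviside/Dirac smoothing width (px).
#' @param dt explicit time step, or `NA` for per-iteration CFL normalization.
#' @param max_iters iteration cap.
#' @param stability_tol,stability_window stalled-point detection parameters.
#' @param compensation_enabled enable CNN speed compensation.
#' @param ambiguity_margin drop rule threshold on `|p1 - p2|`.
#' @param compensation_coupling `"ball"` or `"direct"`.
#' @param reg_weight distance-regularization weight.
#' @param stop_tol,stop_window legacy energy-plateau parameters, retained
#'   in the configuration surface; the driver stops on the stable-point
#'   convergence lock (see [runSegmentation()]).
#' @param seed integer seed.
#' @return a [RunConfig] object.
#' @export
runConfig <- function(energy_model = "UM", mu = 0.05,
                      lambda1 = 1.0, lambda2 = 1.0,
                      ball_radius = 11, arc_radius = 4, band_width = 8,
                      epsilon_heaviside = 1.5, dt = NA_real_,
                      max_iters = 300L, stability_tol = 0.05,
                      stability_window = 5L, compensation_enabled = FALSE,
                      ambiguity_margin = 0.2,
                      compensation_coupling = "ball",
                      reg_weight = 0.2, stop_tol = 1e-4, stop_window = 10L,
                      seed = 1L) {
  new("RunConfig", energyModel = as.character(energy_model),
      mu = mu, lambda1 = lambda1, lambda2 = lambda2,
      ballRadius = ball_radius, arcRadius = arc_radius,
      bandWidth = band_width,
      epsHeaviside = epsilon_heaviside, dt = as.numeric(dt),
      maxIters = as.integer(max_iters), stabilityTol = stability_tol,
      stabilityWindow = as.integer(stability_window),
      compensationEnabled = isTRUE(compensation_enabled),
      ambiguityMargin = ambiguity_margin,
      compensationCoupling = compensation_coupling,
      regWeight = reg_weight, stopTol = stop_tol,
      stopWindow = as.integer(stop_window), seed = as.integer(seed))
}

.configKeys <- c("energy_model", "mu", "lambda1", "lambda2", "ball_radius",
                 "arc_radius", "band_width", "epsilon_heaviside", "dt", "max_iters",
                 "stability_tol", "stability_window", "compensation_enabled",
                 "ambiguity_margin", "compensation_coupling", "reg_weight",
                 "stop_tol", "stop_window", "seed")

#' Load / save a run configuration as a flat YAML document
#'
#' The config dialect is one flat YAML mapping whose keys are the arguments
#' of [runConfig()].  Absent keys take the defaults; unknown keys are an
#' error so typos fail loudly.  `loadRunConfig(saveRunConfig(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param path a YAML file.
#' @param cfg a [RunConfig].
#' @return `loadRunConfig` returns a [RunConfig]; `saveRunConfig` returns
#'   `path` invisibly.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), .configKeys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

#' @rdname loadRunConfig
#' @export
saveRunConfig <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  vals <- list(
    energy_model = cfg@energyModel, mu = cfg@mu,
    lambda1 = cfg@lambda1, lambda2 = cfg@lambda2,
    ball_radius = cfg@ballRadius, arc_radius = cfg@arcRadius,
    band_width = cfg@bandWidth,
    epsilon_heaviside = cfg@epsHeaviside, dt = cfg@dt,
    max_iters = cfg@maxIters, stability_tol = cfg@stabilityTol,
    stability_window = cfg@stabilityWindow,
    compensation_enabled = cfg@compensationEnabled,
    ambiguity_margin = cfg@ambiguityMargin,
    compensation_coupling = cfg@compensationCoupling,
    reg_weight = cfg@regWeight, stop_tol = cfg@stopTol,
    stop_window = cfg@stopWindow, seed = cfg@seed)
  yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:", object@energyModel, "energy\n")
  cat(sprintf("  mu=%g lambda1=%g lambda2=%g ball=%g band=%g eps=%g\n",
              object@mu, object@lambda1, object@lambda2, object@ballRadius,
              object@bandWidth, object@epsHeaviside))
  cat(sprintf("  compensation=%s (margin %.2f, %s coupling), max_iters=%d\n",
              object@compensationEnabled, object@ambiguityMargin,
              object@compensationCoupling, object@maxIters))
})
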