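## preprocess: normalization, CLAHE and patch extraction, exactly as the
## classifier sees its inputs.

#' Min--max normalize an image to [0, 1]
#'
#' @param image numeric matrix.
#' @return matrix with minimum 0 and maximum 1; a constant image maps to all
#'   zeros with a warning.
#' @export
normalizeImage <- function(image) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  rng <- range(image)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant image: normalization returns all zeros")
    return(array(0, dim(image)))
  }
  (image - rng[1]) / diff(rng)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tiled histogram equalization with clipped histograms and bilinear blending
#' between tiles, applied to an image already normalized to [0, 1].  The clip
#' limit is expressed as the fraction of a tile's pixel count at which each
#' histogram bin is clipped (so 0.02 clips bins above 2% of the tile).
#'
#' @param image numeric matrix in [0, 1].
#' @param clip_limit histogram clip limit as a fraction of tile size.
#' @param tile_grid tiles as (rows, cols).
#' @param bins histogram bins.
#' @return matrix in [0, 1]; a constant image is returned unchanged.
#' @export
claheEnhance <- function(image, clip_limit = 0.02, tile_grid = c(4, 4),
                         bins = 256) {
  rng <- range(image)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("claheEnhance expects an image normalized to [0, 1]")
  if (tile_grid[1] > nrow(image) || tile_grid[2] > ncol(image))
    stop("tile grid exceeds image dimensions")
  if (diff(rng) < 1e-12) return(image)  # flat histogram: equalization no-op
  out <- EBImage::clahe(t(image), nx = tile_grid[2], ny = tile_grid[1],
                        bins = bins, limit = max(clip_limit * bins, 1))
  clampUnit(t(as.matrix(out)))
}

#' Bilinear upsampling of a patch
#'
#' @param raw numeric matrix (typically the 10x10 raw patch).
#' @param out output side length (default 32).
#' @return `out` x `out` matrix; constant inputs stay constant and output
#'   extrema are bounded by the input extrema.
#' @export
bilinearUpsample <- function(raw, out = 32L) {
  if (any(!is.finite(raw))) stop("raw patch must be finite")
  t(as.matrix(EBImage::resize(t(raw), w = out, h = out,
                              filter = "bilinear")))
}

#' Extract a classifier patch around a contour point
#'
#' The raw window is the 10x10 block spanning rows `center[1] - 5` to
#' `center[1] + 4` (and likewise columns): with an even window the centre
#' pixel sits at position 6, one pixel right/below the geometric middle.
#' The enhanced patch is the raw window bilinearly upsampled to 32x32 and
#' CLAHE-equalized, matching what the classifier was trained on.
#'
#' @param image numeric matrix, already normalized to [0, 1].
#' @param center integer (row, col); must be at least 5 px from every border,
#'   i.e. `center >= 6` and `center <= dim - 4`.
#' @param label optional class label.
#' @return a [Patch]; an error of class `"alrls_border"` signals a centre too
#'   close to the border (callers skip such points).
#' @export
extractPatch <- function(image, center, label = NA_character_) {
  r <- as.integer(center[1]); c0 <- as.integer(center[2])
  if (r - 5L < 1L || c0 - 5L < 1L ||
      r + 4L > nrow(image) || c0 + 4L > ncol(image))
    stop(structure(class = c("alrls_border", "error", "condition"),
                   list(message = sprintf(
                     "patch centre (%d, %d) is closer than 5 px to the border",
                     r, c0), call = sys.call(-1))))
  raw <- image[(r - 5L):(r + 4L), (c0 - 5L):(c0 + 4L)]
  enhanced <- claheEnhance(clampUnit(bilinearUpsample(raw, 32L)))
  new("Patch", raw = raw, enhanced = enhanced,
      center = c(r, c0), label = label)
}

## Assemble a PatchSet from a list of Patch objects.
patchSetFrom <- function(patches) {
  n <- length(patches)
  enh <- array(0, c(32L, 32L, n))
  raw <- array(0, c(10L, 10L, n))
  centers <- matrix(NA_integer_, n, 2L)
  labels <- character(n)
  for (i in seq_len(n)) {
    p <- patches[[i]]
    enh[, , i] <- p@enhanced
    raw[, , i] <- p@raw
    centers[i, ] <- p@center
    labels[i] <- p@label
  }
  new("PatchSet", enhanced = enh, raw = raw, labels = labels,
      centers = centers)
}

#' Number of patches, and subsetting
#' @param x a [PatchSet]
#' @export
setMethod("length", "PatchSet", function(x) dim(x@enhanced)[3])

#' @rdname length-PatchSet-method
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  new("PatchSet", enhanced = x@enhanced[, , i, drop = FALSE],
      raw = if (dim(x@raw)[3] == dim(x@enhanced)[3])
              x@raw[, , i, drop = FALSE] else x@raw,
      labels = x@labels[i], centers = x@centers[i, , drop = FALSE])
})

#' Patch labels
#' @param x a [PatchSet]
#' @export
patchLabels <- function(x) x@labels

#' Enhanced patch array (32 x 32 x n)
#' @param x a [PatchSet]
#' @export
patchArray <- function(x) x@enhanced

#' Concatenate patch sets
#' @param x,... [PatchSet] objects
#' @export
setMethod("c", "PatchSet", function(x, ...) {
  sets <- c(list(x), list(...))
  enh <- do.call(abind3, lapply(sets, function(s) s@enhanced))
  raw <- do.call(abind3, lapply(sets, function(s) s@raw))
  new("PatchSet", enhanced = enh, raw = raw,
      labels = unlist(lapply(sets, function(s) s@labels)),
      centers = do.call(rbind, lapply(sets, function(s) s@centers)))
})

## Bind 3-d arrays along the third margin.
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[3], integer(1)))
  out <- array(0, c(d[1], d[2], n))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3]
    if (k > 0) out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

setMethod("show", "PatchSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf("PatchSet: %d patches (%s)\n", length(object),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})
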