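## augmentation: elastic and affine patch distortions for training-set
## enlargement.  Rotation is deliberately absent: it was tried and rejected
## as an augmentation for this task, so it only exists behind an explicit
## flag.

#' Elastic distortion of a patch
#'
#' Draws per-axis displacement fields uniformly in [-1, 1], smooths them
#' with a Gaussian of width `sigma`, rescales the smoothed field to unit
#' peak magnitude and multiplies by `alpha` (so `alpha` is the peak
#' displacement in pixels), then resamples the patch bilinearly with border
#' replication.  `alpha = 0` returns the input unchanged.
#'
#' @param patch numeric matrix in [0, 1] (typically 32x32).
#' @param sigma Gaussian smoothing width of the displacement field (px).
#' @param alpha peak displacement (px).
#' @param seed integer seed; the distortion is deterministic given it.
#' @return distorted patch, same shape, values within [0, 1].
#' @export
elasticDistort <- function(patch, sigma = 4, alpha = 2, seed = 1L) {
  if (alpha == 0) return(patch)
  nr <- nrow(patch); nc <- ncol(patch)
  withSeed(seed, {
    dr <- matrix(runif(nr * nc, -1, 1), nr, nc)
    dc <- matrix(runif(nr * nc, -1, 1), nr, nc)
    rad <- min(2L * ceiling(2 * sigma) + 1L,
               2L * (min(nr, nc) %/% 2L) - 1L)  # kernel must fit the patch
    dr <- as.matrix(EBImage::gblur(dr, sigma = sigma, radius = rad))
    dc <- as.matrix(EBImage::gblur(dc, sigma = sigma, radius = rad))
    mr <- max(abs(dr)); mc <- max(abs(dc))
    if (mr > 1e-12) dr <- dr / mr
    if (mc > 1e-12) dc <- dc / mc
    rows <- matrix(seq_len(nr), nr, nc) + alpha * dr
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + alpha * dc
    out <- bilinearSample(patch, as.vector(rows), as.vector(cols))
    matrix(out, nr, nc)
  })
}

#' Affine distortion of a patch (no rotation)
#'
#' Random anisotropic scaling, shear and translation within the stated
#' ranges, applied about the patch centre with bilinear resampling and
#' border replication.  There is deliberately no rotation component by
#' default; set `allow_rotation` with a `rotation_range` (degrees) to
#' reintroduce it explicitly.
#'
#' @param patch numeric matrix in [0, 1].
#' @param scale_range multiplicative scale range per axis.
#' @param shear_range shear range in degrees.
#' @param translation_range translation range in pixels.
#' @param seed integer seed.
#' @param allow_rotation logical; off by default.
#' @param rotation_range rotation range in degrees when allowed.
#' @return distorted patch, same shape, values within [0, 1].
#' @export
affineDistort <- function(patch, scale_range = c(0.9, 1.1),
                          shear_range = c(-5, 5),
                          translation_range = c(-2, 2), seed = 1L,
                          allow_rotation = FALSE,
                          rotation_range = c(-10, 10)) {
  nr <- nrow(patch); nc <- ncol(patch)
  withSeed(seed, {
    sx <- runif(1, scale_range[1], scale_range[2])
    sy <- runif(1, scale_range[1], scale_range[2])
    sh <- tan(runif(1, shear_range[1], shear_range[2]) * pi / 180)
    tr <- runif(2, translation_range[1], translation_range[2])
    A <- matrix(c(sx, 0, sh * sx, sy), 2, 2)
    if (allow_rotation) {
      th <- runif(1, rotation_range[1], rotation_range[2]) * pi / 180
      A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% A
    }
    Ainv <- solve(A)
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    rows <- matrix(seq_len(nr), nr, nc) - ctr[1]
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[2]
    src_r <- Ainv[1, 1] * (rows - tr[1]) + Ainv[1, 2] * (cols - tr[2]) + ctr[1]
    src_c <- Ainv[2, 1] * (rows - tr[1]) + Ainv[2, 2] * (cols - tr[2]) + ctr[2]
    matrix(bilinearSample(patch, as.vector(src_r), as.vector(src_c)), nr, nc)
  })
}

#' Enlarge a patch set by elastic + affine augmentation
#'
#' Output size is `factor` times the input; the originals are retained and
#' each extra copy is an elastic distortion (sigma in [3, 6], alpha in
#' [1, 4]) followed by an affine distortion, with labels preserved.
#' Deterministic given the seed.
#'
#' @param data a [PatchSet] of enhanced (post-CLAHE) patches.
#' @param factor integer >= 1.
#' @param seed integer seed.
#' @return a [PatchSet] of `factor * length(data)` patches.
#' @export
augmentPatchSet <- function(data, factor, seed = 1L) {
  factor <- as.integer(factor)
  if (factor < 1) stop("augmentation factor must be >= 1")
  if (factor == 1L) return(data)
  n <- length(data)
  arr <- patchArray(data)
  labs <- patchLabels(data)
  withSeed(seed, {
    extra <- (factor - 1L) * n
    out <- array(0, c(32L, 32L, extra))
    outLab <- character(extra)
    subseeds <- sample.int(2^30, 2L * extra)
    k <- 0L
    for (rep in seq_len(factor - 1L)) {
      for (i in seq_len(n)) {
        k <- k + 1L
        sg <- runif(1, 3, 6); al <- runif(1, 1, 4)
        p <- elasticDistort(arr[, , i], sigma = sg, alpha = al,
                            seed = subseeds[2L * k - 1L])
        p <- affineDistort(p, seed = subseeds[2L * k])
        out[, , k] <- clampUnit(p)
        outLab[k] <- labs[i]
      }
    }
    aug <- new("PatchSet", enhanced = out,
               raw = array(0, c(10L, 10L, 0L)), labels = outLab,
               centers = matrix(NA_integer_, extra, 2L))
    c(data, aug)
  })
}
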