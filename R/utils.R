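## Internal helpers shared across modules.

.alrlsCache <- new.env(parent = emptyenv())

## Evaluate expr with a local RNG stream; the caller's RNG state survives.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clampUnit <- function(x) pmin(pmax(x, 0), 1)

## Binary disk of lattice sites within `radius` of the centre, cached.
diskKernel <- function(radius) {
  key <- paste0("disk", radius)
  k <- .alrlsCache[[key]]
  if (is.null(k)) {
    r <- ceiling(radius)
    d <- seq(-r, r)
    k <- outer(d, d, function(i, j) (i^2 + j^2 <= radius^2 + 1e-9)) * 1
    .alrlsCache[[key]] <- k
  }
  k
}

## Disk convolution (unnormalized sums) with zero boundary, which matches
## clipping the disk at the image border.  Kernels larger than the image
## (global-statistics limits) are handled by zero-padding the image first.
convDisk <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nrow(x) || kc > ncol(x)) {
    big <- matrix(0, max(nrow(x), kr), max(ncol(x), kc))
    big[seq_len(nrow(x)), seq_len(ncol(x))] <- x
    return(as.matrix(EBImage::filter2(big, kernel,
                                      boundary = 0))[seq_len(nrow(x)),
                                                     seq_len(ncol(x)),
                                                     drop = FALSE])
  }
  as.matrix(EBImage::filter2(x, kernel, boundary = 0))
}

## Bounding box of a logical mask, expanded by `margin` and clipped.
maskBBox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(max(1L, min(idx[, 1]) - margin), min(nrow(mask), max(idx[, 1]) + margin),
    max(1L, min(idx[, 2]) - margin), min(ncol(mask), max(idx[, 2]) + margin))
}

## Quantize a bounding box outward to a multiple of `q` so that per-crop
## cached quantities (ball area, image moments) are reused across iterations.
quantizeBBox <- function(bb, q, nr, nc) {
  c(max(1L, (bb[1] - 1L) %/% q * q + 1L),
    min(nr, ((bb[2] + q - 1L) %/% q) * q),
    max(1L, (bb[3] - 1L) %/% q * q + 1L),
    min(nc, ((bb[4] + q - 1L) %/% q) * q))
}

## Morphological dilation of a logical matrix by a disk of radius r.
dilateMask <- function(mask, r) {
  if (r < 1) return(mask)
  k <- diskKernel(r)
  convDisk(mask * 1, k) > 0.5
}

## Replicate-padded central differences.
shiftUp <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shiftDown <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shiftLeft <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shiftRight <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

gradCentral <- function(m) {
  list(dr = (shiftDown(m) - shiftUp(m)) / 2,
       dc = (shiftRight(m) - shiftLeft(m)) / 2)
}

## Bilinear sampling of `img` at fractional (rows, cols), replicate border.
bilinearSample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

## Exact signed distance field of a mask (negative inside), pixel-centred:
## boundary pixels sit at +-0.5.
sdfFromMask <- function(fg) {
  dIn <- t(as.matrix(EBImage::distmap(EBImage::Image(t(fg * 1)))))
  dOut <- t(as.matrix(EBImage::distmap(EBImage::Image(t((!fg) * 1)))))
  ifelse(fg, -(dIn - 0.5), dOut - 0.5)
}

## 5x5 running maximum filter (replicate border), used to keep spatially
## smooth per-pixel speed scales.
localMax5 <- function(m) {
  r1 <- pmax(shiftUp(m), m, shiftDown(m))
  r2 <- pmax(shiftUp(r1), r1, shiftDown(r1))
  c1 <- pmax(shiftLeft(r2), r2, shiftRight(r2))
  pmax(shiftLeft(c1), c1, shiftRight(c1))
}

## Stable two-class softmax on an n x 2 matrix of logits.
softmax2 <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m); e2 <- exp(z[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}
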