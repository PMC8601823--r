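## Independent brute-force oracles used to pin down the vectorized
## implementations.  Everything here is written as plainly as possible
## (explicit per-cell loops, no shared code with the package internals).

## Naive local statistics: loop over every cell of the clipped disk.
naiveLocalStats <- function(image, phi, center, radius, eps) {
  A_u <- 0; A_v <- 0; su <- 0; sv <- 0
  for (r in seq_len(nrow(image))) {
    for (c0 in seq_len(ncol(image))) {
      if ((r - center[1])^2 + (c0 - center[2])^2 <= radius^2 + 1e-9) {
        h <- heaviside(phi[r, c0], eps)
        A_u <- A_u + h
        A_v <- A_v + (1 - h)
        su <- su + h * image[r, c0]
        sv <- sv + (1 - h) * image[r, c0]
      }
    }
  }
  list(u = if (A_u > 1e-8) su / A_u else 0,
       v = if (A_v > 1e-8) sv / A_v else 0,
       A_u = A_u, A_v = A_v)
}

## Naive localized speeds: statistics from the big ball, Dirac-weighted
## residual from the small arc disk, cell by cell.
naiveUmSpeed <- function(image, phi, x, cfg) {
  st <- naiveLocalStats(image, phi, x, cfg@ballRadius, cfg@epsHeaviside)
  s <- 0
  for (r in seq_len(nrow(image))) {
    for (c0 in seq_len(ncol(image))) {
      if ((r - x[1])^2 + (c0 - x[2])^2 <=
          min(cfg@arcRadius, cfg@ballRadius)^2 + 1e-9) {
        s <- s + dirac(phi[r, c0], cfg@epsHeaviside) *
          (cfg@lambda1 * (image[r, c0] - st$u)^2 -
           cfg@lambda2 * (image[r, c0] - st$v)^2)
      }
    }
  }
  s
}

naiveMsSpeed <- function(image, phi, x, cfg) {
  st <- naiveLocalStats(image, phi, x, cfg@ballRadius, cfg@epsHeaviside)
  s <- 0
  for (r in seq_len(nrow(image))) {
    for (c0 in seq_len(ncol(image))) {
      if ((r - x[1])^2 + (c0 - x[2])^2 <=
          min(cfg@arcRadius, cfg@ballRadius)^2 + 1e-9) {
        s <- s + dirac(phi[r, c0], cfg@epsHeaviside) *
          (cfg@lambda1 * (image[r, c0] - st$u)^2 / st$A_u -
           cfg@lambda2 * (image[r, c0] - st$v)^2 / st$A_v)
      }
    }
  }
  s
}

## A small self-contained *global* Chan--Vese segmenter (full-grid means,
## no localization, no narrow band): the independent reference for the
## global-limit equivalence check.
globalChanVese <- function(image, phi, mu = 0.05, lambda1 = 1, lambda2 = 1,
                           iters = 400, dt = 0.5, eps = 1.5) {
  for (it in seq_len(iters)) {
    Hin <- heaviside(phi, eps)
    c1 <- sum(Hin * image) / max(sum(Hin), 1e-8)
    c2 <- sum((1 - Hin) * image) / max(sum(1 - Hin), 1e-8)
    d <- dirac(phi, eps)
    kap <- curvatureField(phi)
    G <- lambda1 * (image - c1)^2 - lambda2 * (image - c2)^2
    M <- max(abs(G))
    if (M > 0) G <- G / M
    phi <- phi + dt * (d * eps) * (G + mu * kap)
    if (it %% 4 == 0) phi <- alrls:::sdfFromMask(phi <= 0)
  }
  phi <= 0
}

## Random two-level disk scene: a dark disk on a bright background (or the
## reverse), the canonical test image for region-based segmentation.
randomTwoLevelScene <- function(n = 32, seed = 1) {
  set.seed(seed)
  ctr <- c(runif(1, 13, 19), runif(1, 13, 19))
  rad <- runif(1, 6, 9)
  lev <- sort(runif(2, 0, 1))
  while (diff(lev) < 0.4) lev <- sort(runif(2, 0, 1))
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  inside <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
  img <- matrix(lev[2], n, n)
  img[inside] <- lev[1]
  list(image = img, truth = inside, center = round(ctr), radius = rad)
}
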