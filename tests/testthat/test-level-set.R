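test_that("circle initialization is an exact signed distance field", {
  phi <- initPhiCircle(c(64, 64), c(32, 32), 3)
  expect_equal(phi[32, 32], -3)
  expect_lt(min(abs(phi)), 0.5)            # lattice sites near the circle
  area <- sum(phi <= 0)
  expect_lt(abs(area - pi * 9), 0.1 * pi * 9 + 3)
  g <- alrls:::gradCentral(phi)
  mag <- sqrt(g$dr^2 + g$dc^2)
  far <- phi > 2 & phi < 20                # exterior, clear of the cone apex
  expect_lt(max(abs(mag[far] - 1)), 0.01)
  expect_error(initPhiCircle(c(64, 64), c(3, 32), 5), "border")
  expect_error(initPhiCircle(c(64, 64), c(32, 32), 1.5), "radius")
})

test_that("mollified Heaviside/Dirac pair has the step/impulse properties", {
  expect_equal(heaviside(0), 0.5)
  expect_gt(heaviside(-10 * 1.5), 0.99)
  expect_lt(heaviside(10 * 1.5), 0.01)
  x <- seq(-5, 5, 0.25)
  expect_equal(heaviside(x) + heaviside(-x), rep(1, length(x)))
  ## dirac peaks at 1/eps for the cosine pair and integrates to one
  expect_equal(dirac(0, 1.5), 1 / 1.5)
  expect_lt(dirac(5 * 1.5, 1.5), 0.05 * dirac(0, 1.5))
  zz <- seq(-75, 75, 0.01)
  expect_equal(sum(dirac(zz, 1.5)) * 0.01, 1, tolerance = 0.01)
  ## dirac is the derivative magnitude of heaviside
  h <- 1e-5
  num <- abs((heaviside(0.7 + h) - heaviside(0.7 - h)) / (2 * h))
  expect_equal(num, dirac(0.7), tolerance = 1e-6)
  expect_error(heaviside(1, eps = 0), "width")
  expect_error(dirac(1, eps = -1), "width")
})

test_that("narrow band matches a brute-force scan and flags saturation", {
  phi <- initPhiCircle(c(64, 64), c(32, 32), 10)
  b <- narrowBand(phi, 2)
  expect_identical(b, abs(phi) <= 2)
  expect_true(all(abs(phi[b]) <= 2))
  expect_equal(sum(b), sum(abs(phi) <= 2))
  expect_true(all(narrowBand(phi, max(abs(phi)) + 1)))
  expect_error(narrowBand(phi, 0.5), "width")
})

test_that("curvature approximates 1/r on circles, 0 on planes, with positive convex sign", {
  phi <- initPhiCircle(c(64, 64), c(32, 32), 8)
  k <- curvatureField(phi)
  onC <- which(abs(phi) < 0.3, arr.ind = TRUE)
  kc <- k[onC]
  expect_lt(max(abs(kc - 1 / 8)) / (1 / 8), 0.15)
  expect_true(all(kc > 0))                 # convex foreground: positive
  plane <- matrix(seq_len(64), 64, 64) - 20.5
  expect_lt(max(abs(curvatureField(plane)[5:60, 5:60])), 1e-10)
  expect_equal(curvatureAt(phi, c(32, 40)), k[32, 40])
})

test_that("distance regularization restores |grad phi| = 1 from both sides", {
  phi <- initPhiCircle(c(48, 48), c(24, 24), 9)
  band <- narrowBand(phi, 6)
  sdfErr <- function(p) {
    g <- alrls:::gradCentral(p)
    mean(abs(sqrt(g$dr^2 + g$dc^2)[band] - 1))
  }
  ## an exact SDF is a fixed point up to the per-axis discretization of the
  ## flux (on a radial field the axis-aligned differences are |cos|, |sin|
  ## of the local normal, so the stationarity error is O(1e-3))
  expect_lte(sdfErr(distanceRegularize(phi)), sdfErr(phi) + 0.003)
  ## too-steep and too-flat fields both relax toward a distance profile
  for (fac in c(2, 0.7)) {
    p <- phi * fac
    e0 <- sdfErr(p)
    p2 <- distanceRegularize(p)
    expect_lt(sdfErr(p2), e0)
  }
  expect_error(distanceRegularize(phi, weight = 0.3, dt = 1), "unstable")
})

test_that("inner contour extraction is one pixel thick and handles degenerate fields", {
  phi <- initPhiCircle(c(64, 64), c(32, 32), 10)
  cp <- contourPoints(phi)
  expect_true(all(phi[cp] <= 0))
  n <- sum(cp)
  expect_gt(n, 0.8 * 2 * pi * 10)
  expect_lt(n, 1.3 * 2 * pi * 10)
  expect_warning(contourPoints(matrix(-1, 8, 8)), "border")
  single <- matrix(1, 8, 8); single[4, 4] <- -0.5
  sp <- contourPoints(single)
  expect_identical(which(sp), which(single < 0))
  expect_false(any(contourPoints(matrix(2, 8, 8))))
})

test_that("one evolution step: null dynamics, sign convention, locality", {
  ph <- cleanPhantom()
  img <- phantomImage(ph)
  cfg <- runConfig()
  phi <- initPhiCircle(dim(img), c(64, 64), 8)

  ## uniform negative speed grows the foreground (interior-negative phi)
  st <- newEvolutionState(phi)
  a0 <- sum(phi <= 0)
  for (i in 1:10) st <- evolveStep(st, matrix(-1, 128, 128), runConfig(mu = 0))
  expect_gt(sum(st@phi <= 0), a0)

  ## zero speed and mu = 0: the interface is untouched and the field moves
  ## only by the regularizer's small discretization residual
  st2 <- evolveStep(newEvolutionState(phi), matrix(0, 128, 128),
                    runConfig(mu = 0))
  expect_identical(st2@phi <= 0, phi <= 0)
  expect_lt(max(abs(st2@phi - phi)), 0.2)

  ## locality: pixels outside the band (and its 3-px regularization margin)
  ## are bit-identical
  band <- narrowBand(phi, cfg@bandWidth)
  touched <- alrls:::dilateMask(band, 3)
  st3 <- evolveStep(newEvolutionState(phi), matrix(-0.5, 128, 128), cfg)
  expect_identical(st3@phi[!touched], phi[!touched])

  ## strong curvature with zero data speed shortens the contour
  wig <- initPhiCircle(dim(img), c(64, 64), 10)
  set.seed(9)
  wig[narrowBand(wig, 1)] <- wig[narrowBand(wig, 1)] + runif(sum(narrowBand(wig, 1)), -0.4, 0.4)
  stw <- newEvolutionState(wig)
  len0 <- sum(contourPoints(wig))
  cfgK <- runConfig(mu = 5)
  for (i in 1:20) stw <- evolveStep(stw, matrix(0, 128, 128), cfgK)
  expect_lte(sum(contourPoints(stw@phi)), len0)

  expect_error(evolveStep(newEvolutionState(phi),
                          matrix(NaN, 128, 128), cfg), "non-finite")
})
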