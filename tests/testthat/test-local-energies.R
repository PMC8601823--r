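test_that("ball masks are exact disks, clipped at borders", {
  b <- ballMask(c(20, 20), 1, c(40, 40))
  expect_equal(sum(b$mask), 5)             # centre + 4-neighbours
  expect_true(b$mask[which(b$rows == 20), which(b$cols == 20)])

  corner <- ballMask(c(1, 1), 10, c(40, 40))
  full <- ballMask(c(20, 20), 10, c(40, 40))
  expect_lt(sum(corner$mask), sum(full$mask))
  expect_equal(sum(corner$mask) / sum(full$mask), 0.25, tolerance = 0.2)

  ## brute-force scan oracle for the cell count
  cnt <- 0
  for (r in 1:40) for (c0 in 1:40)
    if ((r - 20)^2 + (c0 - 20)^2 <= 25 + 1e-9) cnt <- cnt + 1
  expect_equal(sum(ballMask(c(20, 20), 5, c(40, 40))$mask), cnt)
  expect_error(ballMask(c(20, 20), 0.2, c(40, 40)), "radius")
  expect_error(ballMask(c(50, 20), 5, c(40, 40)), "outside")
})

test_that("local statistics and speeds match brute-force loop oracles", {
  cfg <- runConfig(ball_radius = 5, arc_radius = 3)
  set.seed(42)
  worstS <- 0; worstU <- 0; worstM <- 0
  for (k in 1:50) {
    img <- matrix(runif(16 * 16), 16, 16)
    phi <- matrix(runif(16 * 16, -4, 4), 16, 16)
    x <- c(sample(3:14, 1), sample(3:14, 1))
    st <- localStats(img, phi, ballMask(x, cfg@ballRadius, c(16, 16)),
                     cfg@epsHeaviside)
    ref <- naiveLocalStats(img, phi, x, cfg@ballRadius, cfg@epsHeaviside)
    worstS <- max(worstS, abs(st$u - ref$u), abs(st$v - ref$v),
                  abs(st$A_u - ref$A_u), abs(st$A_v - ref$A_v))
    worstU <- max(worstU, abs(umSpeed(img, phi, x, cfg) -
                              naiveUmSpeed(img, phi, x, cfg)))
    worstM <- max(worstM, abs(msSpeed(img, phi, x, cfg) -
                              naiveMsSpeed(img, phi, x, cfg)))
  }
  expect_lt(worstS, 1e-10)
  expect_lt(worstU, 1e-10)
  expect_lt(worstM, 1e-10)
})

test_that("the vectorized speed field agrees with the per-point operators", {
  cfg <- runConfig(ball_radius = 5, arc_radius = 3)
  set.seed(7)
  img <- matrix(runif(24 * 24), 24, 24)
  phi <- initPhiCircle(c(24, 24), c(12, 12), 6) +
    matrix(rnorm(24 * 24, 0, 0.1), 24, 24)
  parts <- alrls:::speedFieldCrop(img, phi, cfg)
  for (x in list(c(12, 18), c(8, 12), c(15, 9))) {
    expect_equal(parts$speed[x[1], x[2]],
                 as.numeric(umSpeed(img, phi, x, cfg)), tolerance = 1e-9)
  }
  cfgMS <- runConfig(energy_model = "MS", ball_radius = 5, arc_radius = 3)
  partsMS <- alrls:::speedFieldCrop(img, phi, cfgMS)
  expect_equal(partsMS$speed[12, 18],
               as.numeric(msSpeed(img, phi, c(12, 18), cfgMS)),
               tolerance = 1e-9)
})

test_that("speed signs: equilibrium on a symmetric edge, expansion in a dark cavity", {
  cfg <- runConfig(ball_radius = 6, arc_radius = 4)
  ## symmetric two-level step with the contour exactly on the edge
  img <- matrix(0.2, 32, 32); img[, 17:32] <- 0.8
  phi <- matrix(rep(seq_len(32) - 16.5, each = 32), 32, 32)
  s <- umSpeed(img, phi, c(16, 16), cfg)
  expect_lt(abs(s), 0.4)                  # near zero vs O(5) off-equilibrium
  ## contour strictly inside the dark cavity, bright ring within the ball:
  ## the force must drive expansion (negative under positive-shrinks)
  ph <- cleanPhantom()
  img2 <- phantomImage(ph)
  phi2 <- initPhiCircle(dim(img2), c(64, 64), 8)
  cp <- which(contourPoints(phi2), arr.ind = TRUE)
  sp <- vapply(seq_len(nrow(cp)), function(i)
    as.numeric(umSpeed(img2, phi2, cp[i, ], runConfig())), numeric(1))
  expect_lt(mean(sp), 0)
  expect_gt(mean(sp < 0), 0.9)
  ## null weights give zero speed
  expect_equal(as.numeric(umSpeed(img2, phi2, c(64, 72),
                                  runConfig(lambda1 = 1e-12, lambda2 = 1e-12))),
               0, tolerance = 1e-9)
})

test_that("interior/exterior relabeling with swapped weights flips both speeds", {
  cfg12 <- runConfig(ball_radius = 5, arc_radius = 3,
                     lambda1 = 1.3, lambda2 = 0.6)
  cfg21 <- runConfig(ball_radius = 5, arc_radius = 3,
                     lambda1 = 0.6, lambda2 = 1.3)
  set.seed(11)
  for (k in 1:5) {
    img <- matrix(runif(16 * 16), 16, 16)
    phi <- matrix(runif(16 * 16, -3, 3), 16, 16)
    x <- c(sample(4:13, 1), sample(4:13, 1))
    expect_equal(as.numeric(umSpeed(img, -phi, x, cfg21)),
                 -as.numeric(umSpeed(img, phi, x, cfg12)), tolerance = 1e-9)
    expect_equal(as.numeric(msSpeed(img, -phi, x, cfg21)),
                 -as.numeric(msSpeed(img, phi, x, cfg12)), tolerance = 1e-9)
  }
})

test_that("energy: zero for MS on constants, linear in mu, degenerate regions flagged", {
  cfg <- runConfig(energy_model = "MS", mu = 0)
  img <- matrix(0.5, 32, 32)
  phi <- initPhiCircle(c(32, 32), c(16, 16), 6)
  expect_equal(energyValue(img, phi, cfg), 0, tolerance = 1e-9)
  ## doubling mu doubles the regularization part exactly
  set.seed(3)
  img2 <- matrix(runif(32 * 32), 32, 32)
  e0 <- energyValue(img2, phi, runConfig(mu = 0))
  e1 <- energyValue(img2, phi, runConfig(mu = 0.1))
  e2 <- energyValue(img2, phi, runConfig(mu = 0.2))
  expect_equal(e2 - e0, 2 * (e1 - e0), tolerance = 1e-9)
  ## fully interior ball: degenerate exterior flagged, zero speed
  phiAll <- matrix(-10, 16, 16)
  s <- umSpeed(img[1:16, 1:16], phiAll, c(8, 8), runConfig(ball_radius = 4))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  ## constant image: u = v = c
  stc <- localStats(matrix(0.3, 16, 16), matrix(rnorm(256), 16, 16),
                    ballMask(c(8, 8), 5, c(16, 16)))
  expect_equal(stc$u, 0.3, tolerance = 1e-12)
  expect_equal(stc$v, 0.3, tolerance = 1e-12)
})
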