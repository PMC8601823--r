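test_that("compensation term: analytic zeros, printed values, bounds, monotonicity", {
  expect_equal(compensationTerm(c(1, 0), 1, 1), 0)
  expect_equal(compensationTerm(c(0, 1), 1, 1), 1.5 * exp(sqrt(2)),
               tolerance = 1e-12)
  expect_equal(compensationTerm(c(0.5, 0.5), 1, 1), 0.5 * exp(sqrt(2)),
               tolerance = 1e-12)
  ## non-negative over the whole probability square
  g <- seq(0, 1, by = 0.01)
  vals <- outer(g, g, Vectorize(function(p1, p2)
    compensationTerm(c(p1, p2), 1, 1)))
  expect_gte(min(vals), 0)
  ## strictly decreasing in p1 along p2 = 1 - p1
  p1 <- seq(0, 1, length.out = 100)
  tv <- vapply(p1, function(p) compensationTerm(c(p, 1 - p), 1, 1),
               numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_error(compensationTerm(c(-0.1, 0.5), 1, 1), "probabilities")
})

test_that("the decision rule drops ambiguous calls and fixes the others", {
  cfg <- runConfig()
  expect_equal(decidePoint(c(0.9, 0.1), cfg), "confirmed_boundary")
  expect_equal(decidePoint(c(0.45, 0.55), cfg), "ambiguous")   # |diff| = 0.1
  expect_equal(decidePoint(c(0.1, 0.9), cfg), "compensated")
  expect_equal(decidePoint(c(0.65, 0.35), cfg), "confirmed_boundary")
  expect_equal(decidePoint(c(0.4, 0.6), cfg), "ambiguous")     # exactly 0.2
  expect_error(decidePoint(c(NA, 0.5), cfg), "probabilities")
})

test_that("stalled points: empty before the window, all stalled at a settled interface", {
  cfg <- runConfig()
  ph <- cleanPhantom()
  phi <- initPhiCircle(dim(phantomImage(ph)), c(64, 64), 8)
  st <- newEvolutionState(phi)
  expect_false(any(detectStalledPoints(st, cfg)))   # window not elapsed
  ## zero speed: the interface never moves; after the window every contour
  ## point is stalled
  for (i in 1:7) st <- evolveStep(st, matrix(0, 128, 128), runConfig(mu = 0))
  stalled <- detectStalledPoints(st, cfg)
  cp <- contourPoints(st@phi)
  expect_gte(sum(stalled & cp) / sum(cp), 0.99)
  ## a moving interface is never reported stalled
  st2 <- newEvolutionState(phi)
  for (i in 1:7) st2 <- evolveStep(st2, matrix(-3, 128, 128),
                                   runConfig(mu = 0))
  expect_false(any(detectStalledPoints(st2, runConfig(mu = 0))))
})

test_that("applying compensation boosts only compensated points, outward", {
  set.seed(4)
  speed <- matrix(rnorm(32 * 32), 32, 32)
  m0 <- matrix(runif(32 * 32, 0.5, 2), 32, 32)
  cfg <- runConfig()
  comp <- matrix(0, 32, 32)
  expect_identical(applyCompensation(speed, comp, m0, cfg), speed)
  comp[10, 12] <- compensationTerm(c(0, 1), 1, 1)
  out <- applyCompensation(speed, comp, m0, cfg)
  expect_lt(out[10, 12], speed[10, 12])    # outward = more negative
  expect_equal(out[10, 12], speed[10, 12] - comp[10, 12] * m0[10, 12])
  ## the boost spreads over the point's arc disk...
  expect_lt(out[10 + cfg@arcRadius, 12], speed[10 + cfg@arcRadius, 12])
  ## ...and no further
  far <- abs(row(speed) - 10) + abs(col(speed) - 12) > 2 * cfg@arcRadius
  expect_identical(out[far], speed[far])
  ## direct coupling skips the local Dirac mass
  cfgD <- runConfig(compensation_coupling = "direct")
  outD <- applyCompensation(speed, comp, m0, cfgD)
  expect_equal(outD[10, 12], speed[10, 12] - comp[10, 12])
})

test_that("point classification is deterministic and a valid two-class softmax", {
  model <- toyTrainedCNN()
  ph <- lesionPhantom()
  img <- phantomImage(ph)
  loc <- c(64, 64)
  p1 <- classifyPoint(model, img, loc)
  p2 <- classifyPoint(model, img, loc)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  untrained <- buildCNN(cnnSpec(d1 = 2L, d2 = 2L, fc1 = 8L, fc2 = 4L))
  expect_error(classifyPoint(untrained, img, loc), "trained")
})
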