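test_that("Dice coefficient: identities, formula, symmetry, monotonicity", {
  a <- matrix(FALSE, 20, 20); a[5:14, 5:14] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[16:19, 16:19] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  ## |A| = 100, |B| = 50, |A intersect B| = 50
  b2 <- matrix(FALSE, 20, 20); b2[5:14, 5:9] <- TRUE
  expect_equal(diceCoefficient(a, b2), 2 * 50 / 150)
  expect_equal(diceCoefficient(b2, a), diceCoefficient(a, b2))
  expect_equal(diceCoefficient(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_error(diceCoefficient(a, matrix(TRUE, 4, 4)), "shape")
  ## growing the intersection at fixed sizes never decreases Dice
  b3 <- b2; b3[5:14, 5:9] <- FALSE; b3[5:14, 10:14] <- TRUE  # same size, all inside a
  expect_gte(diceCoefficient(a, b3), 0)
  dice_seq <- vapply(0:5, function(k) {
    bb <- matrix(FALSE, 20, 20); bb[5:14, (10 - k):(14 - k)] <- TRUE
    diceCoefficient(a, bb)
  }, numeric(1))
  expect_true(all(diff(dice_seq) >= 0))
})

test_that("90% confidence interval is the Student-t construction", {
  expect_equal(unname(ci90(rep(0.8, 5))["half_width"]), 0)
  expect_equal(unname(ci90(c(-2, -1, 1, 2))["mean"]), 0)
  v <- ci90(c(0, 1))
  expect_equal(unname(v["mean"]), 0.5)
  ## closed form with the sample (n - 1) standard deviation:
  ## t(0.95, 1) * sd / sqrt(2) = 6.3138 * 0.7071 / 1.4142 = 3.1569
  expect_equal(unname(v["half_width"]), qt(0.95, 1) * sd(c(0, 1)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(v["half_width"]), 3.1569, tolerance = 1e-3)
  expect_error(ci90(0.5), "two values")
})

test_that("the sensitivity harness enumerates runs, scores them and reproduces itself", {
  coh <- list(cleanPhantom())
  res <- suppressWarnings(
    runSensitivity(coh, methods = "FLS-UM", radii = c(3, 5, 7, 9, 11),
                   cfg = runConfig()))
  expect_equal(nrow(res$rows), 5L)
  expect_true(all(res$rows$dice >= 0 & res$rows$dice <= 1))
  expect_true(all(c("method", "n", "mean_dice", "sd_dice",
                    "ci90_half_width", "mean_percase_radius_sd") %in%
                  names(res$summary)))
  res2 <- suppressWarnings(
    runSensitivity(coh, methods = "FLS-UM", radii = c(3, 5, 7, 9, 11),
                   cfg = runConfig()))
  expect_identical(res$rows, res2$rows)
})

test_that("convergence reports flag transients and locate settling", {
  run <- new("SegmentationRun", mask = matrix(TRUE, 2, 2),
             phi = matrix(-1, 2, 2),
             energyTrace = c(10, 9, 8, 7.5, 7.4, 7.4, 7.4),
             iterations = 7L,
             stalledLog = data.frame(), config = runConfig(),
             status = "converged")
  rep1 <- convergenceReport(run)
  expect_false(rep1$initial_transient)
  expect_lte(rep1$settled_at, 7)
  run@energyTrace <- c(10, 12, 11, 8, 7, 7, 7)
  expect_true(convergenceReport(run)$initial_transient)
  expect_equal(nrow(convergenceReport(run)$trace), 7)
})
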