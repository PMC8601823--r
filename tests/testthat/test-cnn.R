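test_that("architecture validation and seeded initialization", {
  expect_error(cnnSpec(flatten = 1234L), "flatten")
  spec <- cnnSpec()
  expect_equal(spec@flatten, 8L * 8L * 25L)
  m1 <- buildCNN(spec, seed = 3L)
  m2 <- buildCNN(spec, seed = 3L)
  expect_identical(m1@weights, m2@weights)
  expect_true(all(abs(m1@weights$W1) <= 0.2 + 1e-12))  # truncated at 2 sd
  ## forward pass on a zero image: finite probabilities summing to 1
  m1@trained <- TRUE
  p <- predictCNN(m1, matrix(0, 32, 32))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("loss equals cross-entropy plus the L2 term, with exact linearity in eta", {
  spec <- cnnSpec(d1 = 2L, d2 = 2L, fc1 = 16L, fc2 = 8L)
  m <- buildCNN(spec, seed = 1L)
  set.seed(2)
  X <- array(runif(32 * 32 * 2), c(32, 32, 2))
  labs <- c("boundary", "lesion")
  l2 <- sum(m@weights$W1^2) + sum(m@weights$W2^2) + sum(m@weights$Wf1^2) +
    sum(m@weights$Wf2^2) + sum(m@weights$Wf3^2)
  l0 <- cnnLoss(m, X, labs, eta = 0)
  l1 <- cnnLoss(m, X, labs, eta = 1)
  l2x <- cnnLoss(m, X, labs, eta = 2)
  expect_equal(l1 - l0, l2 / 2, tolerance = 1e-9)
  expect_equal(l2x - l0, l2, tolerance = 1e-9)
  ## zeroed weights give the uniform softmax: -log(1/2) per example
  mz <- m
  for (nm in c("W1", "W2", "Wf1", "Wf2", "Wf3", "b1", "b2", "bf1", "bf2",
               "bf3", "be1", "be2"))
    mz@weights[[nm]][] <- 0
  expect_equal(cnnLoss(mz, X, labs, eta = 0), log(2), tolerance = 1e-9)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- cnnSpec(d1 = 2L, d2 = 2L, fc1 = 16L, fc2 = 8L)
  m <- buildCNN(spec, seed = 3L)
  set.seed(1)
  X <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  targets <- c(1L, 2L, 1L)
  eta <- 0.7
  res <- alrls:::.cnnLossGrad(m, X, targets, eta, keepProb = 1)
  h <- 1e-5
  worst <- 0
  for (nm in names(m@weights)) {
    n <- length(m@weights[[nm]])
    for (idx in unique(c(1L, n %/% 2L + 1L, n))) {
      wp <- m; wp@weights[[nm]][idx] <- wp@weights[[nm]][idx] + h
      wm <- m; wm@weights[[nm]][idx] <- wm@weights[[nm]][idx] - h
      num <- (alrls:::.cnnLossGrad(wp, X, targets, eta, keepProb = 1,
                                   wantGrads = FALSE)$loss -
              alrls:::.cnnLossGrad(wm, X, targets, eta, keepProb = 1,
                                   wantGrads = FALSE)$loss) / (2 * h)
      ana <- res$grads[[nm]][idx]
      worst <- max(worst, abs(ana - num) / max(abs(ana) + abs(num), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training learns separable patches, follows the schedule, and is reproducible", {
  data <- toySeparableSet()
  m <- buildCNN(cnnSpec(d1 = 4L, d2 = 4L, fc1 = 64L, fc2 = 32L), seed = 1L)
  cfg <- trainingConfig(max_steps = 200L, initial_lr = 1e-3,
                        log_every = 20L, seed = 2L)
  res <- trainCNN(m, data, cfg)
  expect_gte(tail(res$log$val_accuracy, 1), 0.95)
  ## loss trend: the end of training is below the start
  expect_lt(mean(tail(res$log$loss, 3)), mean(head(res$log$loss, 3)))
  ## learning-rate schedule arithmetic: two decay boundaries by step 25000
  lrAt <- function(step) cfg$initial_lr * cfg$lr_decay^(step %/% 10000L)
  expect_equal(lrAt(25000), cfg$initial_lr * 0.9997^2)
  expect_equal(res$log$lr[1], cfg$initial_lr)
  ## same seed twice: identical weights
  res2 <- trainCNN(m, data, cfg)
  expect_identical(res$model@weights, res2$model@weights)
  expect_error(trainCNN(m, data[patchLabels(data) == "lesion"], cfg),
               "both classes")
})

test_that("inference uses frozen statistics: deterministic, normalized, order-fixed", {
  model <- toyTrainedCNN()
  set.seed(5)
  batch <- array(runif(32 * 32 * 4), c(32, 32, 4))
  P <- predictCNN(model, batch)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
  expect_identical(P, predictCNN(model, batch))
  expect_identical(colnames(P), c("boundary", "lesion"))
  ## the toy classes are separable: bright patches score as lesion
  bright <- clampUnit(matrix(rnorm(1024, 0.75, 0.08), 32, 32))
  dark <- clampUnit(matrix(rnorm(1024, 0.25, 0.08), 32, 32))
  expect_gt(predictCNN(model, bright)["lesion"], 0.5)
  expect_gt(predictCNN(model, dark)["boundary"], 0.5)
})

test_that("checkpoints round-trip bitwise and reject corrupt or mismatched files", {
  model <- toyTrainedCNN()
  d <- withr::local_tempdir()
  f <- file.path(d, "model.rds")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  set.seed(6)
  probe <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predictCNN(back, probe), predictCNN(model, probe))
  ## corrupted blob
  writeBin(as.raw(1:32), f)
  expect_error(loadCheckpoint(f), "corrupt")
  ## sidecar version mismatch
  saveCheckpoint(model, f)
  sc <- jsonlite::read_json(paste0(f, ".json"))
  sc$format_version <- 99L
  jsonlite::write_json(sc, paste0(f, ".json"), auto_unbox = TRUE)
  expect_error(loadCheckpoint(f), "version")
  expect_error(loadCheckpoint(file.path(d, "nope.rds")), "missing")
})
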