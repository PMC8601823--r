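## Shared, lazily built fixtures.  Heavy objects (a trained classifier, the
## stalling-cohort comparison) are computed once per test run and cached so
## several test files can share them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## A small lesion-free phantom used by many unit tests.
cleanPhantom <- function(seed = 5L)
  fixture(paste0("clean", seed), function()
    generatePhantom(phantomSpec(n_lesions = 0L, seed = seed)))

## A lesioned phantom with both patch classes available.
lesionPhantom <- function(seed = 11L)
  fixture(paste0("lesion", seed), function()
    generatePhantom(phantomSpec(n_lesions = 2L,
                                lesion_radius_range = c(5, 7),
                                wall_attached_prob = 1, seed = seed)))

## A quickly trained classifier on trivially separable synthetic patches:
## bright-noise vs dark-noise 32x32 patches.  Used where a *trained* model
## is needed but its accuracy is incidental.
toySeparableSet <- function(n_per_class = 120, seed = 7) {
  set.seed(seed)
  n <- 2L * n_per_class
  arr <- array(0, c(32, 32, n))
  labs <- character(n)
  for (i in seq_len(n_per_class)) {
    arr[, , i] <- clampUnit(matrix(rnorm(1024, 0.25, 0.08), 32, 32))
    labs[i] <- "boundary"
    arr[, , n_per_class + i] <- clampUnit(matrix(rnorm(1024, 0.75, 0.08), 32, 32))
    labs[n_per_class + i] <- "lesion"
  }
  new("PatchSet", enhanced = arr, raw = array(0, c(10, 10, 0)),
      labels = labs, centers = matrix(NA_integer_, n, 2))
}

toyTrainedCNN <- function()
  fixture("toycnn", function() {
    m <- buildCNN(cnnSpec(d1 = 4L, d2 = 4L, fc1 = 64L, fc2 = 32L), seed = 1L)
    trainCNN(m, toySeparableSet(), trainingConfig(max_steps = 150,
                                                  initial_lr = 1e-3,
                                                  log_every = 50,
                                                  seed = 2L))$model
  })

## The full-size phantom-trained classifier shared by the acceptance tests
## (criterion-scale training is expensive; build once).
phantomTrainedCNN <- function()
  fixture("phantomcnn", function() {
    coh <- generateCohort(40, "stalling", seed = 301)
    base <- harvestPatches(coh, 5000, seed = 302)
    aug <- augmentPatchSet(base, 2L, seed = 77)
    m <- buildCNN(cnnSpec(), seed = 5L)
    trainCNN(m, aug, trainingConfig(max_steps = 3000L, seed = 6L))
  })

## FLS vs compensated comparison on the stalling cohort, shared by the
## escape-property and initialization-sensitivity tests.
stallingComparison <- function()
  fixture("stallcmp", function() {
    model <- phantomTrainedCNN()$model
    coh <- generateCohort(20, "stalling", seed = 501)
    suppressWarnings(
      runSensitivity(coh, methods = c("FLS-UM", "ALRLS-UM"),
                     radii = c(3, 5, 7, 9, 11), cfg = runConfig(),
                     model = model))
  })
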