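test_that("min-max normalization handles endpoints, midpoints and degenerate input", {
  expect_equal(range(normalizeImage(matrix(c(0, 255, 100, 30), 2, 2))), c(0, 1))
  m <- normalizeImage(matrix(c(10, 20, 30, 10), 2, 2))
  expect_equal(sort(unique(as.vector(m))), c(0, 0.5, 1))
  expect_warning(z <- normalizeImage(matrix(5, 4, 4)), "constant")
  expect_true(all(z == 0))
  expect_error(normalizeImage(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("CLAHE keeps range, preserves constants and does not wash out contrast", {
  flat <- matrix(0.4, 32, 32)
  expect_identical(claheEnhance(flat), flat)

  set.seed(1)
  noisy <- matrix(runif(64 * 64), 64, 64)
  out <- claheEnhance(noisy)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)

  ## a two-level step image: tiles containing the edge have a bimodal
  ## histogram, so equalization stretches the step itself (tiles wholly on
  ## one plateau are flat and map to mid-grey -- that is CLAHE semantics,
  ## not contrast loss at the edge)
  step <- matrix(0.4, 32, 32)
  step[, 17:32] <- 0.6
  enh <- claheEnhance(step, clip_limit = 0.9)
  expect_gte(mean(enh[, 17:20]) - mean(enh[, 13:16]), 0.2 - 1e-9)

  expect_error(claheEnhance(matrix(0.5, 8, 8), tile_grid = c(16, 16)),
               "tile grid")
  expect_error(claheEnhance(matrix(2, 32, 32)), "normalized")
})

test_that("bilinear upsampling is constant-preserving, monotone and bounded", {
  expect_equal(bilinearUpsample(matrix(0.7, 10, 10)),
               matrix(0.7, 32, 32), tolerance = 1e-12)
  ramp <- matrix(rep(seq(0, 1, length.out = 10), each = 10), 10, 10,
                 byrow = FALSE)
  up <- bilinearUpsample(ramp)
  expect_true(all(diff(up[, 16]) >= -1e-12))     # monotone along rows
  set.seed(2)
  rnd <- matrix(runif(100), 10, 10)
  up2 <- bilinearUpsample(rnd)
  expect_gte(min(up2), min(rnd) - 1e-9)
  expect_lte(max(up2), max(rnd) + 1e-9)
  ## commutes with constant shifts
  expect_equal(bilinearUpsample(rnd + 0.1), up2 + 0.1, tolerance = 1e-9)
})

test_that("patch extraction windows, rejection and purity", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  p <- extractPatch(img, c(20, 20))
  expect_equal(p@raw, img[15:24, 15:24])
  expect_equal(dim(p@enhanced), c(32L, 32L))

  ## boundary-exact window: centre (6,6) of a 10x10 image is the whole image
  small <- matrix(runif(100), 10, 10)
  expect_equal(extractPatch(small, c(6, 6))@raw, small)

  expect_error(extractPatch(img, c(2, 2)), class = "alrls_border")
  expect_error(extractPatch(img, c(20, 38)), class = "alrls_border")

  ## purity: the pipeline applied twice gives identical arrays
  expect_identical(extractPatch(img, c(20, 20))@enhanced, p@enhanced)

  ## constant image -> constant enhanced patch
  cp <- extractPatch(matrix(0.3, 40, 40), c(20, 20))
  expect_true(all(cp@raw == 0.3))
  expect_equal(max(cp@enhanced) - min(cp@enhanced), 0)
})
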