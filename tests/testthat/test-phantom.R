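test_that("phantom generation: two-level interior, determinism, lesion components", {
  ## noiseless, bias-free, lesion-free: exactly two levels within the
  ## cavity-plus-wall region
  sp0 <- phantomSpec(n_lesions = 0L, noise_sigma = 0, bias_amplitude = 0,
                     seed = 3L)
  ph0 <- generatePhantom(sp0)
  wall <- alrls:::dilateMask(cavityMask(ph0), 6) & !cavityMask(ph0)
  vals <- unique(as.vector(phantomImage(ph0)[cavityMask(ph0) | wall]))
  expect_equal(sort(vals), c(0.12, 0.85))

  ## determinism
  expect_identical(phantomImage(generatePhantom(sp0)), phantomImage(ph0))

  ## three well-separated lesions give three connected components
  sp3 <- phantomSpec(n_lesions = 3L, lesion_radius_range = c(3, 4),
                     noise_sigma = 0, seed = 9L)
  ph3 <- generatePhantom(sp3)
  lab <- EBImage::bwlabel(EBImage::Image(t(lesionMask(ph3) * 1)))
  expect_lte(max(lab), 3)
  expect_gte(max(lab), 1)
  expect_true(all(lesionMask(ph3) | !lesionMask(ph3)))
  expect_true(validObject(ph3))

  ## infeasible geometry rejected
  expect_error(phantomSpec(n_lesions = 1L, lesion_radius_range = c(20, 25)),
               "smaller than the cavity")
})

test_that("phantom intensity histogram of a lesioned phantom is multimodal", {
  ph <- lesionPhantom()
  dens <- density(as.vector(phantomImage(ph)), bw = 0.03)
  peaks <- sum(diff(sign(diff(dens$y))) == -2)
  expect_gte(peaks, 2)
})

test_that("labelled patch sampling is balanced, on-boundary and deterministic", {
  ph <- lesionPhantom()
  ps <- sampleLabelledPatches(ph, 10, seed = 4)
  expect_equal(length(ps), 20L)
  expect_equal(as.integer(table(patchLabels(ps))), c(10L, 10L))
  ## every centre sits on its class's boundary set
  air <- airMask(ph)
  nbAir <- alrls:::shiftUp(air) | alrls:::shiftDown(air) |
    alrls:::shiftLeft(air) | alrls:::shiftRight(air)
  lesionEdge <- lesionMask(ph) & nbAir
  for (i in which(patchLabels(ps) == "lesion"))
    expect_true(lesionEdge[ps@centers[i, 1], ps@centers[i, 2]])
  ps2 <- sampleLabelledPatches(ph, 10, seed = 4)
  expect_identical(patchArray(ps), patchArray(ps2))
  expect_identical(ps@centers, ps2@centers)
})

test_that("cohorts are reproducible, within spec ranges, and serializable", {
  coh <- generateCohort(5, "mixed", seed = 21)
  coh2 <- generateCohort(5, "mixed", seed = 21)
  expect_identical(cohortManifest(coh), cohortManifest(coh2))
  nl <- vapply(coh, function(s) s@spec@nLesions, integer(1))
  expect_true(all(nl >= 0 & nl <= 3))
  for (s in coh) expect_true(validObject(s))
  expect_error(generateCohort(0), "size")

  d <- withr::local_tempdir()
  writeCohort(coh[1:2], d)
  expect_true(file.exists(file.path(d, "image_001.png")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- readMask(file.path(d, "cavity_002.png"))
  expect_identical(back, cavityMask(coh[[2]]))
})

test_that("pooled harvesting fills classifier-scale sets from many phantoms", {
  coh <- generateCohort(4, "stalling", seed = 31)
  ps <- harvestPatches(coh, 60, seed = 32)
  expect_equal(length(ps), 120L)
  expect_equal(as.integer(table(patchLabels(ps))), c(60L, 60L))
  expect_gte(min(patchArray(ps)), 0)
  expect_lte(max(patchArray(ps)), 1)
})

test_that("the seed point sits deep in the air pocket", {
  ph <- lesionPhantom()
  sp <- seedPoint(ph)
  expect_true(airMask(ph)[sp$center[1], sp$center[2]])
  expect_gt(sp$maxRadius, 2)
  ## a circle of the reported radius fits inside the air region
  phi <- initPhiCircle(dim(phantomImage(ph)), sp$center,
                       max(2, floor(sp$maxRadius)))
  expect_true(all(airMask(ph)[phi <= 0]))
})
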