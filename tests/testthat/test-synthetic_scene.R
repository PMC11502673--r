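quietSpec <- function(...) {
  sceneSpec(psfSigma = c(0, 0), poissonScale = 0, gaussianSd = 0,
            beadAntigen = 0, ...)
}

test_that("identical spec and seed give voxel-identical scenes", {
  sp <- sceneSpec(nCompartments = 12L, polarization = 0.4, seed = 99L)
  s1 <- generateScene(sp)
  s2 <- generateScene(sp)
  for (ch in channelNames(s1))
    expect_identical(stackData(getChannel(s1, ch)),
                     stackData(getChannel(s2, ch)))
  expect_identical(groundTruth(s1)@compartments,
                   groundTruth(s2)@compartments)
  ## and the generator does not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generateScene(sp)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a spec with no compartments yields noise-only channels and empty truth", {
  sp <- sceneSpec(nCompartments = 0L, beadAntigen = 0, psfSigma = c(0, 0),
                  poissonScale = 0, gaussianSd = 0.05, seed = 3L)
  sc <- generateScene(sp)
  gt <- groundTruth(sc)
  expect_identical(nrow(gt@compartments), 0L)
  expect_true(all(is.na(gt@expectedPI)))
  ## only Gaussian read noise: no structure anywhere
  a <- stackData(getChannel(sc, "LAMP1"))
  expect_lt(max(a), 0.5)
  expect_identical(volume(gt@models$LAMP1), 0)
})

test_that("unpolarized placement centres the fluorescence on the cell", {
  ## p = 0, many compartments, noise off: over seeds, the fluorescence
  ## centre of mass stays within 0.5 um of the cell centre
  dists <- vapply(1:20, function(s) {
    sc <- generateScene(quietSpec(nCompartments = 500L, polarization = 0,
                                  seed = s))
    cm <- centerOfMass(getChannel(sc, "LAMP1"))
    sqrt(sum((cm - groundTruth(sc)@cellCenter)^2))
  }, 0)
  expect_lt(mean(dists), 0.5)
})

test_that("placement-simulation oracle is monotone in p and ~0 when unpolarized", {
  specs <- lapply(c(0, 0.5, 1), function(p)
    sceneSpec(nCompartments = 40L, polarization = p, seed = 17L))
  est <- lapply(specs, expectedPolarity, nSim = 120L)
  m <- vapply(est, `[[`, 0, "mean")
  se <- vapply(est, function(e) e$sd / sqrt(e$nSim), 0)
  expect_lt(abs(m[1]), 4 * se[1])      # symmetric when p = 0
  expect_gt(m[2], m[1])
  expect_gt(m[3], m[2])
  expect_gt(m[3], 0.25)                # strongly polarized at p = 1
  ## deterministic given (spec, seed)
  again <- expectedPolarity(specs[[2]], nSim = 120L)
  expect_identical(again$mean, est[[2]]$mean)
})

test_that("ground-truth polarity matches the rendered measurement scene by scene", {
  for (s in 1:5) {
    sc <- generateScene(quietSpec(nCompartments = 30L, polarization = 0.7,
                                  seed = 100L + s))
    gt <- groundTruth(sc)
    measured <- indexValue(scenePolarity(sc, "LAMP1"))
    ## same scene, so the only differences are voxelization of the sphere
    ## masses and the uniform-vs-analytic cell centroid
    expect_lt(abs(measured - gt@expectedPI["LAMP1"]), 0.08)
  }
})

test_that("noise- and blur-free volumes are recovered by segmentation", {
  sc <- generateScene(quietSpec(nCompartments = 6L, radiusMean = 0.45,
                                radiusSd = 0.05, seed = 8L))
  gt <- groundTruth(sc)
  bin <- thresholdStack(getChannel(sc, "LAMP1"), "fixed", 0.5)
  comps <- linkRoi3d(bin)
  expect_equal(volume(comps), volume(gt@models$LAMP1))
  labOracle <- bfsLabel(stackData(gt@models$LAMP1), offsets3d8z())
  expect_identical(countComponents(comps), max(labOracle))
})

test_that("impossible placements fail with the violated constraint named", {
  sp <- sceneSpec(nCompartments = 2L, radiusMean = 3.4, radiusSd = 0,
                  cellSemiAxes = c(3.5, 3.5, 3.5), seed = 1L)
  expect_error(generateScene(sp), "cannot fit strictly")
})

test_that("marker membership follows the marker table and flags unlabeled", {
  sp <- quietSpec(nCompartments = 200L, seed = 12L,
                  markerTable = c(LAMP1 = 1, Ag = 0, SNX5 = 0.5))
  gt <- groundTruth(generateScene(sp))
  expect_true(all(gt@compartments$LAMP1))
  expect_false(any(gt@compartments$Ag))
  expect_gt(sum(gt@compartments$SNX5), 60)
  expect_lt(sum(gt@compartments$SNX5), 140)
  expect_false(any(gt@compartments$unlabeled))   # LAMP1 everywhere
  sp2 <- quietSpec(nCompartments = 50L, seed = 13L,
                   markerTable = c(LAMP1 = 0.5, Ag = 0, SNX5 = 0))
  gt2 <- groundTruth(generateScene(sp2))
  expect_identical(gt2@compartments$unlabeled, !gt2@compartments$LAMP1)
})
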