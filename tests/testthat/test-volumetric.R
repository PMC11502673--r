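vs <- c(0.3, 0.1, 0.1)

mkModel <- function(arr, marker = "m") asVoxelModel(binaryStack(arr, vs), marker)

test_that("voxel intersection: idempotence, disjointness, exhaustive oracle", {
  set.seed(61)
  d <- c(5, 8, 8)
  a <- mkModel(array(runif(prod(d)) < 0.4, d), "LAMP1")
  expect_equal(volume(intersect(a, a)), volume(a))
  left <- array(FALSE, d); left[, , 1:3] <- TRUE
  right <- array(FALSE, d); right[, , 6:8] <- TRUE
  expect_identical(volume(intersect(mkModel(left), mkModel(right))), 0)
  ## offset boxes vs double-loop AND count
  b1 <- array(FALSE, d); b1[2:4, 2:6, 2:6] <- TRUE
  b2 <- array(FALSE, d); b2[3:5, 4:8, 4:8] <- TRUE
  got <- sum(stackData(intersect(mkModel(b1, "x"), mkModel(b2, "y"))))
  cnt <- 0L
  for (iz in 1:5) for (iy in 1:8) for (ix in 1:8)
    if (b1[iz, iy, ix] && b2[iz, iy, ix]) cnt <- cnt + 1L
  expect_identical(got, cnt)
  ## commutative/associative; bounded by the smaller parent
  c3 <- mkModel(array(runif(prod(d)) < 0.5, d), "z")
  expect_identical(stackData(intersect(a, c3)), stackData(intersect(c3, a)))
  expect_identical(
    stackData(intersect(intersect(a, c3), mkModel(b1))),
    stackData(intersect(a, intersect(c3, mkModel(b1)))))
  expect_lte(volume(intersect(a, c3)), min(volume(a), volume(c3)))
  expect_identical(intersect(a, c3)@marker, "LAMP1&z")
  wrong <- asVoxelModel(binaryStack(array(TRUE, c(2, 2, 2)), vs), "w")
  expect_error(intersect(a, wrong), "shape")
})

test_that("compartment selection is all-or-nothing and marker-monotone", {
  d <- c(4, 10, 10)
  m <- array(FALSE, d)
  m[1:2, 1:4, 1:4] <- TRUE        # component A: 32 voxels
  m[4, 7:9, 7:9] <- TRUE          # component B: 9 voxels
  comps <- linkRoi3d(binaryStack(m, vs))
  ## marker touching A by a single voxel selects all of A
  mk <- array(FALSE, d); mk[1, 1, 1] <- TRUE
  sel <- selectCompartmentsContaining(comps, mkModel(mk, "Ag"))
  expect_length(sel@selectedIds, 1L)
  expect_equal(sel@selectedVolume, 32 * prod(vs))
  expect_equal(sel@fraction, 100 * 32 / 41)
  ## no overlap: nothing selected
  off <- array(FALSE, d); off[3, 1, 1] <- TRUE
  sel0 <- selectCompartmentsContaining(comps, mkModel(off, "Ag"))
  expect_length(sel0@selectedIds, 0L)
  expect_identical(sel0@selectedVolume, 0)
  ## enlarging the marker never deselects
  grow <- mk; grow[4, 8, 8] <- TRUE
  sel2 <- selectCompartmentsContaining(comps, mkModel(grow, "Ag"))
  expect_true(all(sel@selectedIds %in% sel2@selectedIds))
  ## minOverlap knob
  expect_length(
    selectCompartmentsContaining(comps, mkModel(grow, "Ag"),
                                 minOverlap = 2L)@selectedIds, 0L)
  ## mixed population vs per-component brute force
  set.seed(62)
  for (i in 1:6) {
    b <- randomBinary(c(5, 9, 9), 0.25, vs)
    cc <- linkRoi3d(b)
    mark <- mkModel(array(runif(405) < 0.1, c(5, 9, 9)), "Ag")
    got <- selectCompartmentsContaining(cc, mark)
    expVol <- 0
    for (id in componentTable(cc)$id) {
      if (any(cc@labels == id & stackData(mark)))
        expVol <- expVol + componentTable(cc)$volume[
          componentTable(cc)$id == id]
    }
    expect_equal(got@selectedVolume, expVol)
  }
})

test_that("nested containment percentages match hand-computed voxel arithmetic", {
  d <- c(3, 12, 12)
  lamp <- array(FALSE, d)
  lamp[1, 1:3, 1:3] <- TRUE       # comp 1: 9 voxels
  lamp[1, 6:8, 6:8] <- TRUE       # comp 2: 9 voxels
  lamp[3, 10:12, 10:12] <- TRUE   # comp 3: 9 voxels
  comps <- linkRoi3d(binaryStack(lamp, vs))
  ag <- array(FALSE, d); ag[1, 1:2, 1:2] <- TRUE         # touches comp 1 only
  snx <- array(FALSE, d)
  snx[1, 1, 1] <- TRUE            # 1 voxel in comp 1 (selected)
  snx[1, 6:7, 6] <- TRUE          # 2 voxels in comp 2 (not selected)
  nf <- nestedFraction(comps, mkModel(ag, "Ag"), mkModel(snx, "SNX5"))
  expect_equal(nf$primaryPercent, 100 * 9 / 27)
  expect_equal(nf$nestedPercent, 100 * 1 / 3)
  expect_identical(nf$undefined, character())
  ## every compartment overlapping marker1 -> 100%
  all1 <- nestedFraction(comps, mkModel(lamp, "Ag"), mkModel(snx, "SNX5"))
  expect_equal(all1$primaryPercent, 100)
  ## empty marker2 -> undefined-flagged, not zero
  nf0 <- nestedFraction(comps, mkModel(ag, "Ag"),
                        mkModel(array(FALSE, d), "SNX5"))
  expect_true(is.na(nf0$nestedPercent))
  expect_true("nestedPercent" %in% nf0$undefined)
})

test_that("volume binning respects the stated boundary convention", {
  vsC <- c(1, 0.5, 0.5)   # 0.25 um^3 voxels keep the slabs small
  mkComps <- function(vols) {
    ## synthesise LabeledComponents with prescribed volumes via flat slabs
    nv <- round(vols / prod(vsC))
    d <- c(length(nv) * 2, 10, ceiling(max(nv) / 10) + 1)
    arr <- array(FALSE, d)
    for (i in seq_along(nv)) {
      lin <- arrayInd(seq_len(nv[i]), d[2:3])
      arr[cbind(2 * i - 1, lin)] <- TRUE
    }
    linkRoi3d(binaryStack(arr, vsC))
  }
  small <- mkComps(c(1, 1, 1))
  expect_equal(as.vector(binVolumes(small)), c(100, 0, 0))
  mixed <- mkComps(c(2, 7, 20))
  pct <- binVolumes(mixed)
  expect_equal(as.vector(pct), 100 * c(2, 7, 20) / 29, tolerance = 0.01)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  ## boundary values: 6 goes to the middle bin (closed), 12 stays there
  edge <- mkComps(c(6, 12))
  expect_equal(as.vector(binVolumes(edge)), c(0, 100, 0), tolerance = 0.02)
  expect_error(binVolumes(small, c(12, 6)), "strictly increasing")
  none <- linkRoi3d(binaryStack(array(FALSE, c(2, 4, 4)), vs))
  expect_true(all(is.na(binVolumes(none))))
  expect_true(attr(binVolumes(none), "undefined"))
  expect_identical(countComponents(none), 0L)
})

test_that("component counts equal the flood-fill oracle", {
  k <- 4L
  d <- c(6, 20, 20)
  arr <- array(FALSE, d)
  ctrs <- list(c(2, 4, 4), c(2, 14, 5), c(4, 9, 15), c(5, 17, 17))
  for (ctr in ctrs)
    arr[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- TRUE
  expect_identical(countComponents(linkRoi3d(binaryStack(arr, vs))), k)
  set.seed(63)
  b <- randomBinary(c(6, 10, 10), 0.3, vs)
  expect_identical(countComponents(linkRoi3d(b)),
                   max(bfsLabel(stackData(b), offsets3d8z())))
})

test_that("Pearson matches its closed form; Manders sums intensities", {
  set.seed(64)
  d <- c(4, 6, 6)
  a <- channelStack("a", array(runif(prod(d)), d), vs)
  expect_equal(pearsonColoc(a, a), 1)
  inv <- channelStack("b", max(stackData(a)) - stackData(a), vs)
  expect_equal(pearsonColoc(a, inv), -1)
  b <- channelStack("b", array(runif(prod(d)), d), vs)
  msk <- binaryStack(array(runif(prod(d)) < 0.6, d), vs)
  expect_equal(pearsonColoc(a, b, msk),
               pearsonOracle(stackData(a)[stackData(msk)],
                             stackData(b)[stackData(msk)]))
  flat <- channelStack("f", array(2, d), vs)
  expect_error(pearsonColoc(a, flat), "zero variance")
  ## Manders M1
  ref <- array(FALSE, d); ref[1:2, , ] <- TRUE
  inside <- array(0, d); inside[1, , ] <- 3
  expect_identical(mandersM1(channelStack("i", inside, vs),
                             mkModel(ref, "LAMP1")), 1)
  outside <- array(0, d); outside[4, , ] <- 3
  expect_identical(mandersM1(channelStack("o", outside, vs),
                             mkModel(ref, "LAMP1")), 0)
  half <- array(0, d); half[2, , ] <- 5; half[3, , ] <- 5
  expect_identical(mandersM1(channelStack("h", half, vs),
                             mkModel(ref, "LAMP1")), 0.5)
  ## invariant to uniform rescaling of the intensity channel
  expect_equal(mandersM1(b, mkModel(ref, "L")),
               mandersM1(channelStack("b", stackData(b) * 12, vs),
                         mkModel(ref, "L")))
  expect_error(mandersM1(channelStack("z", array(0, d), vs),
                         mkModel(ref, "L")), "zero total")
})

test_that("noise-free synthetic truth reproduces nested fractions within a voxel shell", {
  sc <- generateScene(sceneSpec(nCompartments = 25L, psfSigma = c(0, 0),
                                poissonScale = 0, gaussianSd = 0,
                                beadAntigen = 0, seed = 71L))
  gt <- groundTruth(sc)
  ## segment the noise-free rendering exactly
  comps <- linkRoi3d(thresholdStack(getChannel(sc, "LAMP1"), "fixed", 0.5))
  nf <- nestedFraction(comps, gt@models$Ag, gt@models$SNX5)
  ## oracle: identical construction from the ground-truth LAMP1 model
  compsGT <- linkRoi3d(binaryStack(stackData(gt@models$LAMP1), voxelSize(sc)))
  nfGT <- nestedFraction(compsGT, gt@models$Ag, gt@models$SNX5)
  expect_equal(nf$primaryPercent, nfGT$primaryPercent)
  expect_equal(nf$nestedPercent, nfGT$nestedPercent)
})
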