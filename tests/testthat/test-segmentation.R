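vs <- c(0.3, 0.1, 0.1)

test_that("fixed thresholding keeps exactly the voxels above the value", {
  a <- array(0, c(3, 8, 8)); a[2, 4, 5] <- 255
  ch <- channelStack("x", a, vs)
  expect_identical(sum(stackData(thresholdStack(ch, "fixed", 100))), 1L)
  expect_false(any(stackData(thresholdStack(ch, "fixed", 255))))  # strict >
  expect_false(any(stackData(thresholdStack(ch, "fixed", 1e6))))
  expect_error(thresholdStack(ch, "fixed"), "requires a threshold")
})

test_that("Otsu separates a bimodal channel with <1% misclassification", {
  set.seed(31)
  d <- c(6, 40, 40)
  truth <- array(runif(prod(d)) < 0.3, d)
  a <- array(0, d)
  a[!truth] <- pmax(rnorm(sum(!truth), 20, 5), 0)
  a[truth] <- pmax(rnorm(sum(truth), 200, 20), 0)
  bin <- thresholdStack(channelStack("x", a, vs), "otsu")
  misOtsu <- mean(stackData(bin) != truth)
  expect_lt(misOtsu, 0.01)
  ## exhaustive threshold sweep oracle: Otsu is close to the best achievable
  cand <- sort(unique(round(as.vector(a))))
  misBest <- min(vapply(cand, function(t) mean((a > t) != truth), 0))
  expect_lt(misOtsu, misBest + 0.01)
  expect_error(thresholdStack(channelStack("c", array(7, d), vs), "otsu"),
               "constant")
})

test_that("per-slice thresholds adapt to slice-wise intensity scales", {
  set.seed(32)
  d <- c(4, 30, 30)
  truth <- array(runif(prod(d)) < 0.2, d)
  a <- array(0, d)
  gain <- c(1, 5, 10, 20)
  for (iz in 1:4) {
    sl <- truth[iz, , ]
    base <- matrix(abs(rnorm(900, 2, 0.5)), 30, 30)
    base[sl] <- abs(rnorm(sum(sl), 20, 2))
    a[iz, , ] <- base * gain[iz]
  }
  bin <- thresholdStack(channelStack("x", a, vs), "otsu", perSlice = TRUE)
  expect_length(bin@provenance$threshold, 4L)
  expect_lt(mean(stackData(bin) != truth), 0.01)
})

test_that("slice erosion matches the 8-neighbourhood minimum oracle", {
  m <- array(FALSE, c(1, 5, 5)); m[1, 2:4, 2:4] <- TRUE
  e <- erodeSlices(binaryStack(m, vs), 1L)
  expect_identical(sum(stackData(e)), 1L)
  expect_true(stackData(e)[1, 3, 3])
  single <- array(FALSE, c(1, 4, 4)); single[1, 2, 2] <- TRUE
  expect_false(any(stackData(erodeSlices(binaryStack(single, vs)))))
  set.seed(33)
  r <- array(runif(3 * 12 * 12) < 0.6, c(3, 12, 12))
  er <- stackData(erodeSlices(binaryStack(r, vs), 1L))
  for (iz in 1:3)
    expect_identical(er[iz, , ], erodeOracle2d(r[iz, , ]))
  ## erosion is contractive; zero iterations is the identity
  expect_true(all(which(er) %in% which(r)))
  expect_identical(stackData(erodeSlices(binaryStack(r, vs), 0L)), r)
  ## two single steps compose to one double step
  expect_identical(stackData(erodeSlices(binaryStack(r, vs), 2L)),
                   stackData(erodeSlices(erodeSlices(binaryStack(r, vs)))))
})

test_that("3D linking: cubes, z-gaps, and agreement with a BFS oracle", {
  cube <- array(FALSE, c(4, 6, 6)); cube[2:3, 2:4, 2:4] <- TRUE
  comps <- linkRoi3d(binaryStack(cube, vs))
  expect_identical(countComponents(comps), 1L)
  expect_equal(componentTable(comps)$volume, sum(cube) * prod(vs))
  ## overlapping in (x, y) but separated by an all-false slice
  gap <- array(FALSE, c(5, 6, 6))
  gap[1:2, 2:4, 2:4] <- TRUE; gap[4:5, 2:4, 2:4] <- TRUE
  expect_identical(countComponents(linkRoi3d(binaryStack(gap, vs))), 2L)
  ## random sparse masks vs flood-fill oracle
  set.seed(34)
  for (i in 1:8) {
    b <- randomBinary(c(6, 10, 10), 0.25, vs)
    lab <- linkRoi3d(b)@labels
    oracle <- bfsLabel(stackData(b), offsets3d8z())
    expect_true(samePartition(lab, oracle))
    expect_identical(max(lab), max(oracle))
  }
})

test_that("component volumes conserve the model volume and survive slice reversal", {
  set.seed(35)
  b <- randomBinary(c(8, 14, 14), 0.3, vs)
  comps <- linkRoi3d(b)
  expect_equal(sum(componentTable(comps)$volume), volume(b))
  rev <- binaryStack(stackData(b)[dim(stackData(b))[1]:1, , ], vs)
  compsRev <- linkRoi3d(rev)
  expect_identical(countComponents(comps), countComponents(compsRev))
  expect_equal(sort(componentTable(comps)$volume),
               sort(componentTable(compsRev)$volume))
  ## ids sorted by size descending
  expect_false(is.unsorted(-componentTable(comps)$nVoxels))
})

test_that("2D particle filter applies the closed area window", {
  px <- c(0.1, 0.1)  # pixel area 0.01 um^2
  plane <- matrix(FALSE, 20, 30)
  plane[2:3, 2:3] <- TRUE            # 4 px = 0.04 um^2, below 0.10
  plane[8:11, 8:17] <- TRUE          # 40 px = 0.40 um^2, inside
  plane[14:18, 14:21] <- TRUE        # 40 px window edge case below
  out <- filterParticles2D(plane, 0.10, 4.00, px)
  expect_identical(nrow(out), 2L)
  ## particle exactly at max_area is included (inclusive bounds)
  exact <- matrix(FALSE, 25, 25); exact[3:22, 3:22] <- TRUE  # 400 px = 4.00
  expect_identical(nrow(filterParticles2D(exact, 0.10, 4.00, px)), 1L)
  expect_identical(nrow(filterParticles2D(exact, 0.10, 3.99, px)), 0L)
  expect_error(filterParticles2D(plane, -1, 4, px), "non-negative")
  expect_error(filterParticles2D(plane, 5, 4, px), "minArea")
  ## random planes against brute-force labeling + area filter
  set.seed(36)
  for (i in 1:5) {
    p <- matrix(runif(400) < 0.35, 20, 20)
    got <- nrow(filterParticles2D(p, 0.03, 0.20, px))
    lab <- bfsLabel(array(p, c(1, 20, 20)), offsets2d8())
    areas <- tabulate(lab[lab > 0]) * 0.01
    expect_identical(got, sum(areas >= 0.03 & areas <= 0.20))
  }
})
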