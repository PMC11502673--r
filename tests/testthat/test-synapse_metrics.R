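vs <- c(0.3, 0.1, 0.1)

mkScene <- function(a, maskArr = array(TRUE, dim(a)), name = "Ag") {
  scene(list(channelStack(name, a, vs)),
        beads = data.frame(x = 1, y = 1, z = 0.3, radius = 0.5),
        cellMask = binaryStack(maskArr, vs))
}

test_that("around-bead fraction: extremes, uniform oracle, radius monotonicity", {
  d <- c(4, 30, 30)
  bd <- beadROI(c(1.5, 1.5), beadRadius = 0.5, analysisRadius = 0.8)
  inDisc <- outer(((1:30 - 1) * 0.1 - 1.5)^2, ((1:30 - 1) * 0.1 - 1.5)^2,
                  "+") <= 0.8^2
  all3 <- aperm(array(inDisc, c(30, 30, 4)), c(3, 1, 2))
  aIn <- array(0, d); aIn[all3] <- 2
  msk <- binaryStack(array(TRUE, d), vs)
  expect_identical(
    aroundBeadFraction(channelStack("x", aIn, vs), bd, msk), 1)
  aOut <- array(1, d); aOut[all3] <- 0
  expect_identical(
    aroundBeadFraction(channelStack("x", aOut, vs), bd, msk), 0)
  ## uniform intensity: fraction = pixels in disc / pixels in cell
  u <- channelStack("u", array(1, d), vs)
  expect_equal(aroundBeadFraction(u, bd, msk), sum(inDisc) / (30 * 30))
  ## monotone non-decreasing in the analysis radius, in [0, 1] throughout
  set.seed(51)
  r <- channelStack("r", array(runif(prod(d)), d), vs)
  fr <- vapply(seq(0.5, 3, by = 0.25), function(rad)
    aroundBeadFraction(r, beadROI(c(1.5, 1.5), 0.5, rad), msk), 0)
  expect_false(is.unsorted(fr))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(aroundBeadFraction(channelStack("z", array(0, d), vs), bd, msk),
               "zero total")
})

test_that("antigen extraction normalizes to 100% at time 0", {
  base <- array(0, c(3, 20, 20))
  base[, 8:12, 8:12] <- 4
  mk <- function(scale, t) {
    s <- mkScene(base * scale)
    s@metadata$time <- t
    s
  }
  bd <- beadROI(c(1, 1), 0.5, 3.5)
  out <- extractionRemaining(list(mk(1, 0), mk(0.5, 30), mk(0.25, 60)),
                             "Ag", bd)
  expect_identical(out$percentRemaining[out$time == 0], 100)
  expect_equal(out$percentRemaining, c(100, 50, 25))
  ## arbitrary decay series vs direct per-pixel accumulation
  set.seed(52)
  decays <- c(1, runif(3))
  scenes <- lapply(seq_along(decays), function(i)
    mk(decays[i], c(0, 10, 20, 40)[i]))
  res <- extractionRemaining(scenes, "Ag", bd)
  disc <- outer(((1:20 - 1) * 0.1 - 1)^2, ((1:20 - 1) * 0.1 - 1)^2,
                "+") <= 3.5^2
  direct <- vapply(scenes, function(s) {
    pr <- apply(stackData(getChannel(s, "Ag")), c(2, 3), sum)
    sum(pr[disc])
  }, 0)
  expect_equal(res$percentRemaining, 100 * direct / direct[1])
  expect_error(extractionRemaining(list(mk(1, 10)), "Ag", bd), "time 0")
})

test_that("spreading area: mask counting, analytic disc, shoelace polygon", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  expect_equal(spreadingArea(m, c(0.1, 0.1)), 1.0)
  ## rasterized 5-um disc at 0.05-um pixels: within 1% of pi * 25
  px <- 0.05; n <- 220
  ctr <- (n - 1) / 2 * px
  disc <- outer(((1:n - 1) * px - ctr)^2, ((1:n - 1) * px - ctr)^2,
                "+") <= 25
  expect_lt(abs(spreadingArea(disc, c(px, px)) - 25 * pi) / (25 * pi), 0.01)
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(spreadingArea(sq), 4)
  expect_error(spreadingArea(matrix(FALSE, 5, 5), c(0.1, 0.1)), "empty")
})

test_that("recruitment index: uniform 0, central 3, peripheral -1, scale-free", {
  px <- c(0.05, 0.05)
  n <- 200
  ## polygon outline: a centred square of side 8 um
  poly <- cbind(c(1, 9, 9, 1), c(1, 1, 9, 9))
  uni <- matrix(1, n, n)
  expect_lt(abs(recruitmentIndex(uni, poly, px)), 0.02)
  ## all intensity inside the central quarter-area region
  ctr <- c(5, 5)
  central <- matrix(0, n, n)
  xs <- (col(central) - 1) * px[2]; ys <- (row(central) - 1) * px[1]
  ## guard bands keep rasterized region edges away from the intensity edges
  inWell <- abs(xs - ctr[1]) < 1.8 & abs(ys - ctr[2]) < 1.8
  central[inWell] <- 7
  expect_equal(recruitmentIndex(central, poly, px), 3, tolerance = 0.02)
  ## all intensity strictly outside the central region: exactly -1
  outBand <- abs(xs - ctr[1]) > 2.2 | abs(ys - ctr[2]) > 2.2
  peri <- matrix(0, n, n); peri[outBand] <- 3
  expect_equal(recruitmentIndex(peri, poly, px), -1)
  ## invariant to global intensity scaling; raster-mask outline agrees
  set.seed(53)
  img <- matrix(runif(n * n), n, n)
  v1 <- recruitmentIndex(img, poly, px)
  expect_equal(recruitmentIndex(img * 37.5, poly, px), v1)
  mask <- xs >= 1 & xs <= 9 & ys >= 1 & ys <= 9
  expect_equal(recruitmentIndex(img, mask, px), v1, tolerance = 0.05)
  expect_gte(v1, -1)
})

test_that("circularity: analytic circle and square, Crofton oracle, rugosity", {
  th <- seq(0, 2 * pi, length.out = 1025)[-1025]
  circle <- cbind(3 * cos(th), 3 * sin(th))
  expect_equal(circularity(circle), 1, tolerance = 1e-4)
  expect_equal(circularity(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), pi / 4,
               tolerance = 1e-12)
  ## rasterized ellipse: agreement with an independent Crofton perimeter
  px <- 0.05; n <- 220; ctr <- (n - 1) / 2 * px
  xs <- ((1:n) - 1) * px - ctr
  ell <- outer(xs^2 / 4, xs^2 / 16, function(a, b) a + b) <= 1
  cImpl <- circularity(ell, c(px, px))
  A <- sum(ell) * px^2
  cOracle <- 4 * pi * A / croftonPerimeter(ell, px)^2
  expect_lt(abs(cImpl - cOracle) / cOracle, 0.02)
  ## boundary rugosity decreases circularity of a disc
  rough <- cbind((3 + 0.25 * sin(12 * th)) * cos(th),
                 (3 + 0.25 * sin(12 * th)) * sin(th))
  expect_lt(circularity(rough), circularity(circle) - 0.05)
  expect_lt(circularity(circle), 1 + 1e-6)
  ## multi-component masks are rejected with advice
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(circularity(two, c(0.1, 0.1)), "largest component")
})

test_that("focus counting applies threshold and area window inside the outline", {
  px <- c(0.1, 0.1)
  img <- matrix(0, 60, 60)
  ## three discs of ~0.5 um^2 (r = 4 px -> 49 px -> 0.49 um^2)
  for (ctr in list(c(15, 15), c(30, 40), c(45, 20))) {
    d2 <- outer((1:60 - ctr[1])^2, (1:60 - ctr[2])^2, "+")
    img[d2 <= 16] <- 10
  }
  outline <- matrix(TRUE, 60, 60)
  pl <- synapticPlane(1L, list(actin = img), outline, px)
  expect_identical(countFoci(pl, "actin", 0.10, 4.00, "fixed", value = 5), 3L)
  expect_identical(countFoci(synapticPlane(1L, list(actin = img * 0),
                                           outline, px),
                             "actin", 0.10, 4.00, "fixed", value = 5), 0L)
  ## a single focus of ~8 um^2 exceeds the window
  big <- matrix(0, 60, 60)
  d2 <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+")
  big[d2 <= 16^2] <- 10   # r = 1.6 um -> ~8 um^2
  expect_identical(countFoci(synapticPlane(1L, list(actin = big), outline, px),
                             "actin", 0.10, 4.00, "fixed", value = 5), 0L)
})

test_that("intensity summaries match direct sums", {
  px <- c(0.1, 0.1)
  expect_equal(intensitySummary(matrix(4.2, 8, 8), pixelSize = px)$mean, 4.2)
  chk <- matrix(c(0, 10), 10, 10)
  expect_equal(intensitySummary(chk, pixelSize = px)$mean, 5)
  set.seed(54)
  img <- matrix(runif(100), 10, 10)
  msk <- matrix(runif(100) < 0.5, 10, 10)
  s <- intensitySummary(img, msk, px)
  expect_equal(s$integrated, sum(img[msk]))
  expect_equal(s$mean, sum(img[msk]) / sum(msk))
  expect_equal(s$area, sum(msk) * 0.01)
  expect_equal(s$density, s$integrated / s$area)
})

test_that("the synaptic plane is the slice of maximal template intensity", {
  a <- array(0, c(6, 10, 10))
  a[4, , ] <- 5; a[2, , ] <- 1
  sc <- mkScene(a, name = "actin")
  pl <- findSynapticPlane(sc, "actin")
  expect_identical(pl@zIndex, 4L)
  pl2 <- findSynapticPlane(sc, "actin", zIndex = 2L)
  expect_identical(pl2@zIndex, 2L)
})
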