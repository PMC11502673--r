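#' Threshold a channel into a binary marker model
#'
#' Voxels are true iff intensity strictly exceeds the threshold, computed
#' globally or per z-slice.  Otsu thresholds are obtained from the
#' intensity histogram (256 levels); a constant-intensity channel has no
#' separable classes and is an error under \code{method = "otsu"}.
#'
#' @param channel a \linkS4class{ChannelStack}
#' @param method \code{"otsu"} or \code{"fixed"}
#' @param value threshold for \code{method = "fixed"}
#' @param perSlice compute one threshold per z-slice instead of one global
#'   threshold (a constant slice thresholds to all-false)
#' @return a \linkS4class{BinaryStack} with the method recorded in its
#'   provenance
#' @examples
#' a <- array(0, c(2, 4, 4)); a[1, 2, 2] <- 255
#' sum(stackData(thresholdStack(
#'   channelStack("x", a, c(0.5, 0.1, 0.1)), "fixed", 100)))  # 1
#' @export
thresholdStack <- function(channel, method = c("otsu", "fixed"),
                           value = NULL, perSlice = FALSE) {
  stopifnot(is(channel, "ChannelStack"))
  method <- match.arg(method)
  a <- channel@data
  if (method == "fixed") {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    out <- a > value
    thr <- value
  } else if (!perSlice) {
    thr <- .otsuThreshold(a)
    out <- a > thr
  } else {
    out <- array(FALSE, dim(a))
    thr <- numeric(dim(a)[1L])
    for (iz in seq_len(dim(a)[1L])) {
      sl <- a[iz, , ]
      if (max(sl) == min(sl)) { thr[iz] <- max(sl); next }
      thr[iz] <- .otsuThreshold(sl)
      out[iz, , ] <- sl > thr[iz]
    }
  }
  binaryStack(out, channel@voxelSize,
              provenance = list(channel = channel@name, method = method,
                                threshold = thr, perSlice = perSlice))
}

.otsuThreshold <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo)
    stop("constant-intensity data: Otsu thresholding has no separable ",
         "classes; supply a fixed threshold instead")
  t01 <- EBImage::otsu(EBImage::Image((x - lo) / (hi - lo)),
                       range = c(0, 1), levels = 256L)
  lo + t01 * (hi - lo)
}

#' Per-slice 2D erosion of a binary model
#'
#' Each z-slice is eroded with a 3 x 3 square structuring element (pixels
#' outside the image are background), applied \code{iterations} times, to
#' refine segmentation boundaries.  Erosion never grows the set.
#'
#' @param binary a \linkS4class{BinaryStack}
#' @param iterations non-negative integer, default 1
#' @return the eroded \linkS4class{BinaryStack}
#' @export
erodeSlices <- function(binary, iterations = 1L) {
  stopifnot(is(binary, "BinaryStack"), iterations >= 0L)
  a <- binary@data
  offs <- .neighborOffsets(8L, linkZ = FALSE)
  for (it in seq_len(iterations)) {
    out <- a
    for (off in offs)
      out <- out & .shift3d(a, off[1], off[2], off[3], fill = FALSE)
    a <- out
  }
  prov <- binary@provenance
  prov$eroded <- (if (is.null(prov$eroded)) 0L else prov$eroded) +
    as.integer(iterations)
  binaryStack(a, binary@voxelSize, provenance = prov)
}

#' Link segmented slices into 3D compartments
#'
#' Connects true voxels into 3D regions of interest: 8-connectivity
#' in-plane (configurable to 4) and face adjacency between consecutive
#' z-slices (at least one overlapping voxel column links two slices'
#' regions).  Volumes are quantified by voxel counting times the physical
#' voxel volume; component ids are sorted by size, largest first.
#'
#' @param binary a \linkS4class{BinaryStack}
#' @param inPlane in-plane connectivity, 8 (default) or 4
#' @return a \linkS4class{LabeledComponents}
#' @examples
#' a <- array(FALSE, c(3, 5, 5)); a[1:2, 2:3, 2:3] <- TRUE
#' componentTable(linkRoi3d(binaryStack(a, c(0.5, 0.1, 0.1))))
#' @export
linkRoi3d <- function(binary, inPlane = 8L) {
  stopifnot(is(binary, "BinaryStack"), inPlane %in% c(4L, 8L))
  lab <- .labelComponents(binary@data, .neighborOffsets(inPlane, linkZ = TRUE))
  .componentsFromLabels(lab, binary@voxelSize)
}

.componentsFromLabels <- function(lab, vs) {
  k <- max(lab)
  if (k == 0L)
    return(new("LabeledComponents", labels = lab, voxelSize = vs,
               table = data.frame(id = integer(), nVoxels = integer(),
                                  volume = numeric(), cx = numeric(),
                                  cy = numeric(), cz = numeric(),
                                  xMin = numeric(), xMax = numeric(),
                                  yMin = numeric(), yMax = numeric(),
                                  zMin = integer(), zMax = integer())))
  idx <- which(lab > 0, arr.ind = TRUE)
  g <- lab[lab > 0]
  nvox <- tabulate(g, nbins = k)
  px <- (idx[, 3L] - 1) * vs["dx"][[1L]]
  py <- (idx[, 2L] - 1) * vs["dy"][[1L]]
  pz <- (idx[, 1L] - 1) * vs["dz"][[1L]]
  tb <- data.frame(
    id = seq_len(k), nVoxels = nvox, volume = nvox * prod(vs),
    cx = rowsum(px, g)[, 1L] / nvox, cy = rowsum(py, g)[, 1L] / nvox,
    cz = rowsum(pz, g)[, 1L] / nvox,
    xMin = tapply(px, g, min), xMax = tapply(px, g, max),
    yMin = tapply(py, g, min), yMax = tapply(py, g, max),
    zMin = as.integer(tapply(idx[, 1L], g, min)),
    zMax = as.integer(tapply(idx[, 1L], g, max)))
  ord <- order(-tb$nVoxels, tb$id)       # stable: size desc, then first-voxel
  tb <- tb[ord, , drop = FALSE]
  remap <- integer(k); remap[tb$id] <- seq_len(k)
  tb$id <- seq_len(k)
  rownames(tb) <- NULL
  lab2 <- lab
  lab2[lab > 0] <- remap[g]
  new("LabeledComponents", labels = lab2, voxelSize = vs, table = tb)
}

#' 2D particle analysis with a physical area window
#'
#' Labels 8-connected particles in a 2D binary plane and keeps those whose
#' physical area lies within \code{[minArea, maxArea]}, both bounds
#' inclusive (the closed range convention of the 0.10-4.00 micrometre^2
#' particle-size window).
#'
#' @param plane 2D logical matrix \code{[y, x]}
#' @param minArea,maxArea area bounds, micrometres^2
#' @param pixelSize \code{c(dy, dx)}, micrometres
#' @param connectivity 8 (default) or 4
#' @return data.frame with one row per surviving particle: \code{id},
#'   \code{nPixels}, \code{area}, centroid \code{cx, cy} (micrometres);
#'   the full label matrix is attached as attribute \code{labels}
#' @export
filterParticles2D <- function(plane, minArea = 0.10, maxArea = 4.00,
                              pixelSize, connectivity = 8L) {
  stopifnot(is.matrix(plane), is.logical(plane))
  if (minArea < 0 || maxArea < 0) stop("area bounds must be non-negative")
  if (minArea > maxArea) stop("minArea must be <= maxArea")
  dy <- pixelSize[1L]; dx <- pixelSize[2L]
  a3 <- array(plane, c(1L, dim(plane)))
  lab3 <- .labelComponents(a3, .neighborOffsets(as.integer(connectivity),
                                                linkZ = FALSE))
  lab <- lab3[1L, , ]
  k <- max(lab)
  pxArea <- dy * dx
  if (k == 0L) {
    out <- data.frame(id = integer(), nPixels = integer(), area = numeric(),
                      cx = numeric(), cy = numeric())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  g <- lab[lab > 0]
  npix <- tabulate(g, nbins = k)
  area <- npix * pxArea
  ## inclusive bounds, robust to floating-point area rounding
  tol <- 1e-9 * max(1, maxArea)
  keep <- which(area >= minArea - tol & area <= maxArea + tol)
  out <- data.frame(
    id = keep, nPixels = npix[keep], area = area[keep],
    cx = (rowsum((idx[, 2L] - 1) * dx, g)[, 1L] / npix)[keep],
    cy = (rowsum((idx[, 1L] - 1) * dy, g)[, 1L] / npix)[keep])
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}
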