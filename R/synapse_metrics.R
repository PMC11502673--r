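#' Construct the around-bead analysis disc
#'
#' @param center bead centre (x, y), micrometres
#' @param beadRadius bead radius, micrometres
#' @param analysisRadius radius of the concentric analysis disc measured
#'   from the bead centre, micrometres; the 3.5 default fully contains a
#'   3-micrometre bead plus a docking rim
#' @return a \linkS4class{BeadROI}
#' @export
beadROI <- function(center, beadRadius = 1.5, analysisRadius = 3.5) {
  new("BeadROI", center = as.numeric(center), beadRadius = beadRadius,
      analysisRadius = analysisRadius)
}

#' Construct a SynapticPlane
#'
#' @param zIndex 1-based z-slice index
#' @param images named list of 2D matrices \code{[y, x]}
#' @param outline N x 2 polygon (micrometres) or logical mask matrix
#' @param pixelSize \code{c(dy, dx)}, micrometres
#' @return a \linkS4class{SynapticPlane}
#' @export
synapticPlane <- function(zIndex, images, outline, pixelSize) {
  ps <- as.numeric(pixelSize); names(ps) <- c("dy", "dx")
  new("SynapticPlane", zIndex = as.integer(zIndex), images = images,
      outline = outline, pixelSize = ps)
}

#' Select the synaptic plane of a scene
#'
#' Chooses the z-slice with maximal integrated intensity of the given
#' channel (the actin/phalloidin channel in practice, mirroring manual
#' selection on the phalloidin label), or accepts an explicit slice.  The
#' outline is the cell-mask slice at that z.
#'
#' @param x a \linkS4class{Scene} with a cell mask
#' @param channel channel used to pick the slice
#' @param zIndex explicit slice (overrides the channel criterion)
#' @return a \linkS4class{SynapticPlane} carrying all channels
#' @export
findSynapticPlane <- function(x, channel = channelNames(x)[1L],
                              zIndex = NULL) {
  stopifnot(is(x, "Scene"))
  if (is.null(x@cellMask)) stop("scene has no cell mask to outline")
  if (is.null(zIndex)) {
    a <- getChannel(x, channel)@data
    a[!x@cellMask@data] <- 0
    zIndex <- which.max(apply(a, 1L, sum))
  }
  msk <- x@cellMask@data[zIndex, , ]
  if (!any(msk)) stop("cell mask is empty at slice ", zIndex)
  imgs <- lapply(x@channels, function(ch) ch@data[zIndex, , ])
  synapticPlane(zIndex, imgs, msk, voxelSize(x)[c("dy", "dx")])
}

## pixels (as a [y, x] logical matrix) whose centres fall inside an
## outline given as polygon (micrometres) or logical mask
.outlineMask <- function(outline, dimyx, pixelSize) {
  if (is.logical(outline)) return(outline)
  dy <- pixelSize[1L]; dx <- pixelSize[2L]
  px <- rep((seq_len(dimyx[2L]) - 1) * dx, each = dimyx[1L])
  py <- rep((seq_len(dimyx[1L]) - 1) * dy, times = dimyx[2L])
  matrix(.pointsInPolygon(px, py, outline), dimyx[1L], dimyx[2L])
}

#' Around-bead accumulation fraction of a channel
#'
#' Fraction of a channel's total cellular fluorescence that lies, in the
#' z-projection sense, within the concentric analysis disc around the
#' bead: summed intensity of cell voxels whose (x, y) position falls
#' within \code{analysisRadius} of the bead centre, divided by the total
#' intensity over the cell.  Always in [0, 1] and non-decreasing in the
#' analysis radius.
#'
#' @param channel a \linkS4class{ChannelStack}
#' @param bead a \linkS4class{BeadROI}
#' @param cellMask a \linkS4class{BinaryStack} delimiting the cell
#' @return fraction in [0, 1]
#' @export
aroundBeadFraction <- function(channel, bead, cellMask) {
  stopifnot(is(channel, "ChannelStack"), is(bead, "BeadROI"),
            is(cellMask, "BinaryStack"))
  .checkVoxelMatch(channel, cellMask, "channel and cell mask")
  d <- dim(channel@data)
  vs <- channel@voxelSize
  a <- channel@data
  a[!cellMask@data] <- 0
  tot <- sum(a)
  if (tot <= 0) stop("zero total cell intensity: fraction undefined")
  xs <- .axisCoords(d[3L], vs["dx"][[1L]])
  ys <- .axisCoords(d[2L], vs["dy"][[1L]])
  disc <- outer((ys - bead@center[2L])^2, (xs - bead@center[1L])^2, "+") <=
    bead@analysisRadius^2
  inDisc <- aperm(array(disc, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  sum(a[inDisc]) / tot
}

#' Antigen remaining on the bead over a time course
#'
#' Quantifies bead-associated antigen fluorescence in a fixed area around
#' the bead on sum projections of each time point's z-stack, normalized to
#' 100 percent at time 0.  Antigen extraction at time t is
#' \code{100 - extractionRemaining(t)}.
#'
#' @param series named list of \linkS4class{Scene}s; time points are taken
#'   from each scene's \code{metadata$time}, else from the list names
#' @param antigenChannel channel holding the antigen label
#' @param bead a \linkS4class{BeadROI} defining the fixed area
#' @return data.frame with \code{time} and \code{percentRemaining},
#'   ordered by time; time 0 is 100 by construction
#' @export
extractionRemaining <- function(series, antigenChannel = "Ag", bead) {
  stopifnot(is.list(series), length(series) > 0L, is(bead, "BeadROI"))
  times <- vapply(seq_along(series), function(i) {
    tm <- series[[i]]@metadata$time
    if (!is.null(tm)) as.numeric(tm)
    else if (!is.null(names(series))) suppressWarnings(as.numeric(names(series)[i]))
    else NA_real_
  }, 0)
  if (anyNA(times)) stop("every scene needs a time point (metadata$time ",
                         "or a numeric list name)")
  if (!any(times == 0)) stop("the series must include time 0 for ",
                             "normalization")
  vals <- vapply(series, function(sc) {
    pr <- projectStack(getChannel(sc, antigenChannel), "sum")
    ps <- attr(pr, "pixelSize")
    xs <- .axisCoords(ncol(pr), ps["dx"][[1L]])
    ys <- .axisCoords(nrow(pr), ps["dy"][[1L]])
    disc <- outer((ys - bead@center[2L])^2, (xs - bead@center[1L])^2, "+") <=
      bead@analysisRadius^2
    sum(pr[disc])
  }, 0)
  base <- vals[which(times == 0)[1L]]
  if (base <= 0) stop("zero antigen intensity at time 0: cannot normalize")
  out <- data.frame(time = times, percentRemaining = 100 * vals / base)
  out[order(out$time), , drop = FALSE]
}

#' Spreading area at the synaptic plane
#'
#' Physical area enclosed by the cell outline at the synaptic plane:
#' pixel count times pixel area for a mask, shoelace area for a polygon.
#'
#' @param outline N x 2 polygon (x, y micrometres), a logical mask matrix,
#'   or a \linkS4class{SynapticPlane} (whose outline is used)
#' @param pixelSize \code{c(dy, dx)} micrometres; required for mask input
#' @return area in micrometres^2
#' @examples
#' spreadingArea(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))  # 4
#' @export
spreadingArea <- function(outline, pixelSize = NULL) {
  if (is(outline, "SynapticPlane")) {
    pixelSize <- outline@pixelSize
    outline <- outline@outline
  }
  if (is.matrix(outline) && is.logical(outline)) {
    if (!any(outline)) stop("empty outline mask")
    if (is.null(pixelSize)) stop("mask input requires pixelSize = c(dy, dx)")
    return(sum(outline) * pixelSize[1L] * pixelSize[2L])
  }
  if (is.matrix(outline) && ncol(outline) == 2L) {
    ar <- .polyArea(outline)
    if (ar <= 0) stop("degenerate outline polygon (zero area)")
    return(ar)
  }
  stop("outline must be a polygon matrix, logical mask, or SynapticPlane")
}

#' Central-vs-total recruitment index at the synapse
#'
#' Ratio of fluorescence density between a central region and the whole
#' cell outline at the synaptic plane, minus one.  The central region is
#' the outline scaled about its centroid to one quarter of the total area
#' (linear factor 0.5 for polygons; for raster masks the scale factor is
#' refined by bisection until the rasterized central region holds one
#' quarter of the outline pixels).  The index is 0 for a uniform
#' distribution, positive for central accumulation, negative (bounded
#' below by -1) for a peripheral distribution, and invariant to global
#' intensity scaling.
#'
#' @param image 2D intensity matrix \code{[y, x]}
#' @param outline N x 2 polygon (micrometres) or logical mask
#' @param pixelSize \code{c(dy, dx)}, micrometres
#' @param method \code{"ratio"} (default: density ratio - 1) or
#'   \code{"log"} (natural log of the density ratio)
#' @return signed scalar
#' @export
recruitmentIndex <- function(image, outline, pixelSize,
                             method = c("ratio", "log")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  dimyx <- dim(image)
  isMask <- is.logical(outline)
  if (isMask) {
    poly <- .maskContour(outline, pixelSize)
    if (is.null(poly)) stop("degenerate outline (empty mask)")
    wholeMask <- outline
  } else {
    poly <- outline
    if (.polyArea(poly) <= 0) stop("degenerate outline (zero area)")
    wholeMask <- .outlineMask(poly, dimyx, pixelSize)
  }
  nTot <- sum(wholeMask)
  fTot <- sum(image[wholeMask])
  if (fTot <= 0) stop("zero total intensity inside the outline")
  if (!isMask) {
    central <- .polyScale(poly, 0.5)
    aTot <- .polyArea(poly); aCen <- aTot / 4
    cenMask <- .outlineMask(central, dimyx, pixelSize) & wholeMask
    fCen <- sum(image[cenMask])
  } else {
    target <- nTot / 4
    loF <- 0.05; hiF <- 0.95
    cenMask <- NULL
    for (i in 1:30) {
      f <- (loF + hiF) / 2
      cenMask <- .outlineMask(.polyScale(poly, f), dimyx, pixelSize) & wholeMask
      nc <- sum(cenMask)
      if (abs(nc - target) < 0.5) break
      if (nc > target) hiF <- f else loF <- f
    }
    pxA <- pixelSize[1L] * pixelSize[2L]
    aTot <- nTot * pxA; aCen <- sum(cenMask) * pxA
    if (aCen <= 0) stop("central region collapsed to zero area")
    fCen <- sum(image[cenMask])
  }
  ratio <- (fCen / aCen) / (fTot / aTot)
  if (method == "ratio") ratio - 1 else log(ratio)
}

#' Circularity of a cell outline
#'
#' \code{4 * pi * area / perimeter^2}: 1 for a perfect circle, below 1 for
#' ruffled or elongated outlines.  Polygons use the shoelace area and
#' polygonal perimeter; raster masks use pixel-count area with the
#' perimeter measured on the smoothed marching-squares boundary contour.
#' A mask with more than one connected component is an error: pass the
#' largest component explicitly.
#'
#' @param x N x 2 polygon (micrometres) or a single-component logical mask
#' @param pixelSize \code{c(dy, dx)}, micrometres (mask input)
#' @return circularity, dimensionless
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1025)[-1025]
#' circularity(cbind(cos(th), sin(th)))  # ~1
#' @export
circularity <- function(x, pixelSize = NULL) {
  if (is.matrix(x) && is.logical(x)) {
    if (!any(x)) stop("empty mask")
    if (is.null(pixelSize)) stop("mask input requires pixelSize = c(dy, dx)")
    lab <- .labelComponents(array(x, c(1L, dim(x))),
                            .neighborOffsets(8L, linkZ = FALSE))
    if (max(lab) > 1L)
      stop("mask has ", max(lab), " connected components; circularity is ",
           "defined for one region - pass the largest component explicitly")
    A <- sum(x) * pixelSize[1L] * pixelSize[2L]
    poly <- .smoothPolygon(.maskContour(x, pixelSize))
    P <- .polyPerimeter(poly)
  } else if (is.matrix(x) && ncol(x) == 2L) {
    A <- .polyArea(x)
    P <- .polyPerimeter(x)
    if (A <= 0 || P <= 0) stop("degenerate polygon")
  } else stop("x must be a polygon matrix or a logical mask")
  4 * pi * A / P^2
}

#' Count discrete foci at the synaptic plane
#'
#' Thresholds a channel at the synaptic plane (restricted to the cell
#' outline) and counts particles within a physical area window - the
#' actin-focus counting procedure.
#'
#' @param plane a \linkS4class{SynapticPlane}
#' @param channel channel name
#' @param minArea,maxArea particle area window, micrometres^2 (inclusive)
#' @param thresholdMethod \code{"otsu"} or \code{"fixed"}
#' @param value threshold for \code{"fixed"}
#' @return integer focus count
#' @export
countFoci <- function(plane, channel, minArea = 0.10, maxArea = 4.00,
                      thresholdMethod = c("otsu", "fixed"), value = NULL) {
  stopifnot(is(plane, "SynapticPlane"))
  thresholdMethod <- match.arg(thresholdMethod)
  if (!channel %in% names(plane@images))
    stop("synaptic plane has no channel '", channel, "'")
  img <- plane@images[[channel]]
  msk <- .outlineMask(plane@outline, dim(img), plane@pixelSize)
  thr <- if (thresholdMethod == "fixed") {
    if (is.null(value)) stop("thresholdMethod = 'fixed' requires a value")
    value
  } else .otsuThreshold(img[msk])
  bin <- img > thr & msk
  nrow(filterParticles2D(bin, minArea, maxArea, plane@pixelSize))
}

#' Mean and integrated intensity over a region
#'
#' Per-cell intensity summary of a 2D projection or plane: integrated
#' intensity, per-pixel mean, region area and intensity density.
#'
#' @param image 2D intensity matrix \code{[y, x]}
#' @param mask logical matrix selecting the region (NULL: whole image)
#' @param pixelSize \code{c(dy, dx)}, micrometres
#' @return list with \code{integrated}, \code{mean} (per pixel),
#'   \code{area} (micrometres^2) and \code{density} (intensity per
#'   micrometre^2)
#' @export
intensitySummary <- function(image, mask = NULL, pixelSize) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("empty mask")
  vals <- image[mask]
  area <- sum(mask) * pixelSize[1L] * pixelSize[2L]
  list(integrated = sum(vals), mean = mean(vals), area = area,
       density = sum(vals) / area)
}
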