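#' Intensity-weighted centre of mass of a channel
#'
#' Centre of mass of the fluorescence of a channel, restricted to a mask,
#' in physical (x, y, z) micrometres.  The cell centre, by contrast, is
#' conventionally computed with uniform weights over the cell mask (see
#' \code{\link{maskCentroid}}).
#'
#' @param channel a \linkS4class{ChannelStack}
#' @param mask a \linkS4class{BinaryStack} restricting the computation, or
#'   \code{NULL} for the whole stack
#' @return numeric \code{c(x, y, z)} in micrometres
#' @examples
#' a <- array(0, c(3, 3, 3)); a[2, 2, 2] <- 7
#' centerOfMass(channelStack("Ag", a, c(0.5, 0.1, 0.1)))  # (0.1, 0.1, 0.5)
#' @export
centerOfMass <- function(channel, mask = NULL) {
  stopifnot(is(channel, "ChannelStack"))
  d <- dim(channel@data)
  vs <- channel@voxelSize
  if (is.null(mask)) {
    sel <- array(TRUE, d)
  } else {
    .checkVoxelMatch(channel, mask, "channel and mask")
    sel <- mask@data
    if (!any(sel)) stop("empty mask: no voxels to weight")
  }
  w <- channel@data
  w[!sel] <- 0
  tot <- sum(w)
  if (tot <= 0)
    stop("zero total intensity inside the mask; cannot form a centre of mass")
  idx <- which(sel & channel@data > 0, arr.ind = TRUE)
  ww <- channel@data[sel & channel@data > 0]
  c(x = sum(ww * (idx[, 3L] - 1)) * vs["dx"][[1L]] / tot,
    y = sum(ww * (idx[, 2L] - 1)) * vs["dy"][[1L]] / tot,
    z = sum(ww * (idx[, 1L] - 1)) * vs["dz"][[1L]] / tot)
}

#' Uniform-weight centroid of a binary mask
#'
#' @param mask a \linkS4class{BinaryStack}
#' @return numeric \code{c(x, y, z)} in micrometres
#' @export
maskCentroid <- function(mask) {
  stopifnot(is(mask, "BinaryStack"))
  if (!any(mask@data)) stop("empty mask: no voxels")
  vs <- mask@voxelSize
  idx <- which(mask@data, arr.ind = TRUE)
  c(x = mean(idx[, 3L] - 1) * vs["dx"][[1L]],
    y = mean(idx[, 2L] - 1) * vs["dy"][[1L]],
    z = mean(idx[, 1L] - 1) * vs["dz"][[1L]])
}

#' Construct the cell-bead polarity frame
#'
#' @param cellmc cell centre of mass (x, y, z), micrometres
#' @param beadmc bead centre of mass (x, y, z), micrometres
#' @return a \linkS4class{PolarityFrame}
#' @export
polarityFrame <- function(cellmc, beadmc) {
  cellmc <- as.numeric(cellmc); beadmc <- as.numeric(beadmc)
  stopifnot(length(cellmc) == 3L, length(beadmc) == 3L)
  v <- beadmc - cellmc
  len <- sqrt(sum(v^2))
  if (!is.finite(len) || len <= 0)
    stop("degenerate axis: bead centre equals cell centre, ",
         "no polarity index can be reported")
  new("PolarityFrame", cellmc = cellmc, beadmc = beadmc, axis = v / len,
      axisLength = len)
}

#' Signed polarity index of a label along the cell-bead axis
#'
#' The label's centre of mass is projected onto the axis from the cell
#' centre of mass to the bead centre of mass; the index is the signed
#' projection length divided by the axis length.  It is +1 when the label
#' centre coincides with the bead centre (fully polarized), 0 at the cell
#' centre, and -1 at the mirror point of the bead through the cell centre
#' (anti-polarized).  Raw values outside [-1, +1] (label beyond the bead
#' along the axis) are clamped and flagged.
#'
#' @param frame a \linkS4class{PolarityFrame}
#' @param labelCm the label's centre of mass (x, y, z), micrometres
#' @param label channel name recorded on the result
#' @return a \linkS4class{PolarityIndex}
#' @examples
#' fr <- polarityFrame(c(0, 0, 0), c(4, 0, 0))
#' indexValue(polarityIndex(fr, c(2, 2, 0)))  # 0.5
#' @export
polarityIndex <- function(frame, labelCm, label = "label") {
  stopifnot(is(frame, "PolarityFrame"))
  labelCm <- as.numeric(labelCm)
  stopifnot(length(labelCm) == 3L)
  proj <- sum((labelCm - frame@cellmc) * frame@axis)
  pm <- frame@cellmc + proj * frame@axis
  raw <- proj / frame@axisLength
  clamped <- raw < -1 || raw > 1
  new("PolarityIndex", value = max(-1, min(1, raw)), label = label,
      projected = c(x = pm[1L], y = pm[2L], z = pm[3L]), clamped = clamped)
}

#' Polarity index of a scene channel
#'
#' Convenience wrapper for whole scenes: the cell centre is the
#' uniform-weight centroid of the cell mask, the bead centre comes from
#' the bead geometry, and the label centre is the fluorescence centre of
#' mass of the channel inside the cell mask.
#'
#' @param x a \linkS4class{Scene} with a cell mask and at least one bead
#' @param channel channel name
#' @param bead which bead to use (row of \code{beads(x)})
#' @return a \linkS4class{PolarityIndex}
#' @export
scenePolarity <- function(x, channel, bead = 1L) {
  stopifnot(is(x, "Scene"))
  if (is.null(x@cellMask)) stop("scene has no cell mask")
  if (nrow(x@beads) < bead) stop("scene has no bead ", bead)
  fr <- polarityFrame(maskCentroid(x@cellMask),
                      unlist(x@beads[bead, c("x", "y", "z")]))
  cm <- centerOfMass(getChannel(x, channel), x@cellMask)
  polarityIndex(fr, cm, label = channel)
}
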