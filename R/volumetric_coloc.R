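#' Construct a VoxelModel
#'
#' A binary 3D marker model, as produced by z-slice stacking of segmented
#' images.  \code{asVoxelModel} promotes a segmentation result.
#'
#' @param binary a \linkS4class{BinaryStack}
#' @param marker marker name
#' @return a \linkS4class{VoxelModel}
#' @export
asVoxelModel <- function(binary, marker) {
  stopifnot(is(binary, "BinaryStack"))
  new("VoxelModel", data = binary@data, voxelSize = binary@voxelSize,
      provenance = binary@provenance, marker = marker)
}

#' @rdname accessors
setMethod("volume", "VoxelModel", function(x) sum(x@data) * prod(x@voxelSize))

#' Voxel-level intersection of two marker models
#'
#' Voxelwise logical AND of two \linkS4class{VoxelModel}s sharing geometry;
#' the marker of the result records both parents.  Intersection is
#' commutative and associative, and the intersection volume never exceeds
#' either parent volume.
#'
#' @param x,y \linkS4class{VoxelModel}s of identical shape and voxel size
#' @return a \linkS4class{VoxelModel}
#' @examples
#' a <- array(TRUE, c(2, 3, 3))
#' m <- asVoxelModel(binaryStack(a, c(0.5, 0.1, 0.1)), "LAMP1")
#' volume(intersect(m, m)) == volume(m)
#' @aliases intersect,VoxelModel,VoxelModel-method
#' @export
setMethod("intersect", signature("VoxelModel", "VoxelModel"), function(x, y) {
  .checkVoxelMatch(x, y, "voxel models")
  new("VoxelModel", data = x@data & y@data, voxelSize = x@voxelSize,
      provenance = list(operation = "intersection",
                        parents = c(x@marker, y@marker)),
      marker = paste(x@marker, y@marker, sep = "&"))
})

#' Select compartments containing a marker
#'
#' All-or-nothing selection: a component of the parent labelling is
#' selected iff at least \code{minOverlap} of its voxels intersect the
#' marker model (default 1: any contact selects, regardless of the amount
#' of marker), and its whole volume then counts toward the selected
#' volume.  Enlarging the marker model never deselects a component.
#'
#' @param comps \linkS4class{LabeledComponents} (e.g. LAMP1 compartments)
#' @param marker a \linkS4class{VoxelModel} (e.g. the antigen model)
#' @param minOverlap minimum overlapping voxels for selection (default 1)
#' @return a \linkS4class{CompartmentSelection}; its \code{fraction} is
#'   the selected volume as percent of the parent volume (NA when the
#'   parent is empty)
#' @export
selectCompartmentsContaining <- function(comps, marker, minOverlap = 1L) {
  stopifnot(is(comps, "LabeledComponents"), is(marker, "VoxelModel"),
            minOverlap >= 1L)
  if (!identical(dim(comps@labels), dim(marker@data)))
    stop("components and marker model must share one shape")
  if (any(abs(comps@voxelSize - marker@voxelSize) > 1e-9))
    stop("components and marker model must share one voxel size")
  k <- nrow(comps@table)
  ov <- tabulate(comps@labels[marker@data], nbins = k)
  sel <- which(ov >= minOverlap)
  selVol <- sum(comps@table$volume[match(sel, comps@table$id)])
  refVol <- sum(comps@table$volume)
  new("CompartmentSelection", parentTable = comps@table,
      selectedIds = as.integer(sel), selectedVolume = selVol,
      referenceVolume = refVol,
      fraction = if (refVol > 0) 100 * selVol / refVol else NA_real_,
      marker = marker@marker)
}

#' Nested marker-containment percentages of a compartment population
#'
#' The two-step compartment-selection readout: (i) the volume of
#' compartments containing \code{marker1} (e.g. LAMP1+Ag+) as a percent of
#' the total compartment volume (LAMP1+); (ii) the voxel volume of the
#' \code{marker1}-selected compartments intersected with \code{marker2}
#' (LAMP1+Ag+SNX5+) as a percent of the whole population's intersection
#' with \code{marker2} (LAMP1+SNX5+).  A zero denominator yields a flagged
#' \code{NA}, never 0.
#'
#' @param comps \linkS4class{LabeledComponents}
#' @param marker1,marker2 \linkS4class{VoxelModel}s sharing the geometry
#' @param minOverlap voxels required for selection (default 1)
#' @return list with \code{primaryPercent}, \code{nestedPercent},
#'   \code{undefined} (character vector naming any undefined percents) and
#'   the selection object as \code{selection}
#' @export
nestedFraction <- function(comps, marker1, marker2, minOverlap = 1L) {
  stopifnot(is(comps, "LabeledComponents"))
  sel <- selectCompartmentsContaining(comps, marker1, minOverlap)
  undef <- character()
  primary <- sel@fraction
  if (is.na(primary)) undef <- c(undef, "primaryPercent")
  vv <- prod(comps@voxelSize)
  selMask <- array(comps@labels > 0 &
                     array(comps@labels %in% sel@selectedIds,
                           dim(comps@labels)), dim(comps@labels))
  allInter <- sum(comps@labels > 0 & marker2@data) * vv
  selInter <- sum(selMask & marker2@data) * vv
  nested <- if (allInter > 0) 100 * selInter / allInter else NA_real_
  if (is.na(nested)) undef <- c(undef, "nestedPercent")
  list(primaryPercent = primary, nestedPercent = nested, undefined = undef,
       selection = sel)
}

#' Volume-binned distribution of compartment volumes
#'
#' Per-cell percentage of total compartment volume falling in each volume
#' bin.  With the default edges \code{c(6, 12)} micrometres^3 the bins are
#' \code{[0, 6)}, \code{[6, 12]} and \code{(12, Inf)}; the boundary
#' convention is attached as attribute \code{convention}.  Percentages sum
#' to 100.
#'
#' @param comps \linkS4class{LabeledComponents}
#' @param edges strictly increasing bin edges, micrometres^3
#' @return named numeric of per-bin percentages (all NA, with attribute
#'   \code{undefined}, when there are no components)
#' @export
binVolumes <- function(comps, edges = c(6, 12)) {
  stopifnot(is(comps, "LabeledComponents"), length(edges) >= 1L)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing")
  k <- length(edges)
  labs <- c(paste0("<", edges[1L]),
            if (k > 1L) paste0(edges[-k], "-", edges[-1L]),
            paste0(">", edges[k]))
  v <- comps@table$volume
  out <- stats::setNames(rep(NA_real_, k + 1L), labs)
  attr(out, "convention") <- "[0,e1), [e_i,e_{i+1}] closed, (e_k,Inf)"
  if (!length(v)) {
    attr(out, "undefined") <- TRUE
    return(out)
  }
  binOf <- function(x) {
    if (x < edges[1L]) return(1L)
    for (i in seq_len(k - 1L)) if (x >= edges[i] && x <= edges[i + 1L])
      return(i + 1L)
    k + 1L
  }
  b <- vapply(v, binOf, 0L)
  tot <- sum(v)
  for (i in seq_len(k + 1L)) out[i] <- 100 * sum(v[b == i]) / tot
  attr(out, "convention") <- "[0,e1), [e_i,e_{i+1}] closed, (e_k,Inf)"
  out
}

#' Number of 3D compartments
#'
#' @param comps \linkS4class{LabeledComponents}
#' @return integer component count
#' @export
countComponents <- function(comps) {
  stopifnot(is(comps, "LabeledComponents"))
  nrow(comps@table)
}

#' Pearson colocalization over a cell z-stack
#'
#' Sample Pearson correlation of paired voxel intensities of two channels
#' over the whole masked z-stack.
#'
#' @param a,b \linkS4class{ChannelStack}s sharing geometry
#' @param mask optional \linkS4class{BinaryStack} restricting the voxels
#' @return correlation coefficient in [-1, 1]
#' @export
pearsonColoc <- function(a, b, mask = NULL) {
  stopifnot(is(a, "ChannelStack"), is(b, "ChannelStack"))
  .checkVoxelMatch(a, b, "channels")
  sel <- if (is.null(mask)) TRUE else {
    .checkVoxelMatch(a, mask, "channel and mask")
    mask@data
  }
  va <- a@data[sel]; vb <- b@data[sel]
  if (length(va) < 2L) stop("need at least 2 masked voxels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in a channel: correlation undefined")
  stats::cor(va, vb)
}

#' Manders M1 coefficient over a reference label
#'
#' Fraction of a channel's integrated intensity that falls inside the
#' binary reference label (e.g. SNX5 intensity over the LAMP1 model),
#' within the analysis mask.  Invariant to uniform rescaling of the
#' intensity channel; in [0, 1].
#'
#' @param intensity a \linkS4class{ChannelStack}
#' @param reference a \linkS4class{VoxelModel} (the label region)
#' @param mask optional \linkS4class{BinaryStack} analysis region
#' @return M1 in [0, 1]
#' @export
mandersM1 <- function(intensity, reference, mask = NULL) {
  stopifnot(is(intensity, "ChannelStack"), is(reference, "VoxelModel"))
  .checkVoxelMatch(intensity, reference, "channel and reference")
  sel <- if (is.null(mask)) array(TRUE, dim(intensity@data)) else {
    .checkVoxelMatch(intensity, mask, "channel and mask")
    mask@data
  }
  tot <- sum(intensity@data[sel])
  if (tot <= 0) stop("zero total intensity in the mask: M1 undefined")
  sum(intensity@data[sel & reference@data]) / tot
}

#' Bundle Pearson and Manders coefficients for a channel pair
#'
#' @param a,b \linkS4class{ChannelStack}s (M1 measures \code{a} over the
#'   reference)
#' @param reference \linkS4class{VoxelModel} reference label for M1
#' @param mask optional \linkS4class{BinaryStack}
#' @return a \linkS4class{ColocCoefficients}
#' @export
colocCoefficients <- function(a, b, reference, mask = NULL) {
  n <- if (is.null(mask)) length(a@data) else sum(mask@data)
  r <- tryCatch(pearsonColoc(a, b, mask), error = function(e) NA_real_)
  m1 <- tryCatch(mandersM1(a, reference, mask), error = function(e) NA_real_)
  new("ColocCoefficients", pearson = r, mandersM1 = m1,
      nVoxels = as.integer(n))
}
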