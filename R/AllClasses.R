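#' @import methods
NULL

## Conventions used throughout:
##  * arrays are indexed [z, y, x]; dim(data) = c(nz, ny, nx)
##  * voxelSize is a named numeric c(dz, dy, dx) in micrometres
##  * physical coordinates are reported (x, y, z) in micrometres, 0-based:
##    the centre of voxel [iz, iy, ix] (1-based R indices) is
##    ((ix-1)*dx, (iy-1)*dy, (iz-1)*dz)
##  * anisotropy is carried, never resampled: volume = count * dz*dy*dx,
##    in-plane area = count * dy*dx

#' ChannelStack: one fluorescence channel as a 3D intensity grid
#'
#' Holds a single channel of a multi-channel z-stack as a non-negative
#' 3D intensity array indexed \code{[z, y, x]}, together with the physical
#' voxel size \code{c(dz, dy, dx)} in micrometres.
#'
#' @slot name channel label, e.g. \code{"LAMP1"}, \code{"SNX5"}, \code{"Ag"}
#' @slot data 3D numeric array of non-negative intensities, \code{[z, y, x]}
#' @slot voxelSize named numeric \code{c(dz, dy, dx)}, micrometres, all > 0
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(name = "character", data = "array", voxelSize = "numeric"))

setValidity("ChannelStack", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "'data' must be a 3D array indexed [z, y, x]")
  if (anyNA(object@data) || any(object@data < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values c(dz, dy, dx)")
  if (length(msg)) msg else TRUE
})

#' BinaryStack: a 3D boolean mask with provenance
#'
#' Result of segmenting a \linkS4class{ChannelStack} (or a user-supplied
#' mask): a logical grid of the same shape, the voxel size, and a record of
#' how it was produced.
#'
#' @slot data 3D logical array \code{[z, y, x]}
#' @slot voxelSize named numeric \code{c(dz, dy, dx)} in micrometres
#' @slot provenance list describing the source channel and method
#' @exportClass BinaryStack
setClass("BinaryStack",
  representation(data = "array", voxelSize = "numeric", provenance = "list"),
  prototype(provenance = list()))

setValidity("BinaryStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "'data' must be a 3D logical array")
  if (anyNA(object@data))
    msg <- c(msg, "'data' must not contain NA")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values c(dz, dy, dx)")
  if (length(msg)) msg else TRUE
})

#' VoxelModel: binary 3D model of one marker
#'
#' A \linkS4class{BinaryStack} tagged with the marker it models.  Voxel
#' models support voxel-wise intersection (\code{intersect}) and drive
#' compartment selection; their volume is the true-voxel count times the
#' voxel volume.
#'
#' @slot marker marker name; intersections concatenate parent names
#' @exportClass VoxelModel
setClass("VoxelModel", contains = "BinaryStack",
  representation(marker = "character"))

setValidity("VoxelModel", function(object) {
  if (length(object@marker) != 1L || !nzchar(object@marker))
    "'marker' must be a single non-empty string" else TRUE
})

#' Scene: co-registered channels, bead geometry, masks and ground truth
#'
#' The unit of analysis: a set of \linkS4class{ChannelStack}s sharing shape
#' and voxel size, the bead(s) in physical coordinates, an optional cell
#' mask, free-form metadata (condition, time point) and, for synthetic
#' scenes only, a \linkS4class{SceneGroundTruth}.
#'
#' @slot channels named list of \linkS4class{ChannelStack}
#' @slot beads data.frame with columns \code{x, y, z, radius} (micrometres)
#' @slot cellMask a \linkS4class{BinaryStack} or \code{NULL}
#' @slot metadata list (e.g. \code{condition}, \code{time})
#' @slot groundTruth \linkS4class{SceneGroundTruth} or \code{NULL}
#' @exportClass Scene
setClass("Scene",
  representation(channels = "list", beads = "data.frame", cellMask = "ANY",
                 metadata = "list", groundTruth = "ANY"),
  prototype(metadata = list(), cellMask = NULL, groundTruth = NULL))

setValidity("Scene", function(object) {
  msg <- character()
  ch <- object@channels
  if (!length(ch) || !all(vapply(ch, is, TRUE, "ChannelStack")))
    msg <- c(msg, "'channels' must be a non-empty list of ChannelStack")
  else {
    nms <- unname(vapply(ch, function(x) x@name, ""))
    if (anyDuplicated(nms))
      msg <- c(msg, "channel names must be unique")
    if (is.null(names(ch)) || !identical(names(ch), nms))
      msg <- c(msg, "'channels' must be named by channel name")
    dims <- vapply(ch, function(x) dim(x@data), integer(3))
    if (length(ch) > 1L && any(dims != dims[, 1L]))
      msg <- c(msg, "all channels must share one shape")
    vs <- vapply(ch, function(x) x@voxelSize, numeric(3))
    if (length(ch) > 1L && any(abs(vs - vs[, 1L]) > 1e-9))
      msg <- c(msg, "all channels must share one voxel size")
    if (!is.null(object@cellMask)) {
      if (!is(object@cellMask, "BinaryStack"))
        msg <- c(msg, "'cellMask' must be a BinaryStack or NULL")
      else if (!identical(dim(object@cellMask@data), dim(ch[[1L]]@data)))
        msg <- c(msg, "'cellMask' shape must match the channels")
    }
  }
  bd <- object@beads
  if (nrow(bd)) {
    if (!all(c("x", "y", "z", "radius") %in% names(bd)))
      msg <- c(msg, "'beads' needs columns x, y, z, radius")
    else if (any(bd$radius <= 0))
      msg <- c(msg, "bead radius must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' SceneSpec: parameters of the synthetic-scene generator
#'
#' Describes one synthetic B-cell/bead scene: an ellipsoidal cell, an
#' antigen-coated bead docked on its surface, and spherical labelled
#' compartments whose placement is polarized toward the bead with
#' controllable strength.  See \code{\link{sceneSpec}} for defaults and
#' units.
#'
#' @slot cellSemiAxes ellipsoid semi-axes \code{c(ax, ay, az)} micrometres
#' @slot beadRadius bead radius, micrometres (default 1.5: a 3-micron bead)
#' @slot beadDirection unit vector from cell centre toward the bead (x, y, z)
#' @slot nCompartments number of labelled compartments
#' @slot radiusMean,radiusSd compartment radius distribution, micrometres
#' @slot polarization p in [0, 1]: fraction of compartments drawn from the
#'   bead-directed angular kernel rather than uniformly in the cell
#' @slot kappa concentration of the von Mises-Fisher angular kernel
#' @slot markerTable named numeric: per-channel probability that a
#'   compartment carries that marker
#' @slot psfSigma Gaussian PSF sigma \code{c(lateral, axial)}, micrometres
#' @slot poissonScale photon scaling for shot noise (0 disables)
#' @slot gaussianSd additive Gaussian read-noise sd (0 disables)
#' @slot beadAntigen amplitude of the bead-surface antigen shell rendered
#'   into the \code{"Ag"} channel (0 disables)
#' @slot voxelSize c(dz, dy, dx), micrometres
#' @slot margin clear margin between objects and the grid border, micrometres
#' @slot seed integer RNG seed driving the single generator stream
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(cellSemiAxes = "numeric", beadRadius = "numeric",
                 beadDirection = "numeric", nCompartments = "integer",
                 radiusMean = "numeric", radiusSd = "numeric",
                 polarization = "numeric", kappa = "numeric",
                 markerTable = "numeric", psfSigma = "numeric",
                 poissonScale = "numeric", gaussianSd = "numeric",
                 beadAntigen = "numeric", voxelSize = "numeric",
                 margin = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@cellSemiAxes) != 3L || any(object@cellSemiAxes <= 0))
    msg <- c(msg, "'cellSemiAxes' must be 3 positive lengths")
  if (object@beadRadius <= 0) msg <- c(msg, "'beadRadius' must be > 0")
  if (object@nCompartments < 0L) msg <- c(msg, "'nCompartments' must be >= 0")
  if (object@polarization < 0 || object@polarization > 1)
    msg <- c(msg, "'polarization' must lie in [0, 1]")
  if (!length(object@markerTable) || is.null(names(object@markerTable)) ||
      any(object@markerTable < 0) || any(object@markerTable > 1))
    msg <- c(msg, "'markerTable' must be named probabilities in [0, 1]")
  if (object@radiusMean <= 0) msg <- c(msg, "'radiusMean' must be > 0")
  if (object@radiusSd < 0) msg <- c(msg, "'radiusSd' must be >= 0")
  if (length(object@psfSigma) != 2L || any(object@psfSigma < 0))
    msg <- c(msg, "'psfSigma' must be c(lateral, axial) >= 0")
  if (object@poissonScale < 0 || object@gaussianSd < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values c(dz, dy, dx)")
  if (length(msg)) msg else TRUE
})

#' SceneGroundTruth: analytic truth attached to a synthetic Scene
#'
#' Pre-noise geometry of a generated scene: per-compartment centres, radii,
#' volumes and marker membership; per-channel fluorescence centres of mass
#' and the polarity index they imply; and the voxelized pre-blur marker
#' models from which true overlap volumes are counted.
#'
#' @slot compartments data.frame: id, x, y, z, radius, volume and one
#'   logical column per marker (compartments with no marker are flagged
#'   \code{unlabeled})
#' @slot labelCoM matrix, one row (x, y, z) per channel
#' @slot expectedPI named numeric, analytic polarity index per channel
#' @slot models named list of pre-blur \linkS4class{VoxelModel}
#' @slot cellCenter,beadCenter physical points (x, y, z), micrometres
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth",
  representation(compartments = "data.frame", labelCoM = "matrix",
                 expectedPI = "numeric", models = "list",
                 cellCenter = "numeric", beadCenter = "numeric"))

#' LabeledComponents: 3D connected compartments of a binary model
#'
#' Output of \code{\link{linkRoi3d}}: a label image plus a per-component
#' table.  Components are 8-connected in-plane and linked across
#' consecutive z-slices by face adjacency; ids are sorted by size,
#' largest first.
#'
#' @slot labels 3D integer array; 0 = background, k = component id
#' @slot voxelSize named numeric \code{c(dz, dy, dx)}
#' @slot table data.frame: id, nVoxels, volume (micrometres^3), centroid
#'   \code{cx, cy, cz} (micrometres), bounding box, slice extent
#' @exportClass LabeledComponents
setClass("LabeledComponents",
  representation(labels = "array", voxelSize = "numeric", table = "data.frame"))

setValidity("LabeledComponents", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "'labels' must be a 3D array")
  tb <- object@table
  if (nrow(tb)) {
    if (is.unsorted(rev(tb$nVoxels)) && is.unsorted(-tb$nVoxels))
      msg <- c(msg, "components must be sorted by size, largest first")
    vv <- prod(object@voxelSize)
    if (any(abs(tb$volume - tb$nVoxels * vv) > 1e-9 * pmax(1, tb$volume)))
      msg <- c(msg, "volume must equal voxel count times voxel volume")
  }
  if (length(msg)) msg else TRUE
})

#' CompartmentSelection: all-or-nothing selection of compartments by a marker
#'
#' Result of \code{\link{selectCompartmentsContaining}}: which components
#' of a parent labelling intersect a marker model (by at least
#' \code{minOverlap} voxels), the volume they jointly carry, and that
#' volume as a percentage of the parent volume.
#'
#' @slot parentTable the parent component table
#' @slot selectedIds integer ids of selected components
#' @slot selectedVolume,referenceVolume micrometres^3
#' @slot fraction selected/reference as percent in [0, 100]
#' @slot marker marker model name used for selection
#' @exportClass CompartmentSelection
setClass("CompartmentSelection",
  representation(parentTable = "data.frame", selectedIds = "integer",
                 selectedVolume = "numeric", referenceVolume = "numeric",
                 fraction = "numeric", marker = "character"))

setValidity("CompartmentSelection", function(object) {
  msg <- character()
  if (!all(object@selectedIds %in% object@parentTable$id))
    msg <- c(msg, "'selectedIds' must be a subset of parent ids")
  if (!is.na(object@fraction) &&
      (object@fraction < -1e-9 || object@fraction > 100 + 1e-9))
    msg <- c(msg, "'fraction' must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' ColocCoefficients: intensity-based colocalization of two channels
#'
#' @slot pearson sample Pearson correlation of paired voxel intensities
#'   over the analysis mask, in [-1, 1] (NA when undefined)
#' @slot mandersM1 fraction of one channel's integrated intensity falling
#'   inside the reference label, in [0, 1] (NA when undefined)
#' @slot nVoxels number of voxels considered
#' @exportClass ColocCoefficients
setClass("ColocCoefficients",
  representation(pearson = "numeric", mandersM1 = "numeric",
                 nVoxels = "integer"))

#' PolarityFrame: the cell-bead reference axis
#'
#' The frame in which polarity indexes are measured: cell centre of mass,
#' bead centre of mass, the unit axis from cell to bead, and its length.
#'
#' @slot cellmc,beadmc physical points (x, y, z), micrometres
#' @slot axis unit vector cellmc -> beadmc
#' @slot axisLength |beadmc - cellmc|, micrometres, > 0
#' @exportClass PolarityFrame
setClass("PolarityFrame",
  representation(cellmc = "numeric", beadmc = "numeric", axis = "numeric",
                 axisLength = "numeric"))

setValidity("PolarityFrame", function(object) {
  if (!is.finite(object@axisLength) || object@axisLength <= 0)
    "'axisLength' must be > 0 (cell and bead centres must differ)" else TRUE
})

#' PolarityIndex: signed polarity of one label along the cell-bead axis
#'
#' @slot value index in [-1, +1]: +1 fully polarized (label at the bead),
#'   0 at the cell centre, -1 anti-polarized
#' @slot label channel name
#' @slot projected the projection of the label centre onto the axis (x, y, z)
#' @slot clamped TRUE when the raw value fell outside [-1, 1] and was clamped
#' @exportClass PolarityIndex
setClass("PolarityIndex",
  representation(value = "numeric", label = "character",
                 projected = "numeric", clamped = "logical"))

#' BeadROI: the around-bead analysis disc
#'
#' In-plane region used for around-bead accumulation and antigen-extraction
#' measurements: a disc concentric with the bead.  The default analysis
#' radius is 3.5 micrometres, fully containing a 3-micron bead plus a
#' docking rim.
#'
#' @slot center bead centre (x, y), micrometres
#' @slot beadRadius micrometres, > 0
#' @slot analysisRadius micrometres, >= beadRadius
#' @exportClass BeadROI
setClass("BeadROI",
  representation(center = "numeric", beadRadius = "numeric",
                 analysisRadius = "numeric"))

setValidity("BeadROI", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "'center' must be (x, y)")
  if (object@beadRadius <= 0) msg <- c(msg, "'beadRadius' must be > 0")
  if (object@analysisRadius < object@beadRadius)
    msg <- c(msg, "'analysisRadius' must be >= 'beadRadius'")
  if (length(msg)) msg else TRUE
})

#' SynapticPlane: the z-slice at the immune synapse
#'
#' Carries the 2D images of each channel at the synaptic plane, the cell
#' outline there (a polygon in micrometres or a logical mask), and the
#' in-plane pixel size.
#'
#' @slot zIndex 1-based slice index in the source stack
#' @slot images named list of 2D matrices [y, x]
#' @slot outline N x 2 polygon (x, y in micrometres) or a logical matrix
#' @slot pixelSize named numeric \code{c(dy, dx)}, micrometres
#' @exportClass SynapticPlane
setClass("SynapticPlane",
  representation(zIndex = "integer", images = "list", outline = "ANY",
                 pixelSize = "numeric"))

setValidity("SynapticPlane", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "'pixelSize' must be 2 positive values c(dy, dx)")
  ol <- object@outline
  if (is.matrix(ol) && is.logical(ol)) {
    if (!any(ol)) msg <- c(msg, "'outline' mask must be non-empty")
  } else if (is.matrix(ol) && is.numeric(ol)) {
    if (ncol(ol) != 2L || nrow(ol) < 3L)
      msg <- c(msg, "'outline' polygon must be an N x 2 matrix, N >= 3")
  } else msg <- c(msg, "'outline' must be a polygon matrix or logical mask")
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: validated configuration of the quantification pipeline
#'
#' Every tunable of the pipeline in one validated object, serialisable to
#' YAML: scene source (synthetic cohort or directory of stored scenes),
#' channel roles, segmentation settings, the around-bead analysis radius,
#' particle-size bounds, volume-bin edges, synaptic-plane selection and the
#' seed.  See \code{\link{pipelineConfig}}.
#'
#' @slot mode \code{"generate"} or \code{"load"}
#' @slot nScenes number of synthetic scenes (generate mode)
#' @slot sceneSpec \linkS4class{SceneSpec} template (generate mode)
#' @slot sceneDir directory of stored scenes (load mode)
#' @slot channels list: \code{lysosome}, \code{antigen}, \code{nested},
#'   \code{actin} channel names (NULL disables the dependent metrics)
#' @slot threshold list: \code{method} ("otsu"/"fixed"), \code{value},
#'   \code{perSlice}, \code{erodeIterations}
#' @slot analysisRadius around-bead disc radius, micrometres (default 3.5)
#' @slot particleBounds in-plane particle area window, micrometres^2
#'   (default c(0.10, 4.00))
#' @slot binEdges volume bin edges, micrometres^3 (default c(6, 12))
#' @slot minOverlap voxels required for compartment selection (default 1)
#' @slot synapticPlane \code{"actin-max"} or an explicit z index
#' @slot backgroundOffset constant offset subtracted from intensities
#'   before quantification (default 0: none)
#' @slot seed integer seed
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(mode = "character", nScenes = "integer", sceneSpec = "ANY",
                 sceneDir = "character", channels = "list",
                 threshold = "list", analysisRadius = "numeric",
                 particleBounds = "numeric", binEdges = "numeric",
                 minOverlap = "integer", synapticPlane = "ANY",
                 backgroundOffset = "numeric", seed = "integer"))
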