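#' Accessors for SynapseQuant objects
#'
#' Small read-only accessors: \code{voxelSize} returns the physical voxel
#' size \code{c(dz, dy, dx)} in micrometres; \code{stackData} the raw 3D
#' array; \code{channelNames}/\code{getChannel} address the channels of a
#' \linkS4class{Scene}; \code{beads}, \code{cellMask} and
#' \code{groundTruth} return the remaining Scene members; \code{volume}
#' the physical volume of a \linkS4class{VoxelModel} or the total volume of
#' \linkS4class{LabeledComponents}; \code{componentTable} the per-component
#' table; \code{indexValue} the scalar of a \linkS4class{PolarityIndex}.
#'
#' @param x the object
#' @param name a channel name
#' @return see the description per accessor
#' @name accessors
#' @aliases voxelSize stackData channelNames getChannel beads cellMask
#'   groundTruth volume componentTable indexValue
#' @examples
#' cs <- channelStack("LAMP1", array(0, c(2, 4, 4)), c(0.5, 0.1, 0.1))
#' voxelSize(cs)
NULL

#' @rdname accessors
setMethod("voxelSize", "ChannelStack", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "BinaryStack", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "LabeledComponents", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "Scene", function(x) x@channels[[1L]]@voxelSize)

#' @rdname accessors
setMethod("stackData", "ChannelStack", function(x) x@data)
#' @rdname accessors
setMethod("stackData", "BinaryStack", function(x) x@data)

#' @rdname accessors
setMethod("channelNames", "Scene", function(x) names(x@channels))

#' @rdname accessors
setMethod("getChannel", "Scene", function(x, name) {
  if (!name %in% names(x@channels))
    stop("scene has no channel '", name, "' (channels: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

#' @rdname accessors
setMethod("beads", "Scene", function(x) x@beads)
#' @rdname accessors
setMethod("cellMask", "Scene", function(x) x@cellMask)
#' @rdname accessors
setMethod("groundTruth", "Scene", function(x) x@groundTruth)

#' @rdname accessors
setMethod("volume", "BinaryStack", function(x)
  sum(x@data) * prod(x@voxelSize))
#' @rdname accessors
setMethod("volume", "LabeledComponents", function(x) sum(x@table$volume))

#' @rdname accessors
setMethod("componentTable", "LabeledComponents", function(x) x@table)

#' @rdname accessors
setMethod("indexValue", "PolarityIndex", function(x) x@value)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChannelStack '%s': %d x %d x %d [z,y,x], voxel %s um\n",
              object@name, d[1], d[2], d[3],
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d [z,y,x], %d true voxels (%.3g um^3)\n",
              class(object), d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@voxelSize)))
  if (is(object, "VoxelModel"))
    cat("  marker:", object@marker, "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance),
        vapply(object@provenance, function(p) paste(format(p), collapse = "/"), ""),
        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@channels[[1L]]@data)
  cat(sprintf("Scene: %d channel(s) [%s], %d x %d x %d [z,y,x]\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "), d[1], d[2], d[3]))
  cat(sprintf("  voxel %s um, %d bead(s)%s%s\n",
              paste(signif(voxelSize(object), 3), collapse = " x "),
              nrow(object@beads),
              if (is.null(object@cellMask)) "" else ", cell mask",
              if (is.null(object@groundTruth)) "" else ", ground truth"))
})

setMethod("show", "LabeledComponents", function(object) {
  cat(sprintf("LabeledComponents: %d component(s), total volume %.4g um^3\n",
              nrow(object@table), sum(object@table$volume)))
  if (nrow(object@table))
    print(utils::head(object@table, 5L))
})

setMethod("show", "CompartmentSelection", function(object) {
  cat(sprintf(
    "CompartmentSelection by '%s': %d/%d components, %.4g/%.4g um^3 (%s%%)\n",
    object@marker, length(object@selectedIds), nrow(object@parentTable),
    object@selectedVolume, object@referenceVolume,
    format(signif(object@fraction, 4))))
})

setMethod("show", "PolarityIndex", function(object) {
  cat(sprintf("PolarityIndex '%s': %.4f%s\n", object@label, object@value,
              if (object@clamped) " (clamped)" else ""))
})

setMethod("show", "ColocCoefficients", function(object) {
  cat(sprintf("ColocCoefficients: Pearson r = %s, Manders M1 = %s (n = %d)\n",
              format(signif(object@pearson, 4)),
              format(signif(object@mandersM1, 4)), object@nVoxels))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: cell %s um, bead r=%.2g um, n=%d compartments, p=%.2f\n",
    paste(signif(object@cellSemiAxes, 3), collapse = " x "),
    object@beadRadius, object@nCompartments, object@polarization))
  cat(sprintf("  markers: %s; psf %s um; noise (poisson %.3g, gauss %.3g); seed %d\n",
              paste(names(object@markerTable), signif(object@markerTable, 2),
                    sep = ":", collapse = ", "),
              paste(signif(object@psfSigma, 2), collapse = "/"),
              object@poissonScale, object@gaussianSd, object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: mode '%s', %s, seed %d\n", object@mode,
              if (object@mode == "generate")
                sprintf("%d synthetic scene(s)", object@nScenes)
              else sprintf("scenes from '%s'", object@sceneDir),
              object@seed))
})
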