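#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname accessors
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
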