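#' Construct a ChannelStack
#'
#' @param name channel label (e.g. \code{"LAMP1"})
#' @param data 3D non-negative numeric array indexed \code{[z, y, x]}
#' @param voxelSize numeric \code{c(dz, dy, dx)} in micrometres
#' @return a \linkS4class{ChannelStack}
#' @examples
#' channelStack("Ag", array(runif(60), c(3, 4, 5)), c(0.5, 0.1, 0.1))
#' @export
channelStack <- function(name, data, voxelSize) {
  storage.mode(data) <- "double"
  voxelSize <- as.numeric(voxelSize)
  names(voxelSize) <- c("dz", "dy", "dx")
  new("ChannelStack", name = name, data = data, voxelSize = voxelSize)
}

#' Construct a BinaryStack
#'
#' @param data 3D logical array \code{[z, y, x]}
#' @param voxelSize numeric \code{c(dz, dy, dx)} in micrometres
#' @param provenance list recording origin (channel, method, parameters)
#' @return a \linkS4class{BinaryStack}
#' @export
binaryStack <- function(data, voxelSize, provenance = list()) {
  storage.mode(data) <- "logical"
  voxelSize <- as.numeric(voxelSize)
  names(voxelSize) <- c("dz", "dy", "dx")
  new("BinaryStack", data = data, voxelSize = voxelSize,
      provenance = provenance)
}

#' Construct a Scene
#'
#' @param channels list of \linkS4class{ChannelStack} (named automatically)
#' @param beads data.frame with columns \code{x, y, z, radius} (micrometres)
#' @param cellMask optional \linkS4class{BinaryStack}
#' @param metadata free-form list (condition, time point, ...)
#' @param groundTruth optional \linkS4class{SceneGroundTruth}
#' @return a \linkS4class{Scene}
#' @export
scene <- function(channels, beads = data.frame(x = numeric(), y = numeric(),
                                               z = numeric(), radius = numeric()),
                  cellMask = NULL, metadata = list(), groundTruth = NULL) {
  names(channels) <- vapply(channels, function(x) x@name, "")
  new("Scene", channels = channels, beads = beads, cellMask = cellMask,
      metadata = metadata, groundTruth = groundTruth)
}

.SCENE_FORMAT <- 1L

.sidecarPath <- function(path) sub("\\.(tiff?|ome\\.tiff?)$", ".json",
                                   path, ignore.case = TRUE)
.maskPath <- function(path) sub("\\.(tiff?|ome\\.tiff?)$", "_cellmask.tif",
                                path, ignore.case = TRUE)

#' Write a Scene to a multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered channel-fastest within z (page = (z-1)*nChannels + c,
#' the ImageJ hyperstack convention).  Integer intensities up to 65535 are
#' stored losslessly as 16-bit; other data are stored as 32-bit float with
#' a per-channel scale.  Voxel size, channel names, beads, metadata and the
#' encoding are written to \code{<stem>.json}; a cell mask, when present,
#' goes to \code{<stem>_cellmask.tif}.
#'
#' @param x a \linkS4class{Scene}
#' @param path output TIFF filename
#' @return \code{path}, invisibly
#' @seealso \code{\link{readScene}}
#' @export
writeScene <- function(x, path) {
  stopifnot(is(x, "Scene"))
  nms <- channelNames(x)
  nz <- dim(x@channels[[1L]]@data)[1L]
  intlike <- vapply(x@channels, function(ch)
    max(ch@data) <= 65535 && all(ch@data == round(ch@data)), TRUE)
  storage <- if (all(intlike)) "uint16" else "float32"
  scales <- vapply(x@channels, function(ch) {
    m <- max(ch@data)
    if (storage == "uint16") 65535 else if (m > 0) m else 1
  }, 0)
  pages <- vector("list", nz * length(nms))
  for (iz in seq_len(nz)) for (ic in seq_along(nms)) {
    pages[[(iz - 1L) * length(nms) + ic]] <-
      x@channels[[ic]]@data[iz, , ] / scales[ic]
  }
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (storage == "uint16") 16L else 32L,
                  reduce = FALSE)
  meta <- list(format = .SCENE_FORMAT, channels = as.list(nms),
               nz = nz, voxelSize = as.list(voxelSize(x)),
               storage = storage, scale = as.list(scales),
               beads = x@beads, metadata = x@metadata)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(x@cellMask)) writeMask(x@cellMask, .maskPath(path))
  invisible(path)
}

#' Read a Scene from a multi-page TIFF
#'
#' Reads a multi-channel z-stack written by \code{\link{writeScene}} (using
#' its JSON sidecar as metadata) or a plain multi-page TIFF described by
#' \code{config}.  The voxel size is taken from the sidecar metadata when
#' present, else from \code{config}; if neither supplies it, reading fails
#' rather than assuming a default.
#'
#' @param path TIFF filename; pages ordered channel-fastest within z
#' @param config optional channel-mapping configuration: a list (or path to
#'   a YAML/JSON file) with \code{channels} (named integer vector or list
#'   mapping channel name -> 1-based channel index), \code{nChannels}, and
#'   \code{voxelSize} = c(dz, dy, dx); ignored fields are allowed
#' @return a \linkS4class{Scene}
#' @export
readScene <- function(path, config = NULL) {
  if (!file.exists(path)) stop("cannot read scene: no such file '", path, "'")
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  npages <- length(pages)
  side <- .sidecarPath(path)
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else NULL

  if (!is.null(meta)) {
    nms <- unlist(meta$channels)
    nc <- length(nms)
    nz <- meta$nz
    vs <- unlist(meta$voxelSize)[c("dz", "dy", "dx")]
    scales <- unlist(meta$scale)
    storage <- meta$storage
  } else {
    if (is.null(config)) stop("no sidecar metadata: a channel-mapping ",
                              "config is required")
    chmap <- unlist(config$channels)
    if (is.null(names(chmap)) || !length(chmap))
      stop("config$channels must map channel names to 1-based indices")
    nc <- if (!is.null(config$nChannels)) as.integer(config$nChannels)
          else as.integer(max(chmap))
    if (npages %% nc != 0L)
      stop("page count ", npages, " is not a multiple of nChannels = ", nc)
    if (any(chmap < 1L | chmap > nc))
      stop("channel index out of range: config references channel ",
           max(chmap), " of a ", nc, "-channel file")
    nz <- npages %/% nc
    if (is.null(config$voxelSize))
      stop("voxel size missing: not in file metadata and not in config; ",
           "declare voxelSize = c(dz, dy, dx) explicitly")
    vs <- as.numeric(unlist(config$voxelSize))
    nms <- names(chmap)
    scales <- NULL
    storage <- "raw"
  }
  if (npages != nz * nc)
    stop("expected ", nz * nc, " pages, found ", npages)
  dimyx <- dim(pages[[1L]])
  chdata <- lapply(seq_len(nc), function(ic) array(0, c(nz, dimyx)))
  idxOf <- if (!is.null(meta)) seq_len(nc) else as.integer(unlist(config$channels))
  for (k in seq_along(nms)) {
    ic <- idxOf[k]
    for (iz in seq_len(nz)) {
      pg <- pages[[(iz - 1L) * nc + ic]]
      chdata[[k]][iz, , ] <- pg
    }
  }
  channels <- lapply(seq_along(nms), function(k) {
    a <- chdata[[k]]
    if (!is.null(scales)) {
      a <- a * scales[k]
      if (identical(storage, "uint16")) a <- round(a)
    }
    channelStack(nms[k], a, vs)
  })
  beads <- if (!is.null(meta) && length(meta$beads))
    as.data.frame(meta$beads) else
    data.frame(x = numeric(), y = numeric(), z = numeric(), radius = numeric())
  mask <- NULL
  mp <- .maskPath(path)
  if (!is.null(meta) && file.exists(mp)) mask <- readMask(mp, vs)
  md <- if (!is.null(meta) && length(meta$metadata)) as.list(meta$metadata)
        else list()
  scene(channels, beads = beads, cellMask = mask, metadata = md)
}

#' Read / write a binary mask as single-channel TIFF
#'
#' @param x a \linkS4class{BinaryStack}
#' @param path TIFF filename (one page per z-slice)
#' @param voxelSize \code{c(dz, dy, dx)} for \code{readMask}
#' @return \code{writeMask}: \code{path}, invisibly; \code{readMask}: a
#'   \linkS4class{BinaryStack}
#' @export
writeMask <- function(x, path) {
  stopifnot(is(x, "BinaryStack"))
  nz <- dim(x@data)[1L]
  pages <- lapply(seq_len(nz), function(iz) x@data[iz, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, voxelSize) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  a <- array(FALSE, c(nz, dim(pages[[1L]])))
  for (iz in seq_len(nz)) a[iz, , ] <- pages[[iz]] > 0.5
  binaryStack(a, voxelSize, provenance = list(source = path))
}

#' Z-projection of a channel
#'
#' Per-pixel sum or maximum over selected slices, as used for
#' intensity quantification on sum projections.  The physical pixel size
#' \code{c(dy, dx)} is preserved as an attribute.
#'
#' @param stack a \linkS4class{ChannelStack}
#' @param method \code{"sum"} or \code{"max"}
#' @param zRange optional integer slice bounds \code{c(from, to)} (1-based,
#'   inclusive); default all slices
#' @return 2D matrix \code{[y, x]} with attribute \code{pixelSize}
#' @examples
#' cs <- channelStack("Ag", array(1, c(5, 3, 3)), c(0.5, 0.1, 0.1))
#' projectStack(cs, "sum")[1, 1]  # 5
#' @export
projectStack <- function(stack, method = c("sum", "max"), zRange = NULL) {
  method <- match.arg(method)
  d <- dim(stack@data)
  if (is.null(zRange)) zRange <- c(1L, d[1L])
  zRange <- as.integer(zRange)
  if (length(zRange) != 2L || zRange[1L] > zRange[2L] ||
      zRange[1L] < 1L || zRange[2L] > d[1L])
    stop("empty or out-of-range zRange: [", paste(zRange, collapse = ", "),
         "] for a ", d[1L], "-slice stack")
  sl <- stack@data[zRange[1L]:zRange[2L], , , drop = FALSE]
  out <- apply(sl, c(2L, 3L), if (method == "sum") sum else max)
  attr(out, "pixelSize") <- stack@voxelSize[c("dy", "dx")]
  out
}
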