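#' Construct a pipeline configuration
#'
#' Validated configuration for the generate -> quantify -> summarize
#' pipeline.  Every tunable of the quantification has a config field:
#' segmentation method and erosion, the around-bead analysis radius,
#' particle-size bounds, volume-bin edges, the compartment-selection
#' overlap, synaptic-plane selection, optional constant background
#' offset, and the seed.
#'
#' @param mode \code{"generate"} (synthetic cohort) or \code{"load"}
#'   (scenes from \code{sceneDir})
#' @param nScenes number of synthetic scenes (generate mode)
#' @param sceneSpec \linkS4class{SceneSpec} template; per-scene seeds are
#'   \code{seed + 1 .. seed + nScenes}
#' @param sceneDir directory containing scene TIFFs (load mode)
#' @param channels list of channel roles: \code{lysosome}, \code{antigen},
#'   \code{nested} (the marker tested inside selected compartments, e.g.
#'   SNX5), \code{actin} (synaptic-plane template); set a role to NULL to
#'   disable its metrics
#' @param threshold list: \code{method} ("otsu"/"fixed"), \code{value},
#'   \code{perSlice}, \code{erodeIterations}
#' @param analysisRadius around-bead disc radius, micrometres
#' @param particleBounds c(min, max) particle area, micrometres^2
#' @param binEdges volume-bin edges, micrometres^3
#' @param minOverlap voxels required for compartment selection
#' @param synapticPlane \code{"actin-max"} or an explicit z index
#' @param backgroundOffset constant offset subtracted (floored at 0) from
#'   every channel before quantification; 0 = none (the default: no
#'   background subtraction)
#' @param seed integer seed
#' @return a \linkS4class{PipelineConfig}
#' @export
pipelineConfig <- function(mode = c("generate", "load"), nScenes = 5L,
                           sceneSpec = NULL, sceneDir = "",
                           channels = list(lysosome = "LAMP1",
                                           antigen = "Ag", nested = "SNX5",
                                           actin = NULL),
                           threshold = list(method = "otsu", value = NULL,
                                            perSlice = FALSE,
                                            erodeIterations = 1L),
                           analysisRadius = 3.5,
                           particleBounds = c(0.10, 4.00),
                           binEdges = c(6, 12), minOverlap = 1L,
                           synapticPlane = "actin-max",
                           backgroundOffset = 0, seed = 1L) {
  mode <- match.arg(mode)
  errs <- character()
  if (mode == "generate") {
    if (is.null(sceneSpec)) sceneSpec <- sceneSpec()
    if (!is(sceneSpec, "SceneSpec"))
      errs <- c(errs, "sceneSpec: must be a SceneSpec")
    if (!is.numeric(nScenes) || nScenes < 1L)
      errs <- c(errs, "nScenes: must be >= 1")
  } else if (!nzchar(sceneDir)) {
    errs <- c(errs, "sceneDir: required in load mode")
  }
  if (!is.list(channels)) errs <- c(errs, "channels: must be a list of roles")
  if (!threshold$method %in% c("otsu", "fixed"))
    errs <- c(errs, "threshold$method: must be 'otsu' or 'fixed'")
  if (identical(threshold$method, "fixed") && is.null(threshold$value))
    errs <- c(errs, "threshold$value: required for method 'fixed'")
  if (is.null(threshold$perSlice)) threshold$perSlice <- FALSE
  if (is.null(threshold$erodeIterations)) threshold$erodeIterations <- 1L
  if (threshold$erodeIterations < 0L)
    errs <- c(errs, "threshold$erodeIterations: must be >= 0")
  if (analysisRadius <= 0) errs <- c(errs, "analysisRadius: must be > 0")
  if (length(particleBounds) != 2L || particleBounds[1L] > particleBounds[2L]
      || any(particleBounds < 0))
    errs <- c(errs, "particleBounds: must be 0 <= min <= max")
  if (is.unsorted(binEdges, strictly = TRUE))
    errs <- c(errs, "binEdges: must be strictly increasing")
  if (minOverlap < 1L) errs <- c(errs, "minOverlap: must be >= 1")
  if (!(identical(synapticPlane, "actin-max") ||
        (is.numeric(synapticPlane) && synapticPlane >= 1)))
    errs <- c(errs, "synapticPlane: 'actin-max' or a z index >= 1")
  if (backgroundOffset < 0) errs <- c(errs, "backgroundOffset: must be >= 0")
  if (length(errs))
    stop("invalid pipeline configuration:\n  ",
         paste(errs, collapse = "\n  "))
  new("PipelineConfig", mode = mode, nScenes = as.integer(nScenes),
      sceneSpec = sceneSpec, sceneDir = sceneDir, channels = channels,
      threshold = threshold, analysisRadius = analysisRadius,
      particleBounds = as.numeric(particleBounds),
      binEdges = as.numeric(binEdges), minOverlap = as.integer(minOverlap),
      synapticPlane = synapticPlane, backgroundOffset = backgroundOffset,
      seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected with a field-level message before
#' any computation.  \code{sceneSpec} sub-keys map onto
#' \code{\link{sceneSpec}} arguments.
#'
#' @param path YAML file
#' @return a \linkS4class{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("mode", "nScenes", "sceneSpec", "sceneDir", "channels",
             "threshold", "analysisRadius", "particleBounds", "binEdges",
             "minOverlap", "synapticPlane", "backgroundOffset", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("invalid pipeline configuration:\n  unknown field(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(y$sceneSpec)) {
    ssArgs <- y$sceneSpec
    if (!is.null(ssArgs$markerTable)) ssArgs$markerTable <- unlist(ssArgs$markerTable)
    y$sceneSpec <- do.call(sceneSpec, ssArgs)
  }
  ## YAML-null roles arrive absent; merge over the defaults explicitly
  args <- y
  do.call(pipelineConfig, args)
}

#' Quantify one scene into a metric record
#'
#' Computes every per-cell metric available for a scene, given the
#' configured channel roles: polarity index and around-bead fraction per
#' channel, per-channel model volumes and component counts, lysosome
#' volume-bin percentages and particle count at the synaptic plane,
#' spreading area, circularity and recruitment indexes at the synaptic
#' plane, nested containment percentages, Pearson correlation
#' (lysosome vs antigen) and Manders M1 (nested-channel intensity over
#' the lysosome label).  Metrics whose inputs are missing are NA, never 0.
#'
#' @param x a \linkS4class{Scene}
#' @param config a \linkS4class{PipelineConfig}
#' @return one-row data.frame (a metric record)
#' @export
quantifyScene <- function(x, config = pipelineConfig()) {
  stopifnot(is(x, "Scene"), is(config, "PipelineConfig"))
  chs <- channelNames(x)
  roles <- config$channels
  if (config@backgroundOffset > 0)
    for (ch in chs) {
      cs <- x@channels[[ch]]
      x@channels[[ch]] <- channelStack(
        ch, pmax(cs@data - config@backgroundOffset, 0), cs@voxelSize)
    }
  rec <- list(
    condition = if (!is.null(x@metadata$condition)) x@metadata$condition
                else NA_character_,
    time = if (!is.null(x@metadata$time)) as.numeric(x@metadata$time)
           else NA_real_)

  haveBead <- nrow(x@beads) >= 1L
  haveMask <- !is.null(x@cellMask)
  bd <- if (haveBead)
    beadROI(unlist(x@beads[1L, c("x", "y")]), x@beads$radius[1L],
            config@analysisRadius) else NULL

  segment <- function(ch) {
    bs <- thresholdStack(getChannel(x, ch), config@threshold$method,
                         config@threshold$value, config@threshold$perSlice)
    if (config@threshold$erodeIterations > 0L)
      bs <- erodeSlices(bs, config@threshold$erodeIterations)
    bs
  }
  models <- list(); comps <- list()
  for (ch in chs) {
    m <- tryCatch(asVoxelModel(segment(ch), ch), error = function(e) NULL)
    models[[ch]] <- m
    rec[[paste0("vol_", ch)]] <- if (is.null(m)) NA_real_ else volume(m)
    if (haveBead && haveMask)
      rec[[paste0("pi_", ch)]] <- tryCatch(
        indexValue(scenePolarity(x, ch)), error = function(e) NA_real_)
    else rec[[paste0("pi_", ch)]] <- NA_real_
    if (haveBead && haveMask)
      rec[[paste0("aroundBead_", ch)]] <- tryCatch(
        aroundBeadFraction(getChannel(x, ch), bd, x@cellMask),
        error = function(e) NA_real_)
    else rec[[paste0("aroundBead_", ch)]] <- NA_real_
  }

  lyso <- roles$lysosome; ag <- roles$antigen; nest <- roles$nested
  lysoComps <- if (!is.null(lyso) && lyso %in% chs && !is.null(models[[lyso]]))
    linkRoi3d(binaryStack(models[[lyso]]@data, voxelSize(x),
                          models[[lyso]]@provenance)) else NULL
  rec$nComp_lyso <- if (is.null(lysoComps)) NA_integer_ else
    countComponents(lysoComps)
  if (!is.null(lysoComps)) {
    bp <- binVolumes(lysoComps, config@binEdges)
    nm <- gsub("-", "_", gsub(">", "gt", gsub("<", "lt", names(bp)), fixed = TRUE),
               fixed = TRUE)
    for (i in seq_along(bp))
      rec[[paste0("volBinPct_", nm[i])]] <- unname(bp[i])
  }
  if (!is.null(lysoComps) && !is.null(ag) && ag %in% chs &&
      !is.null(models[[ag]]) && !is.null(nest) && nest %in% chs &&
      !is.null(models[[nest]])) {
    nf <- nestedFraction(lysoComps, models[[ag]], models[[nest]],
                         config@minOverlap)
    rec$pctContainingAg <- nf$primaryPercent
    rec$pctAgAndNested <- nf$nestedPercent
  } else {
    rec$pctContainingAg <- NA_real_
    rec$pctAgAndNested <- NA_real_
  }
  rec$pearson_lyso_ag <- if (!is.null(lyso) && !is.null(ag) &&
                             all(c(lyso, ag) %in% chs) && haveMask)
    tryCatch(pearsonColoc(getChannel(x, lyso), getChannel(x, ag), x@cellMask),
             error = function(e) NA_real_) else NA_real_
  rec$m1_nested_over_lyso <- if (!is.null(nest) && nest %in% chs &&
                                 !is.null(lyso) && !is.null(models[[lyso]]))
    tryCatch(mandersM1(getChannel(x, nest), models[[lyso]], x@cellMask),
             error = function(e) NA_real_) else NA_real_

  ## synaptic-plane metrics
  planeCh <- if (!is.null(roles$actin) && roles$actin %in% chs) roles$actin
             else lyso
  pl <- tryCatch({
    if (identical(config@synapticPlane, "actin-max"))
      findSynapticPlane(x, planeCh)
    else findSynapticPlane(x, planeCh, zIndex = as.integer(config@synapticPlane))
  }, error = function(e) NULL)
  if (!is.null(pl)) {
    rec$synapticZ <- pl@zIndex
    rec$spreadingArea <- tryCatch(spreadingArea(pl), error = function(e) NA_real_)
    rec$circularity <- tryCatch(
      circularity(.largestComponent2d(pl@outline), pl@pixelSize),
      error = function(e) NA_real_)
    for (ch in chs)
      rec[[paste0("recruit_", ch)]] <- tryCatch(
        recruitmentIndex(pl@images[[ch]], pl@outline, pl@pixelSize),
        error = function(e) NA_real_)
    if (!is.null(lyso) && lyso %in% chs)
      rec$nParticlesIS <- tryCatch(
        countFoci(pl, lyso, config@particleBounds[1L],
                  config@particleBounds[2L],
                  if (config@threshold$method == "fixed") "fixed" else "otsu",
                  config@threshold$value),
        error = function(e) NA_integer_)
  } else {
    rec$synapticZ <- NA_integer_
    rec$spreadingArea <- NA_real_
    rec$circularity <- NA_real_
    rec$nParticlesIS <- NA_integer_
  }
  ## raw antigen signal in the bead disc (sum projection); extraction time
  ## courses are normalized across a series by runPipeline
  rec$agInBeadDisc <- if (haveBead && !is.null(ag) && ag %in% chs) {
    pr <- projectStack(getChannel(x, ag), "sum")
    xs <- .axisCoords(ncol(pr), voxelSize(x)["dx"][[1L]])
    ys <- .axisCoords(nrow(pr), voxelSize(x)["dy"][[1L]])
    disc <- outer((ys - bd@center[2L])^2, (xs - bd@center[1L])^2, "+") <=
      bd@analysisRadius^2
    sum(pr[disc])
  } else NA_real_
  as.data.frame(rec, stringsAsFactors = FALSE)
}

## access list-like slot with NULL passthrough (roles may be absent)
#' @rdname pipelineConfig
#' @param x,name slot access: \code{cfg$field}
#' @aliases $,PipelineConfig-method
#' @export
setMethod("$", "PipelineConfig", function(x, name) slot(x, name))

.largestComponent2d <- function(mask) {
  lab3 <- .labelComponents(array(mask, c(1L, dim(mask))),
                           .neighborOffsets(8L, linkZ = FALSE))
  lab <- lab3[1L, , ]
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Run the quantification pipeline
#'
#' Generates (or loads) the scenes named by the configuration and
#' quantifies each into one metric record.  Per-scene failures are logged
#' and do not abort the run; the returned status is 0 when every scene
#' processed, 2 on partial success, 1 when nothing could be processed.
#' Antigen-in-disc values are normalized into extraction percentages
#' (\code{pctAgRemaining}) within each condition group that includes a
#' time-0 scene.  Deterministic given config and seed.
#'
#' @param config a \linkS4class{PipelineConfig}
#' @return list with \code{metrics} (data.frame, one row per cell),
#'   \code{log} (data.frame of per-scene events) and \code{status}
#' @examples
#' cfg <- pipelineConfig(nScenes = 1L,
#'   sceneSpec = sceneSpec(nCompartments = 6L, seed = 3L))
#' res <- runPipeline(cfg)
#' nrow(res$metrics)
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  if (config@mode == "generate") {
    ids <- sprintf("synthetic-%03d", seq_len(config@nScenes))
    loader <- function(i) {
      sp <- config@sceneSpec
      sp@seed <- config@seed + i
      generateScene(sp)
    }
    n <- config@nScenes
  } else {
    files <- sort(list.files(config@sceneDir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    files <- files[!grepl("_cellmask\\.tif$", files)]
    if (!length(files)) stop("no scene TIFFs found in '", config@sceneDir, "'")
    ids <- basename(files)
    loader <- function(i) readScene(files[i])
    n <- length(files)
  }
  rows <- vector("list", n)
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sc <- loader(i)
      row <- quantifyScene(sc, config)
      row$sceneId <- ids[i]
      row$cellId <- 1L
      list(row = row, event = "ok", detail = "")
    }, error = function(e)
      list(row = NULL, event = "error", detail = conditionMessage(e)))
    rows[i] <- list(res$row)
    logs[[i]] <- data.frame(sceneId = ids[i], event = res$event,
                            detail = res$detail, stringsAsFactors = FALSE)
  }
  ok <- !vapply(rows, is.null, TRUE)
  metrics <- if (any(ok)) do.call(rbind, rows[ok]) else data.frame()
  if (nrow(metrics)) {
    lead <- c("sceneId", "cellId", "condition", "time")
    metrics <- metrics[, c(lead, setdiff(names(metrics), lead)), drop = FALSE]
    ## extraction: normalize antigen-in-disc by the time-0 value per condition
    metrics$pctAgRemaining <- NA_real_
    for (cond in unique(metrics$condition)) {
      g <- which(metrics$condition %in% cond)
      t0 <- g[which(metrics$time[g] == 0)]
      if (length(t0) && isTRUE(mean(metrics$agInBeadDisc[t0]) > 0))
        metrics$pctAgRemaining[g] <-
          100 * metrics$agInBeadDisc[g] / mean(metrics$agInBeadDisc[t0])
    }
  }
  status <- if (all(ok)) 0L else if (any(ok)) 2L else 1L
  list(metrics = metrics, log = do.call(rbind, logs), status = status)
}

#' Descriptive per-group summary of a metric table
#'
#' Mean, standard error of the mean and n for every numeric metric,
#' grouped by the given keys.  Descriptive only; no hypothesis testing.
#'
#' @param table metric data.frame from \code{\link{runPipeline}}
#' @param groupKeys character vector of grouping columns
#' @return long data.frame: group columns, \code{metric}, \code{mean},
#'   \code{sem}, \code{n}
#' @examples
#' tb <- data.frame(condition = "a", v = c(1, 2, 3))
#' summarizeMetrics(tb, "condition")  # mean 2, sem 1/sqrt(3)
#' @export
summarizeMetrics <- function(table, groupKeys) {
  if (!is.data.frame(table) || !nrow(table)) stop("empty metric table")
  missing <- setdiff(groupKeys, names(table))
  if (length(missing))
    stop("unknown group key(s): ", paste(missing, collapse = ", "))
  numCols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], groupKeys)
  key <- interaction(table[groupKeys], drop = TRUE, sep = "\r")
  out <- list()
  for (lv in levels(key)) {
    idx <- which(key == lv)
    gvals <- table[idx[1L], groupKeys, drop = FALSE]
    for (m in numCols) {
      v <- table[[m]][idx]
      v <- v[!is.na(v)]
      if (!length(v)) next
      out[[length(out) + 1L]] <- cbind(
        gvals,
        data.frame(metric = m, mean = mean(v),
                   sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                         else NA_real_,
                   n = length(v), stringsAsFactors = FALSE),
        row.names = NULL)
    }
  }
  if (!length(out)) stop("no numeric metrics to summarize")
  do.call(rbind, out)
}
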