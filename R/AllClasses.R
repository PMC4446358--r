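setClassUnion("functionOrNULL", c("function", "NULL"))

#' LabelVolume: an integer-labelled 2D/3D volume
#'
#' The universal container for superpixel maps, segmentations and ground
#' truth. Labels are non-negative integers; one label (default 0) is reserved
#' for background/ignore. `anisotropy` carries per-axis voxel size ratios.
#'
#' @slot data integer array, 2D or 3D.
#' @slot backgroundLabel integer reserved for outside/ignore pixels.
#' @slot anisotropy numeric per-axis voxel size ratios (unitless).
#' @export
setClass("LabelVolume",
    representation(data = "array", backgroundLabel = "integer",
                   anisotropy = "numeric"))

setValidity("LabelVolume", function(object) {
    d <- dim(object@data)
    if (is.null(d) || !(length(d) %in% c(2L, 3L)))
        return("data must be a 2D or 3D array")
    if (anyNA(object@data)) return("labels must not contain NA")
    if (any(object@data < 0)) return("all labels must be >= 0")
    if (length(object@anisotropy) != length(d))
        return("anisotropy must have one entry per axis")
    if (any(object@anisotropy <= 0)) return("anisotropy must be positive")
    TRUE
})

#' Construct a LabelVolume
#'
#' @param data integer matrix or 3D array of labels.
#' @param backgroundLabel label reserved for background (default 0).
#' @param anisotropy per-axis voxel size ratios; default isotropic.
#' @return a [LabelVolume-class] object.
#' @export
LabelVolume <- function(data, backgroundLabel = 0L, anisotropy = NULL) {
    if (is.null(dim(data))) stop("'data' must be a matrix or array")
    storage.mode(data) <- "integer"
    new("LabelVolume", data = data,
        backgroundLabel = as.integer(backgroundLabel),
        anisotropy = anisotropy %||% rep(1, length(dim(data))))
}

#' ProbabilityMaps: per-pixel multiclass probabilities
#'
#' A stack of class-probability channels over the same spatial grid as a
#' [LabelVolume-class]; the last array dimension indexes channels and the
#' channel values sum to one at every pixel. The canonical channel set for
#' EM data is cell boundary, cytoplasm, mitochondria and mitochondria
#' boundary.
#'
#' @slot data numeric array of shape (spatial dims, channels).
#' @slot channelNames character vector naming the channels.
#' @export
setClass("ProbabilityMaps",
    representation(data = "array", channelNames = "character"))

setValidity("ProbabilityMaps", function(object) {
    d <- dim(object@data)
    if (is.null(d) || !(length(d) %in% c(3L, 4L)))
        return("data must have shape (spatial..., channels) for 2D/3D input")
    nc <- d[length(d)]
    if (length(object@channelNames) != nc)
        return("channelNames length must equal the number of channels")
    if (anyDuplicated(object@channelNames))
        return("channelNames must be unique")
    rng <- range(object@data)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
        return("probabilities must lie in [0, 1]")
    m <- matrix(object@data, ncol = nc)
    s <- rowSums(m)
    if (max(abs(s - 1)) > 1e-4)
        return("channel probabilities must sum to 1 at every pixel")
    TRUE
})

#' Construct ProbabilityMaps
#'
#' @param data numeric array (spatial dims, channels).
#' @param channelNames channel names; defaults to the canonical EM set when
#'   there are four channels.
#' @return a [ProbabilityMaps-class] object.
#' @export
ProbabilityMaps <- function(data, channelNames = NULL) {
    nc <- dim(data)[length(dim(data))]
    if (is.null(channelNames)) {
        channelNames <- if (nc == 4)
            c("cell.boundary", "cytoplasm", "mitochondria", "mito.boundary")
        else paste0("channel", seq_len(nc))
    }
    new("ProbabilityMaps", data = data, channelNames = channelNames)
}

#' RegionGraph: the region adjacency graph
#'
#' Nodes are current regions (merged supersets of superpixels) carrying a
#' kind tag (CYTO/MITO), size and mergeable per-channel statistics; edges are
#' current boundaries carrying face size, boundary statistics, a cached
#' confidence and an ACTIVE/DELAY scheduling flag. `mergeLog` records every
#' merge (survivor, absorbed, confidence at merge, round, endpoint kinds) in
#' order; replaying it onto the initial superpixel map reproduces the current
#' label map.
#'
#' @slot nodes named list of region records, keyed by region id.
#' @slot edges named list of boundary records, keyed by "a-b" (a < b).
#' @slot adj named list: region id -> integer vector of neighbour ids.
#' @slot mergeLog list of merge records.
#' @slot nChannels number of probability channels in the statistics.
#' @slot channelNames channel names.
#' @slot lastMerge bookkeeping for the most recent merge (engine use).
#' @slot report agglomeration run report (filled by the engines).
#' @export
setClass("RegionGraph",
    representation(nodes = "list", edges = "list", adj = "list",
                   mergeLog = "list", nChannels = "integer",
                   channelNames = "character", lastMerge = "list",
                   report = "list"))

setValidity("RegionGraph", function(object) {
    for (key in names(object@edges)) {
        e <- object@edges[[key]]
        if (e$a == e$b) return("self-loop edge found")
        if (is.null(object@nodes[[as.character(e$a)]]) ||
            is.null(object@nodes[[as.character(e$b)]]))
            return(sprintf("edge %s references a dead region", key))
        if (e$faceSize < 1) return("edge with faceSize < 1")
    }
    TRUE
})

#' ConfidencePredictor: a boundary-confidence function h
#'
#' Maps an edge of a [RegionGraph-class] to a confidence in [0, 1] that the
#' boundary is real (separates two true objects). Three modes:
#' `MEAN_PROB` returns the mean of one probability channel over the boundary
#' pixels; `CLASSIFIER` scores the edge feature vector with a trained random
#' forest; `FUNCTION` evaluates an arbitrary `fn(graph, key)` (used for the
#' mitochondria overlap-ratio confidence and in tests).
#'
#' @slot mode one of "MEAN_PROB", "CLASSIFIER", "FUNCTION".
#' @slot model opaque trained-classifier handle (CLASSIFIER mode).
#' @slot channel probability channel averaged in MEAN_PROB mode.
#' @slot fn confidence function in FUNCTION mode.
#' @slot featureConfig feature-layout configuration (CLASSIFIER mode).
#' @export
setClass("ConfidencePredictor",
    representation(mode = "character", model = "ANY", channel = "character",
                   fn = "functionOrNULL", featureConfig = "list"))

setValidity("ConfidencePredictor", function(object) {
    if (!object@mode %in% c("MEAN_PROB", "CLASSIFIER", "FUNCTION"))
        return("mode must be MEAN_PROB, CLASSIFIER or FUNCTION")
    if (object@mode == "CLASSIFIER" && is.null(object@model))
        return("CLASSIFIER mode requires a trained model")
    if (object@mode == "FUNCTION" && is.null(object@fn))
        return("FUNCTION mode requires fn")
    TRUE
})

#' ContingencyTable: ground-truth x segmentation overlap counts
#'
#' Sparse overlap counts |g_i n r_j| for every (ground-truth body, segment)
#' pair with nonzero overlap, plus the total counted pixels Z.
#'
#' @slot counts data.frame with columns g, r, n.
#' @slot Z total number of counted pixels.
#' @export
setClass("ContingencyTable",
    representation(counts = "data.frame", Z = "numeric"))

setValidity("ContingencyTable", function(object) {
    if (!all(c("g", "r", "n") %in% names(object@counts)))
        return("counts must have columns g, r, n")
    if (abs(sum(object@counts$n) - object@Z) > 1e-6)
        return("grand total must equal Z")
    TRUE
})

#' SplitMetrics: split-VI and split Rand error
#'
#' Over-/under-segmentation decomposition of the variation of information
#' (in nats) and of the Rand error (pair fractions) between a segmentation
#' and ground truth. `viOE` penalizes ground-truth bodies fragmented across
#' segments (false splits), `viUE` penalizes segments spanning several
#' ground-truth bodies (false merges); the Rand terms count the corresponding
#' falsely split / falsely merged pixel pairs as fractions of all pairs.
#'
#' @slot viOE over-segmentation conditional entropy (nats).
#' @slot viUE under-segmentation conditional entropy (nats).
#' @slot reOE fraction of pairs same in GT but split in the segmentation.
#' @slot reUE fraction of pairs same in the segmentation but split in GT.
#' @slot table the [ContingencyTable-class] the metrics derive from.
#' @export
setClass("SplitMetrics",
    representation(viOE = "numeric", viUE = "numeric",
                   reOE = "numeric", reUE = "numeric",
                   table = "ContingencyTable"))

#' Scene: a synthetic benchmark scene
#'
#' Ground-truth cells with interior mitochondria, four-channel probability
#' maps derived from them, a superpixel over-segmentation that refines the
#' ground truth, and the true (cell, kind) assignment of every superpixel.
#'
#' @slot gtCells ground-truth cell partition ([LabelVolume-class]).
#' @slot gtMitoMask logical array marking mitochondria pixels.
#' @slot probs [ProbabilityMaps-class] with the four canonical channels.
#' @slot superpixels the over-segmentation ([LabelVolume-class]).
#' @slot gtRegionMap data.frame: superpixel, cell, kind, mito id.
#' @slot spec the generating [sceneSpec()] (list).
#' @export
setClass("Scene",
    representation(gtCells = "LabelVolume", gtMitoMask = "array",
                   probs = "ProbabilityMaps", superpixels = "LabelVolume",
                   gtRegionMap = "data.frame", spec = "list"))

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@data)
    ids <- setdiff(unique(as.vector(object@data)), object@backgroundLabel)
    cat(sprintf("LabelVolume: %s, %d regions (background = %d)\n",
                paste(d, collapse = " x "), length(ids),
                object@backgroundLabel))
})

setMethod("show", "ProbabilityMaps", function(object) {
    d <- dim(object@data)
    cat(sprintf("ProbabilityMaps: %s, channels: %s\n",
                paste(head(d, -1), collapse = " x "),
                paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "RegionGraph", function(object) {
    cat(sprintf("RegionGraph: %d regions, %d boundaries, %d merges logged\n",
                length(object@nodes), length(object@edges),
                length(object@mergeLog)))
})

setMethod("show", "ConfidencePredictor", function(object) {
    extra <- switch(object@mode,
        MEAN_PROB = sprintf(" (channel: %s)", object@channel),
        CLASSIFIER = sprintf(" (%d features)",
                             length(object@model$featureNames)),
        "")
    cat(sprintf("ConfidencePredictor: %s%s\n", object@mode, extra))
})

setMethod("show", "SplitMetrics", function(object) {
    cat(sprintf(paste0("SplitMetrics: VI_OE = %.4f, VI_UE = %.4f nats; ",
                       "RE_OE = %.3g, RE_UE = %.3g\n"),
                object@viOE, object@viUE, object@reOE, object@reUE))
})

setMethod("show", "Scene", function(object) {
    cat(sprintf(
        "Scene: %s, %d cells, %d mitochondria, %d superpixels (seed %s)\n",
        paste(dim(object@gtCells@data), collapse = " x "),
        length(setdiff(unique(as.vector(object@gtCells@data)), 0L)),
        sum(object@gtRegionMap$kind == "MITO"),
        nrow(object@gtRegionMap),
        format(object@spec$seed)))
})

#' @describeIn LabelVolume-class the raw label array.
#' @param object a LabelVolume.
#' @export
labelData <- function(object) object@data

#' @describeIn LabelVolume-class the reserved background label.
#' @export
backgroundLabel <- function(object) object@backgroundLabel

#' @describeIn LabelVolume-class sorted non-background label ids.
#' @export
labelIds <- function(object) {
    sort(setdiff(unique(as.vector(object@data)), object@backgroundLabel))
}

#' @describeIn LabelVolume-class pixel count per non-background label.
#' @export
regionSizes <- function(object) {
    v <- as.vector(object@data)
    v <- v[v != object@backgroundLabel]
    tab <- table(v)
    setNames(as.numeric(tab), names(tab))
}

#' @describeIn ProbabilityMaps-class channel names.
#' @param object a ProbabilityMaps.
#' @export
channelNames <- function(object) object@channelNames

#' @describeIn ProbabilityMaps-class one channel as a spatial array.
#' @param channel channel name or index.
#' @export
probChannel <- function(object, channel) {
    if (is.character(channel)) {
        channel <- match(channel, object@channelNames)
        if (is.na(channel)) stop("unknown channel name")
    }
    d <- dim(object@data)
    nd <- length(d)
    if (nd == 3) array(object@data[, , channel], dim = d[1:2])
    else array(object@data[, , , channel], dim = d[1:3])
}

#' @describeIn RegionGraph-class ids of live regions.
#' @param graph a RegionGraph.
#' @export
regionIds <- function(graph) {
    sort(as.integer(names(graph@nodes)))
}

#' @describeIn RegionGraph-class keys of live boundaries.
#' @export
edgeKeys <- function(graph) names(graph@edges)

#' @describeIn RegionGraph-class one region record (id, members, kind, size,
#'   stats).
#' @param id region id.
#' @export
regionNode <- function(graph, id) {
    n <- graph@nodes[[as.character(id)]]
    if (is.null(n)) stop("unknown region id: ", id)
    n
}

#' @describeIn RegionGraph-class one boundary record (endpoints, faceSize,
#'   stats, confidence, flag).
#' @param key edge key "a-b" (or pass two ids to [boundaryEdgeBetween()]).
#' @export
boundaryEdge <- function(graph, key) {
    e <- graph@edges[[key]]
    if (is.null(e)) stop("unknown edge: ", key)
    e
}

#' @describeIn RegionGraph-class boundary record between two regions.
#' @param a,b region ids.
#' @export
boundaryEdgeBetween <- function(graph, a, b) {
    boundaryEdge(graph, edgeKey(a, b))
}

#' @describeIn RegionGraph-class neighbour ids of a region.
#' @export
neighbourIds <- function(graph, id) {
    graph@adj[[as.character(id)]] %||% integer(0)
}

#' @describeIn RegionGraph-class the ordered merge log as a data.frame.
#' @export
mergeLog <- function(graph) {
    if (length(graph@mergeLog) == 0)
        return(data.frame(survivor = integer(0), absorbed = integer(0),
                          confidence = numeric(0), round = integer(0),
                          survivorKind = character(0),
                          absorbedKind = character(0)))
    do.call(rbind, lapply(graph@mergeLog, function(m)
        data.frame(survivor = m$survivor, absorbed = m$absorbed,
                   confidence = m$confidence, round = m$round,
                   survivorKind = m$survivorKind,
                   absorbedKind = m$absorbedKind)))
}
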