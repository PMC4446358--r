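#' Read and write label volumes as multipage TIFF
#'
#' Integer labels round-trip exactly (32-bit samples, written as-is). A 2D
#' volume is a single page; a 3D volume stores one page per slice along the
#' last axis.
#'
#' @param volume a [LabelVolume-class].
#' @param path TIFF file path.
#' @export
writeLabelVolume <- function(volume, path) {
    if (!is(volume, "LabelVolume")) volume <- LabelVolume(volume)
    d <- dim(volume@data)
    pages <- if (length(d) == 2) list(volume@data)
             else lapply(seq_len(d[3]), function(z) volume@data[, , z])
    # 32-bit integer samples; the tiff interface expects [0,1] reals
    tiff::writeTIFF(lapply(pages, function(p) p / (2^32 - 1)),
                    path, bits.per.sample = 32L)
    invisible(path)
}

#' @rdname writeLabelVolume
#' @param backgroundLabel background label of the volume being read.
#' @return `readLabelVolume`: a [LabelVolume-class].
#' @export
readLabelVolume <- function(path, backgroundLabel = 0L) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- if (length(pages) == 1) pages[[1]]
           else array(unlist(pages), dim = c(dim(pages[[1]]),
                                             length(pages)))
    LabelVolume(arr, backgroundLabel = backgroundLabel)
}

#' Read and write probability maps as per-channel TIFF files
#'
#' Each channel goes to `<basePath>-<channel>.tif` as 32-bit float pages
#' (one page per slice for 3D data); the channel order is carried by the
#' file names handed back and must be redeclared when reading.
#'
#' @param probs a [ProbabilityMaps-class].
#' @param basePath path prefix for the channel files.
#' @return the written file paths (invisibly).
#' @export
writeProbabilityMaps <- function(probs, basePath) {
    nd <- length(dim(probs@data)) - 1
    paths <- character(0)
    for (ch in probs@channelNames) {
        arr <- probChannel(probs, ch)
        pages <- if (nd == 2) list(arr)
                 else lapply(seq_len(dim(arr)[3]), function(z) arr[, , z])
        p <- paste0(basePath, "-", ch, ".tif")
        tiff::writeTIFF(pages, p, bits.per.sample = 32L)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' @rdname writeProbabilityMaps
#' @param channelNames channel order; files are looked up as
#'   `<basePath>-<channel>.tif`.
#' @return `readProbabilityMaps`: a [ProbabilityMaps-class].
#' @export
readProbabilityMaps <- function(basePath,
                                channelNames = c("cell.boundary",
                                                 "cytoplasm",
                                                 "mitochondria",
                                                 "mito.boundary")) {
    chans <- lapply(channelNames, function(ch) {
        pages <- tiff::readTIFF(paste0(basePath, "-", ch, ".tif"),
                                all = TRUE)
        if (!is.list(pages)) pages <- list(pages)
        if (length(pages) == 1) pages[[1]]
        else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    })
    d <- dim(chans[[1]])
    arr <- array(unlist(chans), dim = c(d, length(chans)))
    # clipping + renormalization absorbs float32 quantization
    m <- matrix(arr, ncol = length(chans))
    m[m < 0] <- 0; m[m > 1] <- 1
    m <- m / rowSums(m)
    ProbabilityMaps(array(m, dim = c(d, length(chans))), channelNames)
}

#' Save / load a trained confidence predictor
#'
#' The serialized file embeds the feature layout; [predictConfidence()]
#' refuses to score a graph whose feature columns do not match.
#'
#' @param predictor a [ConfidencePredictor-class] (CLASSIFIER mode).
#' @param path file path.
#' @export
savePredictor <- function(predictor, path) {
    saveRDS(list(format = "cadaSeg-predictor-1", predictor = predictor),
            path)
    invisible(path)
}

#' @rdname savePredictor
#' @return `loadPredictor`: the predictor.
#' @export
loadPredictor <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "cadaSeg-predictor-1"))
        stop("not a serialized cadaSeg predictor: ", path)
    obj$predictor
}
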