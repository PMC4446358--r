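#' Marker-seeded watershed on an arbitrary landscape
#'
#' Priority-flood watershed: marked pixels flood outward in order of
#' increasing landscape height (FIFO at equal height), so every pixel ends
#' up in some basin -- watershed "line" pixels are assigned to the basin
#' that reaches them first, keeping the output gap-free. Optionally the
#' flood is confined within regions of a mask (used by the scene generator
#' to carve fragments inside fixed regions).
#'
#' @param height numeric 2D/3D array, the flooding landscape.
#' @param markers integer array of the same shape; positive values seed
#'   basins with that label, zeros are unmarked.
#' @param region optional integer array; flooding never crosses pixels with
#'   a different region value.
#' @return integer array of basin labels.
#' @export
seededWatershed <- function(height, markers, region = NULL) {
    d <- dim(height)
    if (!identical(d, dim(markers))) stop("markers shape mismatch")
    reg <- if (is.null(region)) integer(0) else as.integer(region)
    lab <- cpp_watershed(as.numeric(height), as.integer(markers),
                         as.integer(d), reg)
    array(lab, dim = d)
}

#' Connected components under face connectivity
#'
#' @param mask logical 2D/3D array.
#' @return integer array; components labelled 1..k, background 0.
#' @export
connectedComponents <- function(mask) {
    d <- dim(mask)
    array(cpp_cc_label(as.logical(mask), as.integer(d)), dim = d)
}

#' Watershed over-segmentation from probability maps
#'
#' The front end of the agglomeration pipeline: connected regions of low
#' cell-boundary probability act as markers, and the (optionally smoothed)
#' boundary-probability landscape is flooded from them. Every pixel is
#' labelled (watershed lines belong to basins), labels are consecutive
#' positive integers, and the result is deterministic given the
#' configuration.
#'
#' @param probs a [ProbabilityMaps-class].
#' @param seedThreshold markers are components of
#'   \{boundary probability < seedThreshold\} (default 0.1).
#' @param minSeedSize drop marker components smaller than this (pixels,
#'   default 5).
#' @param smoothingSigma Gaussian smoothing of the landscape in pixels
#'   (default 1; 0 disables).
#' @param boundaryChannel name of the cell-boundary channel.
#' @return a [LabelVolume-class] of superpixels.
#' @export
watershedOversegment <- function(probs, seedThreshold = 0.1,
                                 minSeedSize = 5L, smoothingSigma = 1,
                                 boundaryChannel = "cell.boundary") {
    if (!is(probs, "ProbabilityMaps")) probs <- ProbabilityMaps(probs)
    land <- gaussianBlur(probChannel(probs, boundaryChannel), smoothingSigma)
    comp <- connectedComponents(land < seedThreshold)
    if (max(comp) == 0)
        stop(sprintf(
            "no watershed markers: no pixel below seed threshold %g",
            seedThreshold))
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    keep <- which(sizes >= minSeedSize)
    if (length(keep) == 0)
        stop(sprintf(
            "no watershed markers of size >= %d at seed threshold %g",
            minSeedSize, seedThreshold))
    relabel <- integer(max(comp) + 1L)
    relabel[keep + 1L] <- seq_along(keep)
    markers <- array(relabel[comp + 1L], dim = dim(comp))
    labels <- seededWatershed(land, markers)
    LabelVolume(labels)
}
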