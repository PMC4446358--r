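#' Default edge feature layout
#'
#' Which channels enter the feature vector, which percentiles the "4
#' quartiles" are, and whether the size terms are included. The default uses
#' all channels, the 25/50/75/100 percentiles and the size terms.
#'
#' @param channels channel names to include (NULL = all channels in the
#'   graph).
#' @param quartiles percentile levels.
#' @param includeSize include log(face size) and log(min/max region size).
#' @return a feature-layout configuration list.
#' @export
featureConfig <- function(channels = NULL, quartiles = c(0.25, 0.5, 0.75, 1),
                          includeSize = TRUE) {
    list(channels = channels, quartiles = quartiles,
         includeSize = includeSize)
}

# mean, sd and quartiles of a summary restricted to selected channels,
# flattened channel-major.
#' @noRd
statsSummaryVector <- function(s, chanIdx, quartiles) {
    m <- statsMean(s)[chanIdx]
    sd <- statsSd(s)[chanIdx]
    q <- statsQuartiles(s, quartiles)[chanIdx, , drop = FALSE]
    out <- numeric(0)
    for (i in seq_along(chanIdx))
        out <- c(out, m[i], sd[i], q[i, ])
    out
}

#' Edge feature vector
#'
#' The statistical representation of a boundary fed to the classifier: for
#' every probability channel the mean, standard deviation and 4 quartiles of
#' (a) the boundary pixels, (b) the larger region, (c) the smaller region,
#' and the absolute differences |(b) - (c)|; plus log face size and log
#' min/max region size. The two endpoint regions are ordered by size (ties
#' by id) and the differences are absolute, so the vector is invariant under
#' swapping the endpoints.
#'
#' @param graph a [RegionGraph-class].
#' @param key edge key "a-b".
#' @param config a [featureConfig()] list.
#' @return named numeric vector.
#' @export
edgeFeatures <- function(graph, key, config = featureConfig()) {
    edgeFeatureMatrix(graph, key, config)[1, ]
}

#' @rdname edgeFeatures
#' @param keys character vector of edge keys.
#' @return `edgeFeatureMatrix`: numeric matrix, one row per edge.
#' @export
edgeFeatureMatrix <- function(graph, keys, config = featureConfig()) {
    chans <- config$channels %||% graph@channelNames
    chanIdx <- match(chans, graph@channelNames)
    if (anyNA(chanIdx))
        stop("unknown channel(s): ",
             paste(chans[is.na(chanIdx)], collapse = ", "))
    qs <- config$quartiles
    nstat <- 2 + length(qs)
    nFeat <- length(chans) * nstat * 4 + if (isTRUE(config$includeSize)) 3 else 0
    out <- matrix(NA_real_, nrow = length(keys), ncol = nFeat)
    for (i in seq_along(keys)) {
        e <- graph@edges[[keys[i]]]
        if (is.null(e)) stop("unknown edge: ", keys[i])
        if (is.null(e$stats) || e$stats$count == 0)
            stop("edge ", keys[i], " has no boundary statistics")
        na <- graph@nodes[[as.character(e$a)]]
        nb <- graph@nodes[[as.character(e$b)]]
        vb <- statsSummaryVector(e$stats, chanIdx, qs)
        va <- statsSummaryVector(na$stats, chanIdx, qs)
        vc <- statsSummaryVector(nb$stats, chanIdx, qs)
        # order the endpoints by size, ties by the statistics themselves,
        # so the vector is invariant under relabelling the two regions
        aFirst <- if (na$size != nb$size) na$size > nb$size else {
            d <- va - vc
            j <- which(abs(d) > 0)[1]
            if (is.na(j)) TRUE else d[j] > 0
        }
        r1 <- if (aFirst) na else nb
        r2 <- if (aFirst) nb else na
        v1 <- if (aFirst) va else vc
        v2 <- if (aFirst) vc else va
        # interleave channel-major: per channel boundary, r1, r2, |r1-r2|
        row <- numeric(0)
        for (c in seq_along(chanIdx)) {
            sl <- ((c - 1) * nstat + 1):(c * nstat)
            row <- c(row, vb[sl], v1[sl], v2[sl], abs(v1[sl] - v2[sl]))
        }
        if (isTRUE(config$includeSize))
            row <- c(row, log(e$faceSize),
                     log(min(r1$size, r2$size)), log(max(r1$size, r2$size)))
        out[i, ] <- row
    }
    colnames(out) <- featureNames(chans, qs, isTRUE(config$includeSize))
    rownames(out) <- keys
    out
}

#' @rdname edgeFeatures
#' @param chans,includeSize layout parameters (see [featureConfig()]).
#' @return `featureNames`: the column names of the feature matrix.
#' @export
featureNames <- function(chans, quartiles = c(0.25, 0.5, 0.75, 1),
                         includeSize = TRUE) {
    statNames <- c("mean", "sd", paste0("q", round(quartiles * 100)))
    nm <- character(0)
    for (ch in chans)
        for (src in c("bnd", "r1", "r2", "diff"))
            nm <- c(nm, paste(ch, src, statNames, sep = "."))
    if (includeSize)
        nm <- c(nm, "log.face.size", "log.min.size", "log.max.size")
    make.names(nm)
}

#' Export a feature matrix as CSV
#'
#' Writes one row per edge with a header naming every feature component,
#' plus the edge key (and optionally a label column) for classifier
#' portability.
#'
#' @param features feature matrix from [edgeFeatureMatrix()].
#' @param path output CSV path.
#' @param labels optional 0/1 edge labels appended as a final column.
#' @export
writeFeatureCSV <- function(features, path, labels = NULL) {
    df <- data.frame(edge = rownames(features) %||%
                         as.character(seq_len(nrow(features))),
                     features, check.names = FALSE)
    if (!is.null(labels)) df$label <- labels
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
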