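#' Partition regions into cytoplasm and mitochondria kinds
#'
#' Tags every region MITO iff its mean mitochondria probability (from the
#' region's mergeable statistics) exceeds the threshold, CYTO otherwise.
#' Tags persist through merges: phase-1 merges are CYTO-CYTO, and a phase-2
#' merged body is tagged CYTO.
#'
#' @param graph a [RegionGraph-class].
#' @param mitoProbThreshold membership threshold on the mean mitochondria
#'   probability (default 0.5).
#' @param channel name of the mitochondria probability channel.
#' @return the graph with kind tags set.
#' @export
partitionKinds <- function(graph, mitoProbThreshold = 0.5,
                           channel = "mitochondria") {
    ci <- match(channel, graph@channelNames)
    if (is.na(ci)) stop("missing probability channel: ", channel)
    for (key in names(graph@nodes)) {
        m <- statsMean(graph@nodes[[key]]$stats)[ci]
        graph@nodes[[key]]$kind <- if (m > mitoProbThreshold) "MITO"
                                   else "CYTO"
    }
    graph
}

#' Boundary-overlap ratio of a mitochondria region
#'
#' The fraction of the total boundary of mitochondria region `m` that it
#' shares with neighbour `c`:
#' \deqn{\rho(\{m, c\}) = \frac{\mathrm{face}(\{m, c\})}
#'       {\sum_i \mathrm{face}(\{m, S_i\})}}
#' summed over all live neighbours of `m` (both kinds; the image exterior
#' contributes nothing, so a fully enclosed organelle reaches rho = 1).
#'
#' @param graph a [RegionGraph-class] with kind tags.
#' @param m a MITO region id.
#' @param c a neighbouring CYTO region id.
#' @return rho in [0, 1].
#' @export
overlapRatio <- function(graph, m, c) {
    if (is.null(graph@edges[[edgeKey(m, c)]]))
        stop("regions ", m, " and ", c, " are not adjacent")
    nbr <- neighbourIds(graph, m)
    total <- sum(vapply(nbr, function(b)
        graph@edges[[edgeKey(m, b)]]$faceSize, numeric(1)))
    if (total == 0) stop("region ", m, " has zero total face size")
    graph@edges[[edgeKey(m, c)]]$faceSize / total
}

#' The mitochondria-absorption confidence h_m = 1 - rho
#'
#' A FUNCTION-mode predictor defined on mitochondria-cytoplasm boundaries:
#' the less of its boundary a mitochondrion shares with a neighbour, the
#' more confident we are the boundary should stand. Merging in increasing
#' h_m order is merging in decreasing overlap-ratio order.
#'
#' @return a [ConfidencePredictor-class].
#' @export
mitoOverlapPredictor <- function() {
    functionPredictor(function(graph, key) {
        ends <- keyEnds(key)
        ka <- graph@nodes[[as.character(ends[1])]]$kind
        kb <- graph@nodes[[as.character(ends[2])]]$kind
        if (ka == kb)
            stop("overlap confidence is defined on MITO-CYTO edges only: ",
                 key)
        m <- if (ka == "MITO") ends[1] else ends[2]
        c <- if (ka == "MITO") ends[2] else ends[1]
        1 - overlapRatio(graph, m, c)
    })
}

#' @noRd
mitoCytoEdge <- function(graph, key) {
    ends <- keyEnds(key)
    graph@nodes[[as.character(ends[1])]]$kind !=
        graph@nodes[[as.character(ends[2])]]$kind
}

#' @noRd
cytoCytoEdge <- function(graph, key) {
    ends <- keyEnds(key)
    graph@nodes[[as.character(ends[1])]]$kind == "CYTO" &&
        graph@nodes[[as.character(ends[2])]]$kind == "CYTO"
}

#' Phase 2: absorb mitochondria into cytoplasm bodies
#'
#' Delayed agglomeration with h_m = 1 - rho, candidates restricted to
#' mitochondria-cytoplasm boundaries (mitochondria-mitochondria boundaries
#' are never considered); equivalently, mitochondria merge in descending
#' order of overlap ratio. A merged body is tagged CYTO, so a chain of
#' stacked mitochondria is absorbed stepwise: once the outer blob joins the
#' cell body, the combined region identifies the next blob with the largest
#' overlap. Mitochondria whose every h_m exceeds `deltaM` are left intact
#' and reported.
#'
#' @param graph phase-1 output [RegionGraph-class] with kind tags.
#' @param deltaM stopping threshold on h_m (default 0.5: absorb when at
#'   least half the mitochondrion boundary touches the target).
#' @param maxMerges safety cap.
#' @return the graph after absorption; `runReport()` describes the phase.
#' @export
absorbMitochondria <- function(graph, deltaM = 0.5, maxMerges = Inf) {
    delayedAgglomerate(graph, mitoOverlapPredictor(), deltaM,
                       maxMerges = maxMerges, eligible = mitoCytoEdge,
                       mergedKind = "CYTO")
}

#' Context-aware two-phase segmentation
#'
#' Phase 1 clusters cytoplasm regions only (candidates restricted to
#' CYTO-CYTO boundaries) by delayed agglomeration under the trained
#' boundary classifier `hc` with threshold `deltaC`; phase 2 absorbs
#' mitochondria into the resulting cell bodies by overlap ratio
#' ([absorbMitochondria()]). Returns the exported label volume together
#' with both phase reports.
#'
#' @param labels superpixel [LabelVolume-class].
#' @param probs aligned [ProbabilityMaps-class].
#' @param hc boundary-confidence predictor for cytoplasm clustering.
#' @param deltaC cytoplasm stopping threshold (the operating range of the
#'   boundary classifier is typically 0.1-0.2).
#' @param deltaM mitochondria stopping threshold on h_m.
#' @param mitoProbThreshold kind-partition threshold.
#' @param connectivity RAG connectivity (see [buildRAG()]).
#' @return list with `labels` (the segmentation), `graph` (final
#'   [RegionGraph-class]), `phase1` and `phase2` (run reports), and
#'   `unabsorbedMito` (ids of mitochondria left intact).
#' @export
cadaSegment <- function(labels, probs, hc, deltaC = 0.14, deltaM = 0.5,
                        mitoProbThreshold = 0.5,
                        connectivity = c("face", "full")) {
    if (!is(labels, "LabelVolume")) labels <- LabelVolume(labels)
    graph <- buildRAG(labels, probs, match.arg(connectivity))
    graph <- partitionKinds(graph, mitoProbThreshold = mitoProbThreshold)
    graph <- delayedAgglomerate(graph, hc, deltaC, eligible = cytoCytoEdge)
    phase1 <- runReport(graph)
    graph <- absorbMitochondria(graph, deltaM = deltaM)
    phase2 <- runReport(graph)
    kinds <- vapply(graph@nodes, `[[`, character(1), "kind")
    list(labels = exportLabels(graph, labels), graph = graph,
         phase1 = phase1, phase2 = phase2,
         unabsorbedMito = as.integer(names(kinds)[kinds == "MITO"]))
}
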