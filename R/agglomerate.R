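# shared helpers -------------------------------------------------------------

#' @noRd
recomputeConfidence <- function(graph, h, keys) {
    if (length(keys) == 0) return(graph)
    conf <- predictConfidence(h, graph, keys)
    for (i in seq_along(keys))
        graph@edges[[keys[i]]]$conf <- conf[i]
    graph
}

# minimal-confidence edge among `keys`; ties broken lexicographically on the
# (smaller id, larger id) pair so runs are deterministic
#' @noRd
popMinEdge <- function(graph, keys) {
    conf <- vapply(keys, function(k) graph@edges[[k]]$conf, numeric(1))
    m <- min(conf)
    cand <- keys[conf <= m]
    if (length(cand) > 1) {
        ends <- t(vapply(cand, keyEnds, integer(2)))
        cand <- cand[order(ends[, 1], ends[, 2])]
    }
    list(key = cand[1], conf = m)
}

# survivor is the larger region (ties: smaller id), matching the convention
# that a merged body keeps the identity of its dominant part
#' @noRd
chooseSurvivor <- function(graph, key) {
    ends <- keyEnds(key)
    sa <- graph@nodes[[as.character(ends[1])]]$size
    sb <- graph@nodes[[as.character(ends[2])]]$size
    if (sb > sa) c(ends[2], ends[1]) else ends
}

#' @noRd
emptyReport <- function(mode, delta) {
    list(mode = mode, delta = delta, rounds = 1L, merges = 0L,
         mergesPerRound = integer(0), confAtMerge = numeric(0),
         flagTally = c(ACTIVE = 0L, DELAY = 0L),
         initialNodes = 0L, initialEdges = 0L,
         finalNodes = 0L, finalEdges = 0L)
}

# engines ---------------------------------------------------------------------

#' Standard agglomerative clustering
#'
#' Repeatedly merges the boundary with the globally smallest confidence
#' h(e), as long as h(e) <= delta; after each merge the confidences of all
#' boundaries incident to the merged body are recomputed. Terminates when
#' the minimum confidence exceeds the threshold. The confidence at each
#' merge is recorded in the merge log.
#'
#' @param graph an initial [RegionGraph-class].
#' @param h a [ConfidencePredictor-class].
#' @param delta stopping threshold in [0, 1].
#' @param maxMerges optional safety cap on the number of merges.
#' @param onPop optional callback `function(graph, key)` invoked for every
#'   edge popped for a merge decision (training-set harvesting).
#' @return the agglomerated graph; `runReport()` summarizes the run.
#' @export
standardAgglomerate <- function(graph, h, delta, maxMerges = Inf,
                                onPop = NULL) {
    report <- emptyReport("standard", delta)
    report$initialNodes <- length(graph@nodes)
    report$initialEdges <- length(graph@edges)
    logStart <- length(graph@mergeLog)
    graph <- recomputeConfidence(graph, h, edgeKeys(graph))
    merges <- 0L
    repeat {
        keys <- edgeKeys(graph)
        if (length(keys) == 0) break
        pop <- popMinEdge(graph, keys)
        if (pop$conf > delta) break
        if (!is.null(onPop)) onPop(graph, pop$key)
        ends <- chooseSurvivor(graph, pop$key)
        graph <- mergeRegions(graph, ends[1], ends[2],
                              confidence = pop$conf, round = 1L)
        touched <- vapply(graph@lastMerge$affected, `[[`, character(1),
                          "key")
        graph <- recomputeConfidence(graph, h, touched)
        merges <- merges + 1L
        if (merges >= maxMerges) break
    }
    report$merges <- merges
    report$mergesPerRound <- merges
    report$confAtMerge <- vapply(graph@mergeLog[seq_len(merges) + logStart],
                                 `[[`, numeric(1), "confidence")
    report$finalNodes <- length(graph@nodes)
    report$finalEdges <- length(graph@edges)
    graph@report <- report
    graph
}

#' Delayed agglomerative clustering
#'
#' Like [standardAgglomerate()], but merge decisions on newly formed bodies
#' are postponed: all initial boundaries start ACTIVE, and only ACTIVE
#' boundaries are candidates. After a merge, every boundary of the merged
#' body is re-examined: it stays ACTIVE only if its recomputed confidence
#' strictly exceeds its pre-merge value; otherwise it is flagged DELAY and
#' set aside, so the engine never acts on a confidence that just dropped.
#' When no ACTIVE boundary remains below the threshold, all DELAY
#' boundaries with h(e) <= delta are reactivated in one batch and a new
#' round begins. The process terminates when neither set contains a
#' mergeable boundary.
#'
#' A boundary combined from two parallel boundaries takes the minimum of the
#' two prior confidences as its "previous" value; a boundary that becomes
#' eligible for the first time (e.g. a mitochondria-mitochondria boundary
#' rerouted onto an absorbed body in phase 2) enters ACTIVE.
#'
#' @inheritParams standardAgglomerate
#' @param eligible optional predicate `function(graph, key)`; ineligible
#'   boundaries are never candidates (used by the context-aware phases).
#' @param mergedKind optional kind tag forced onto every merged body (phase
#'   2 tags absorbed bodies CYTO).
#' @return the agglomerated graph; `runReport()` summarizes rounds and
#'   flags.
#' @export
delayedAgglomerate <- function(graph, h, delta, maxMerges = Inf,
                               eligible = NULL, onPop = NULL,
                               mergedKind = NULL) {
    report <- emptyReport("delayed", delta)
    report$initialNodes <- length(graph@nodes)
    report$initialEdges <- length(graph@edges)
    logStart <- length(graph@mergeLog)

    isEligible <- function(g, k) is.null(eligible) || eligible(g, k)
    eligKeys <- Filter(function(k) isEligible(graph, k), edgeKeys(graph))
    for (k in edgeKeys(graph)) graph@edges[[k]]$flag <- "ACTIVE"
    graph <- recomputeConfidence(graph, h, eligKeys)

    round <- 1L
    merges <- 0L
    mergesPerRound <- integer(0)
    roundMerges <- 0L
    repeat {
        keys <- Filter(function(k) isEligible(graph, k), edgeKeys(graph))
        if (length(keys) == 0) break
        flags <- vapply(keys, function(k) graph@edges[[k]]$flag,
                        character(1))
        conf <- vapply(keys, function(k) graph@edges[[k]]$conf, numeric(1))
        active <- keys[flags == "ACTIVE" & conf <= delta]
        if (length(active) == 0) {
            toWake <- keys[flags == "DELAY" & conf <= delta]
            if (length(toWake) == 0) break
            for (k in toWake) graph@edges[[k]]$flag <- "ACTIVE"
            mergesPerRound <- c(mergesPerRound, roundMerges)
            roundMerges <- 0L
            round <- round + 1L
            next
        }
        pop <- popMinEdge(graph, active)
        # lazy freshness check: a FUNCTION-mode h may depend on state the
        # incident-edge recompute does not cover; a raised key is pushed
        # back instead of merged
        fresh <- predictConfidence(h, graph, pop$key)
        if (fresh > pop$conf + 1e-12) {
            graph@edges[[pop$key]]$conf <- fresh
            next
        }
        if (!is.null(onPop)) onPop(graph, pop$key)
        ends <- chooseSurvivor(graph, pop$key)
        graph <- mergeRegions(graph, ends[1], ends[2], newKind = mergedKind,
                              confidence = pop$conf, round = round)
        affected <- graph@lastMerge$affected
        touched <- vapply(affected, `[[`, character(1), "key")
        stillElig <- vapply(touched,
                            function(k) isEligible(graph, k), logical(1))
        graph <- recomputeConfidence(graph, h, touched[stillElig])
        for (i in seq_along(affected)) {
            a <- affected[[i]]
            if (!stillElig[i]) next
            # "previous" confidence of each edge of the merged body: its
            # own pre-merge value (survivor side), the absorbed-side value
            # (rerouted), or the smaller of the two (parallel combination)
            prev <- switch(a$type,
                survivorOnly = a$prevSurv,
                rerouted = a$prevAbs,
                combined = suppressWarnings(
                    min(a$prevAbs, a$prevSurv, na.rm = TRUE)))
            newConf <- graph@edges[[a$key]]$conf
            graph@edges[[a$key]]$flag <-
                if (is.na(prev) || !is.finite(prev)) "ACTIVE"
                else if (newConf > prev) "ACTIVE"
                else "DELAY"
        }
        merges <- merges + 1L
        roundMerges <- roundMerges + 1L
        if (merges >= maxMerges) break
    }
    mergesPerRound <- c(mergesPerRound, roundMerges)
    flags <- vapply(edgeKeys(graph),
                    function(k) graph@edges[[k]]$flag, character(1))
    report$rounds <- round
    report$merges <- merges
    report$mergesPerRound <- mergesPerRound
    report$confAtMerge <- vapply(graph@mergeLog[seq_len(merges) + logStart],
                                 `[[`, numeric(1), "confidence")
    report$flagTally <- c(ACTIVE = sum(flags == "ACTIVE"),
                          DELAY = sum(flags == "DELAY"))
    report$finalNodes <- length(graph@nodes)
    report$finalEdges <- length(graph@edges)
    graph@report <- report
    graph
}

#' Summarize an agglomeration run
#'
#' Merge counts per round, per-flag edge tallies and a histogram of the
#' confidences at which merges happened.
#'
#' @param graph a graph returned by one of the engines.
#' @param breaks histogram breaks over [0, 1].
#' @return list with fields `mode`, `delta`, `rounds`, `merges`,
#'   `mergesPerRound`, `flagTally`, `confHist`.
#' @export
runReport <- function(graph, breaks = seq(0, 1, by = 0.05)) {
    rep <- graph@report
    if (length(rep) == 0) stop("graph carries no agglomeration report")
    conf <- rep$confAtMerge
    hist <- if (length(conf) == 0)
        integer(length(breaks) - 1)
    else
        tabulate(findInterval(conf, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
    list(mode = rep$mode, delta = rep$delta, rounds = rep$rounds,
         merges = rep$merges, mergesPerRound = rep$mergesPerRound,
         flagTally = rep$flagTally,
         confHist = setNames(hist, paste0("[", head(breaks, -1), ",",
                                          tail(breaks, -1), ")")),
         initialNodes = rep$initialNodes, finalNodes = rep$finalNodes)
}
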