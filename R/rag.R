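# Grouped mergeable statistics: one summary per group id, built vectorized.
#' @noRd
groupedStats <- function(group, values, nBins = 64L) {
    nc <- ncol(values)
    ug <- sort(unique(group))
    gi <- match(group, ug)
    ng <- length(ug)
    cnt <- tabulate(gi, nbins = ng)
    sums <- rowsum(values, gi)
    sqs <- rowsum(values^2, gi)
    bins <- floor(values * nBins) + 1L
    bins[bins > nBins] <- nBins
    hist <- vector("list", nc)
    for (c in seq_len(nc)) {
        idx <- (gi - 1L) * nBins + bins[, c]
        hist[[c]] <- matrix(tabulate(idx, nbins = ng * nBins),
                            nrow = ng, byrow = TRUE)
    }
    out <- vector("list", ng)
    for (g in seq_len(ng)) {
        h <- matrix(0L, nrow = nc, ncol = nBins)
        for (c in seq_len(nc)) h[c, ] <- hist[[c]][g, ]
        out[[g]] <- structure(list(count = cnt[g], s = sums[g, ],
                                   ss = sqs[g, ], hist = h),
                              class = "mergeable_stats")
    }
    names(out) <- as.character(ug)
    out
}

# Adjacent unequal-label pixel pairs along one arbitrary offset (R fallback
# used for diagonal adjacency under "full" connectivity).
#' @noRd
offsetPairs <- function(arr, off, bg) {
    d <- dim(arr)
    nd <- length(d)
    idx1 <- lapply(seq_len(nd), function(i) {
        if (off[i] >= 0) seq_len(d[i] - off[i]) else seq(1 - off[i], d[i])
    })
    idx2 <- lapply(seq_len(nd), function(i) idx1[[i]] + off[i])
    lin <- array(seq_along(arr), dim = d)
    a1 <- as.vector(do.call(`[`, c(list(arr), idx1, list(drop = FALSE))))
    a2 <- as.vector(do.call(`[`, c(list(arr), idx2, list(drop = FALSE))))
    p1 <- as.vector(do.call(`[`, c(list(lin), idx1, list(drop = FALSE))))
    p2 <- as.vector(do.call(`[`, c(list(lin), idx2, list(drop = FALSE))))
    sel <- a1 != a2 & a1 != bg & a2 != bg
    a1 <- a1[sel]; a2 <- a2[sel]; p1 <- p1[sel]; p2 <- p2[sel]
    swap <- a1 > a2
    list(a = ifelse(swap, a2, a1), b = ifelse(swap, a1, a2),
         pa = ifelse(swap, p2, p1), pb = ifelse(swap, p1, p2))
}

#' @noRd
diagonalOffsets <- function(nd) {
    grid <- do.call(expand.grid, rep(list(-1L:1L), nd))
    keep <- apply(grid, 1, function(o) {
        nz <- sum(o != 0)
        if (nz < 2) return(FALSE)           # axis offsets handled in C++
        first <- o[which(o != 0)[1]]
        first > 0                           # one direction per pair
    })
    lapply(which(keep), function(i) as.integer(grid[i, ]))
}

#' Build the region adjacency graph of a superpixel map
#'
#' One node per non-background label; an edge joins two labels iff their
#' pixel sets touch under the chosen connectivity. Node statistics summarize
#' the probability channels over each region's pixels; edge statistics
#' summarize them over the boundary samples: both endpoint pixels of every
#' adjacent pixel pair across the boundary, with multiplicity. (Per-pair
#' sampling keeps the sample sets of parallel edges disjoint, so combining
#' them after a merge is an exact constant-time union; a once-per-pixel
#' convention would double-count pixels adjacent to both constituents.)
#' `faceSize` counts adjacent pixel pairs across the boundary. Background
#' pixels contribute to no node and no edge.
#'
#' @param labels a [LabelVolume-class] (or plain integer array).
#' @param probs a [ProbabilityMaps-class] (or array with trailing channel
#'   dimension) with the same spatial shape.
#' @param connectivity "face" (4-neighbourhood in 2D, 6 in 3D; the default)
#'   or "full" (diagonal contacts also count as adjacency).
#' @param nBins histogram bins for the mergeable statistics.
#' @return a [RegionGraph-class].
#' @export
buildRAG <- function(labels, probs, connectivity = c("face", "full"),
                     nBins = 64L) {
    connectivity <- match.arg(connectivity)
    if (!is(labels, "LabelVolume")) labels <- LabelVolume(labels)
    if (!is(probs, "ProbabilityMaps")) probs <- ProbabilityMaps(probs)
    d <- dim(labels@data)
    dp <- head(dim(probs@data), -1)
    if (!identical(as.integer(d), as.integer(dp)))
        stop(sprintf("shape mismatch: labels %s vs probability maps %s",
                     paste(d, collapse = "x"), paste(dp, collapse = "x")))
    bg <- labels@backgroundLabel
    arr <- labels@data
    ids <- labelIds(labels)
    if (length(ids) < 2)
        stop("need at least 2 distinct non-background labels, found ",
             length(ids))
    nc <- length(probs@channelNames)
    P <- matrix(probs@data, ncol = nc)
    P[P < 0] <- 0; P[P > 1] <- 1

    pr <- cpp_adjacent_pairs(as.integer(arr), as.integer(d), as.integer(bg))
    if (connectivity == "full") {
        for (off in diagonalOffsets(length(d))) {
            ex <- offsetPairs(arr, off, bg)
            pr$a <- c(pr$a, ex$a); pr$b <- c(pr$b, ex$b)
            pr$pa <- c(pr$pa, ex$pa); pr$pb <- c(pr$pb, ex$pb)
        }
    }
    pairDT <- data.table(a = as.integer(pr$a), b = as.integer(pr$b),
                         pa = as.numeric(pr$pa), pb = as.numeric(pr$pb))
    faceDT <- pairDT[, .(faceSize = .N), by = .(a, b)]

    # boundary samples: both endpoint pixels of every adjacent pair (with
    # multiplicity), so that combining parallel edges after a merge is an
    # exact field-wise union of disjoint sample sets
    bnd <- rbind(pairDT[, .(a, b, p = pa)], pairDT[, .(a, b, p = pb)])
    bnd[, key := paste0(a, "-", b)]
    edgeStats <- if (nrow(bnd) > 0)
        groupedStats(bnd$key, P[bnd$p, , drop = FALSE], nBins)
    else list()

    vec <- as.vector(arr)
    fg <- which(vec != bg)
    nodeStats <- groupedStats(vec[fg], P[fg, , drop = FALSE], nBins)

    sizes <- regionSizes(labels)
    nodes <- vector("list", length(ids))
    names(nodes) <- as.character(ids)
    for (i in seq_along(ids)) {
        id <- ids[i]
        nodes[[i]] <- list(id = id, members = id, kind = "CYTO",
                           size = sizes[[as.character(id)]],
                           stats = nodeStats[[as.character(id)]])
    }

    edges <- vector("list", nrow(faceDT))
    keys <- if (nrow(faceDT) > 0) paste0(faceDT$a, "-", faceDT$b)
            else character(0)
    names(edges) <- keys
    for (i in seq_len(nrow(faceDT))) {
        edges[[i]] <- list(a = faceDT$a[i], b = faceDT$b[i],
                           faceSize = faceDT$faceSize[i],
                           stats = edgeStats[[keys[i]]],
                           conf = NA_real_, flag = "ACTIVE")
    }

    adj <- lapply(setNames(ids, as.character(ids)), function(id) {
        sort(c(faceDT$b[faceDT$a == id], faceDT$a[faceDT$b == id]))
    })

    new("RegionGraph", nodes = nodes, edges = edges, adj = adj,
        mergeLog = list(), nChannels = as.integer(nc),
        channelNames = probs@channelNames, lastMerge = list(),
        report = list())
}

#' Merge two adjacent regions
#'
#' The absorbed node is removed; the survivor takes the exact union of sizes,
#' member sets and statistics. Every boundary of the absorbed region is
#' rerouted to the survivor; where a parallel boundary to a common neighbour
#' already exists the two combine (face sizes and statistics summed, cached
#' confidence invalidated). The merge is appended to the merge log.
#' `graph@lastMerge` records, for every edge incident to the merged node,
#' whether it was rerouted, combined, or untouched on the survivor side,
#' together with the pre-merge cached confidences -- the scheduling rule of
#' the delayed engine consumes this.
#'
#' @param graph a [RegionGraph-class].
#' @param survivor,absorbed adjacent region ids; `absorbed` disappears.
#' @param newKind optional kind tag for the merged region (default: the
#'   survivor keeps its kind).
#' @param confidence confidence at merge time, recorded in the merge log.
#' @param round agglomeration round, recorded in the merge log.
#' @return the updated graph.
#' @export
mergeRegions <- function(graph, survivor, absorbed, newKind = NULL,
                         confidence = NA_real_, round = 1L) {
    sKey <- as.character(survivor); aKey <- as.character(absorbed)
    sNode <- graph@nodes[[sKey]]; aNode <- graph@nodes[[aKey]]
    if (is.null(sNode)) stop("unknown region id: ", survivor)
    if (is.null(aNode)) stop("unknown region id: ", absorbed)
    if (survivor == absorbed) stop("cannot merge a region with itself")
    mKey <- edgeKey(survivor, absorbed)
    if (is.null(graph@edges[[mKey]]))
        stop("regions ", survivor, " and ", absorbed, " are not adjacent")

    affected <- list()
    sNbr <- graph@adj[[sKey]]
    aNbr <- graph@adj[[aKey]]

    # survivor-side edges untouched by the reroute
    for (b in setdiff(sNbr, c(absorbed, aNbr))) {
        k <- edgeKey(survivor, b)
        affected[[length(affected) + 1]] <- list(
            neighbour = b, key = k, type = "survivorOnly",
            prevAbs = NA_real_, prevSurv = graph@edges[[k]]$conf)
    }

    for (b in setdiff(aNbr, survivor)) {
        oldKey <- edgeKey(absorbed, b)
        oldEdge <- graph@edges[[oldKey]]
        newKey <- edgeKey(survivor, b)
        if (b %in% sNbr) {
            ex <- graph@edges[[newKey]]
            combined <- ex
            combined$faceSize <- ex$faceSize + oldEdge$faceSize
            combined$stats <- statsUnion(ex$stats, oldEdge$stats)
            combined$conf <- NA_real_
            graph@edges[[newKey]] <- combined
            affected[[length(affected) + 1]] <- list(
                neighbour = b, key = newKey, type = "combined",
                prevAbs = oldEdge$conf, prevSurv = ex$conf)
        } else {
            moved <- oldEdge
            moved$a <- min(survivor, b)
            moved$b <- max(survivor, b)
            moved$conf <- NA_real_
            graph@edges[[newKey]] <- moved
            graph@adj[[sKey]] <- sort(c(graph@adj[[sKey]], b))
            graph@adj[[as.character(b)]] <-
                sort(c(setdiff(graph@adj[[as.character(b)]], absorbed),
                       survivor))
            affected[[length(affected) + 1]] <- list(
                neighbour = b, key = newKey, type = "rerouted",
                prevAbs = oldEdge$conf, prevSurv = NA_real_)
        }
        graph@edges[[oldKey]] <- NULL
        if (b %in% sNbr)
            graph@adj[[as.character(b)]] <-
                setdiff(graph@adj[[as.character(b)]], absorbed)
    }

    merged <- sNode
    merged$members <- c(sNode$members, aNode$members)
    merged$size <- sNode$size + aNode$size
    merged$stats <- statsUnion(sNode$stats, aNode$stats)
    if (!is.null(newKind)) merged$kind <- newKind
    graph@nodes[[sKey]] <- merged
    graph@nodes[[aKey]] <- NULL
    graph@edges[[mKey]] <- NULL
    graph@adj[[sKey]] <- setdiff(graph@adj[[sKey]], absorbed)
    graph@adj[[aKey]] <- NULL

    graph@mergeLog[[length(graph@mergeLog) + 1]] <- list(
        survivor = survivor, absorbed = absorbed, confidence = confidence,
        round = as.integer(round), survivorKind = sNode$kind,
        absorbedKind = aNode$kind)
    graph@lastMerge <- list(survivor = survivor, absorbed = absorbed,
                            affected = affected)
    graph
}

#' Export the current regions as a label volume
#'
#' Each pixel receives the id of the region owning its original superpixel;
#' background pixels are unchanged.
#'
#' @param graph a [RegionGraph-class] built from `original` (possibly after
#'   merges).
#' @param original the superpixel [LabelVolume-class] the graph was built
#'   from.
#' @return a [LabelVolume-class] of current region ids.
#' @export
exportLabels <- function(graph, original) {
    if (!is(original, "LabelVolume")) original <- LabelVolume(original)
    maxId <- max(original@data)
    lookup <- rep(NA_integer_, maxId + 1L)
    for (node in graph@nodes)
        lookup[node$members + 1L] <- node$id
    bg <- original@backgroundLabel
    if (bg <= maxId) lookup[bg + 1L] <- bg
    present <- setdiff(unique(as.vector(original@data)), bg)
    missing <- present[is.na(lookup[present + 1L])]
    if (length(missing) > 0)
        stop("superpixel id(s) absent from graph: ",
             paste(head(missing, 5), collapse = ", "))
    out <- original
    out@data <- array(lookup[original@data + 1L], dim = dim(original@data))
    out
}
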