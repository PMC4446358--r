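# Independent oracles and literal reference implementations used across the
# test suite. Everything here is deliberately naive: full rescans, per-pixel
# loops, no caches.

# --- label-map utilities -----------------------------------------------------

randomLabelMap <- function(shape, nLabels, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    array(sample.int(nLabels, prod(shape), replace = TRUE), dim = shape)
}

uniformProbs <- function(shape, nChannels = 4) {
    arr <- array(runif(prod(shape) * nChannels), dim = c(shape, nChannels))
    m <- matrix(arr, ncol = nChannels)
    ProbabilityMaps(array(m / rowSums(m), dim = c(shape, nChannels)))
}

# adjacency + face sizes by scanning every axis-offset pixel pair
bruteAdjacency <- function(arr, bg = 0L) {
    d <- dim(arr)
    pairs <- list()
    addPair <- function(x, y) {
        if (x == y || x == bg || y == bg) return()
        key <- paste0(min(x, y), "-", max(x, y))
        pairs[[key]] <<- (pairs[[key]] %||% 0L) + 1L
    }
    `%||%` <- function(a, b) if (is.null(a)) b else a
    if (length(d) == 2) {
        for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
            if (i < d[1]) addPair(arr[i, j], arr[i + 1, j])
            if (j < d[2]) addPair(arr[i, j], arr[i, j + 1])
        }
    } else {
        for (i in seq_len(d[1])) for (j in seq_len(d[2]))
            for (k in seq_len(d[3])) {
                if (i < d[1]) addPair(arr[i, j, k], arr[i + 1, j, k])
                if (j < d[2]) addPair(arr[i, j, k], arr[i, j + 1, k])
                if (k < d[3]) addPair(arr[i, j, k], arr[i, j, k + 1])
            }
    }
    pairs
}

# union-find relabelling of a pixel map through a merge sequence
ufRelabel <- function(arr, merges) {
    ids <- sort(unique(as.vector(arr)))
    parent <- stats::setNames(ids, ids)
    find <- function(x) {
        while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
        x
    }
    for (m in merges)
        parent[[as.character(find(m[2]))]] <- find(m[1])
    lookup <- vapply(ids, find, numeric(1))
    map <- stats::setNames(lookup, ids)
    array(map[as.character(arr)], dim = dim(arr))
}

canonicalPartition <- function(members) {
    parts <- lapply(members, function(m) sort(as.integer(m)))
    parts <- parts[order(vapply(parts, `[`, integer(1), 1))]
    unname(parts)
}

graphPartition <- function(graph) {
    canonicalPartition(lapply(graph@nodes, `[[`, "members"))
}

# --- split metric oracles ----------------------------------------------------

entropySplitVI <- function(gt, sg) {
    tab <- table(as.vector(gt), as.vector(sg))
    p <- tab / sum(tab)
    pg <- rowSums(p); pr <- colSums(p)
    term <- function(p, marg) {
        x <- 0
        for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
            if (p[i, j] > 0) x <- x - p[i, j] * log(p[i, j] / marg[[i]])
        x
    }
    # H(SG|GT): condition on the GT marginal; H(GT|SG): on the SG marginal
    c(oe = term(p, pg), ue = term(t(p), pr))
}

brutePairRand <- function(gt, sg) {
    g <- as.vector(gt); r <- as.vector(sg)
    n <- length(g)
    sameG <- outer(g, g, "==")
    sameR <- outer(r, r, "==")
    up <- upper.tri(sameG)
    total <- sum(up)
    c(oe = sum(sameG[up] & !sameR[up]) / total,
      ue = sum(sameR[up] & !sameG[up]) / total,
      fm = sum(sameR[up] & !sameG[up]),
      fs = sum(sameG[up] & !sameR[up]))
}

# --- synthetic region graphs for the engine tests ----------------------------

# random connected simple graph on n nodes: spanning tree + extra edges
randomConnectedGraph <- function(n, extraProb = 0.25) {
    edges <- list()
    for (v in 2:n)
        edges[[length(edges) + 1]] <- c(sample.int(v - 1, 1), v)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (any(vapply(edges, function(e) all(e == c(a, b)), logical(1))))
            next
        if (runif(1) < extraProb) edges[[length(edges) + 1]] <- c(a, b)
    }
    edges
}

randomTree <- function(n) {
    edges <- list()
    for (v in 2:n)
        edges[[length(edges) + 1]] <- c(sample.int(v - 1, 1), v)
    edges
}

# RegionGraph over abstract nodes (unit sizes unless given); single dummy
# channel so mergeable statistics stay well-formed
makeSyntheticGraph <- function(n, edges, sizes = rep(1, n)) {
    nodes <- lapply(seq_len(n), function(i) {
        list(id = i, members = i, kind = "CYTO", size = sizes[i],
             stats = statsFromValues(matrix(0.5, nrow = 1)))
    })
    names(nodes) <- as.character(seq_len(n))
    es <- list()
    adj <- lapply(seq_len(n), function(i) integer(0))
    names(adj) <- as.character(seq_len(n))
    for (e in edges) {
        a <- min(e); b <- max(e)
        key <- paste0(a, "-", b)
        es[[key]] <- list(a = a, b = b, faceSize = 1,
                          stats = statsFromValues(matrix(0.5, nrow = 1)),
                          conf = NA_real_, flag = "ACTIVE")
        adj[[as.character(a)]] <- sort(c(adj[[as.character(a)]], b))
        adj[[as.character(b)]] <- sort(c(adj[[as.character(b)]], a))
    }
    new("RegionGraph", nodes = nodes, edges = es, adj = adj,
        mergeLog = list(), nChannels = 1L,
        channelNames = "cell.boundary", lastMerge = list(), report = list())
}

# deterministic confidence as a pure function of the two member sets; with
# dynamicWeight = 0 the value depends only on which original nodes face each
# other, with > 0 it shifts as regions grow (merge-dependent h)
makeSetH <- function(n, dynamicWeight = 0.31, seed = 1) {
    set.seed(seed)
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2
    function(membersA, membersB) {
        base <- sum(W[membersA, membersB])
        x <- base + dynamicWeight * (length(membersA) + length(membersB))
        x - floor(x)
    }
}

setHPredictor <- function(hFun) {
    functionPredictor(function(graph, key) {
        ends <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
        hFun(graph@nodes[[as.character(ends[1])]]$members,
             graph@nodes[[as.character(ends[2])]]$members)
    })
}

# --- literal reference engines ----------------------------------------------
# Naive line-by-line implementations of the two agglomeration algorithms:
# confidences are recomputed for every edge at every step, there are no
# caches and no incremental bookkeeping. Conventions shared with the
# package engines: survivor = larger region (ties: smaller id), pop ties
# broken lexicographically on the id pair.

refState <- function(n, edges, sizes = rep(1, n)) {
    members <- lapply(seq_len(n), identity)
    names(members) <- as.character(seq_len(n))
    ekeys <- unique(vapply(edges, function(e)
        paste0(min(e), "-", max(e)), character(1)))
    list(members = members, sizes = stats::setNames(sizes,
                                                    as.character(1:n)),
         edges = ekeys)
}

refEdgeEnds <- function(key) as.integer(strsplit(key, "-",
                                                 fixed = TRUE)[[1]])

refH <- function(state, key, hFun) {
    e <- refEdgeEnds(key)
    hFun(state$members[[as.character(e[1])]],
         state$members[[as.character(e[2])]])
}

refPopMin <- function(state, keys, hFun) {
    h <- vapply(keys, function(k) refH(state, k, hFun), numeric(1))
    m <- min(h)
    cand <- keys[h == m]
    if (length(cand) > 1) {
        ends <- t(vapply(cand, refEdgeEnds, integer(2)))
        cand <- cand[order(ends[, 1], ends[, 2])]
    }
    list(key = cand[1], h = m)
}

refMerge <- function(state, key) {
    e <- refEdgeEnds(key)
    sa <- state$sizes[[as.character(e[1])]]
    sb <- state$sizes[[as.character(e[2])]]
    surv <- if (sb > sa) e[2] else e[1]
    abs <- setdiff(e, surv)
    sK <- as.character(surv); aK <- as.character(abs)
    state$members[[sK]] <- c(state$members[[sK]], state$members[[aK]])
    state$members[[aK]] <- NULL
    state$sizes[[sK]] <- sa + sb
    state$sizes <- state$sizes[names(state$sizes) != aK]
    newEdges <- character(0)
    rerouted <- character(0)
    for (k in state$edges) {
        ends <- refEdgeEnds(k)
        if (all(sort(ends) == sort(e))) next
        ends[ends == abs] <- surv
        if (ends[1] == ends[2]) next
        nk <- paste0(min(ends), "-", max(ends))
        if (abs %in% refEdgeEnds(k)) rerouted <- c(rerouted, nk)
        newEdges <- c(newEdges, nk)
    }
    state$edges <- unique(newEdges)
    state$lastRerouted <- unique(rerouted)
    state$lastSurvivor <- surv
    state
}

refStandard <- function(n, edges, hFun, delta, sizes = rep(1, n)) {
    state <- refState(n, edges, sizes)
    merges <- list()
    repeat {
        if (length(state$edges) == 0) break
        pop <- refPopMin(state, state$edges, hFun)
        if (pop$h > delta) break
        merges[[length(merges) + 1]] <- c(pop$key, pop$h)
        state <- refMerge(state, pop$key)
    }
    list(partition = canonicalPartition(state$members), merges = merges)
}

refDelayed <- function(n, edges, hFun, delta, sizes = rep(1, n)) {
    state <- refState(n, edges, sizes)
    flags <- stats::setNames(rep("ACTIVE", length(state$edges)),
                             state$edges)
    rounds <- 1L
    merges <- list()
    repeat {
        h <- vapply(state$edges, function(k) refH(state, k, hFun),
                    numeric(1))
        active <- state$edges[flags[state$edges] == "ACTIVE" & h <= delta]
        if (length(active) == 0) {
            wake <- state$edges[flags[state$edges] == "DELAY" & h <= delta]
            if (length(wake) == 0) break
            flags[wake] <- "ACTIVE"
            rounds <- rounds + 1L
            next
        }
        pop <- refPopMin(state, active, hFun)
        merges[[length(merges) + 1]] <- c(pop$key, pop$h)
        # pre-merge confidences of every edge, for the flag rule
        hBefore <- stats::setNames(h, state$edges)
        ends <- refEdgeEnds(pop$key)
        state2 <- refMerge(state, pop$key)
        surv <- state2$lastSurvivor
        absd <- setdiff(ends, surv)
        newFlags <- stats::setNames(rep("ACTIVE", length(state2$edges)),
                                    state2$edges)
        for (k in state2$edges) {
            kEnds <- refEdgeEnds(k)
            if (!(surv %in% kEnds)) {           # untouched edge
                newFlags[k] <- flags[k]
                next
            }
            b <- setdiff(kEnds, surv)
            oldAbs <- paste0(min(absd, b), "-", max(absd, b))
            oldSurv <- paste0(min(surv, b), "-", max(surv, b))
            hadAbs <- oldAbs %in% names(hBefore)
            hadSurv <- oldSurv %in% names(hBefore)
            prev <- if (hadAbs && hadSurv)
                        min(hBefore[[oldAbs]], hBefore[[oldSurv]])
                    else if (hadAbs) hBefore[[oldAbs]]
                    else hBefore[[oldSurv]]
            newFlags[k] <- if (refH(state2, k, hFun) > prev) "ACTIVE"
                           else "DELAY"
        }
        flags <- newFlags
        state <- state2
    }
    list(partition = canonicalPartition(state$members), merges = merges,
         rounds = rounds)
}
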