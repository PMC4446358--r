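#' Built-in confidence predictors
#'
#' `meanProbPredictor` returns, for each edge, the mean of one probability
#' channel over the boundary pixels (read from the edge's mergeable
#' statistics, so it stays exact under merges). `functionPredictor` wraps an
#' arbitrary `fn(graph, key) -> [0,1]`.
#'
#' @param channel probability channel to average (default cell boundary).
#' @return a [ConfidencePredictor-class].
#' @export
meanProbPredictor <- function(channel = "cell.boundary") {
    new("ConfidencePredictor", mode = "MEAN_PROB", model = NULL,
        channel = channel, fn = NULL, featureConfig = list())
}

#' @rdname meanProbPredictor
#' @param fn function of (graph, key) returning a confidence in [0, 1].
#' @export
functionPredictor <- function(fn) {
    new("ConfidencePredictor", mode = "FUNCTION", model = NULL,
        channel = NA_character_, fn = fn, featureConfig = list())
}

#' Evaluate a confidence predictor on edges
#'
#' Deterministic given the predictor and the graph state; always in [0, 1].
#'
#' @param predictor a [ConfidencePredictor-class].
#' @param graph a [RegionGraph-class].
#' @param keys edge key(s).
#' @return numeric vector of confidences, one per key.
#' @export
predictConfidence <- function(predictor, graph, keys) {
    if (length(keys) == 0) return(numeric(0))
    out <- switch(predictor@mode,
        MEAN_PROB = {
            ci <- match(predictor@channel, graph@channelNames)
            if (is.na(ci)) stop("unknown channel: ", predictor@channel)
            vapply(keys, function(k) {
                e <- graph@edges[[k]]
                if (is.null(e)) stop("unknown edge: ", k)
                statsMean(e$stats)[ci]
            }, numeric(1))
        },
        CLASSIFIER = {
            if (is.null(predictor@model))
                stop("CLASSIFIER predictor has no trained model")
            X <- edgeFeatureMatrix(graph, keys,
                                   predictor@featureConfig)
            if (!identical(colnames(X), predictor@model$featureNames))
                stop("feature layout mismatch between graph and model")
            df <- as.data.frame(X)
            pr <- predict(predictor@model$rf, data = df,
                          num.threads = 1)$predictions
            as.numeric(pr[, "1"])
        },
        FUNCTION = vapply(keys, function(k) predictor@fn(graph, k),
                          numeric(1)),
        stop("unknown predictor mode"))
    pmin(pmax(unname(out), 0), 1)
}

#' Train the random-forest boundary classifier
#'
#' Fits a probability random forest on edge feature vectors with 0/1
#' boundary labels; the confidence of an edge is the forest's class-1
#' probability (fraction-of-trees vote). An optional depth limit caps every
#' tree (the depth-limited variant is trained in a single pass, without
#' training-set accumulation). Training is reproducible given `seed`.
#'
#' @param features numeric feature matrix from [edgeFeatureMatrix()].
#' @param labels 0/1 vector: 1 = true boundary (keep), 0 = false boundary
#'   (merge).
#' @param numTrees number of trees (default 100).
#' @param maxDepth tree depth limit; NULL for unlimited, 20 for the
#'   depth-limited variant.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param config the [featureConfig()] the features were built with.
#' @return a CLASSIFIER-mode [ConfidencePredictor-class].
#' @export
trainBoundaryClassifier <- function(features, labels, numTrees = 100L,
                                    maxDepth = 20L, seed,
                                    config = featureConfig()) {
    if (missing(seed)) stop("a seed is required for reproducible training")
    labels <- as.integer(labels)
    tab <- table(factor(labels, levels = c(0, 1)))
    if (any(tab == 0))
        stop(sprintf(
            "training set must contain both classes (class 0: %d, class 1: %d)",
            tab[1], tab[2]))
    df <- as.data.frame(features)
    df$.label <- factor(labels, levels = c(0, 1))
    rf <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = numTrees, probability = TRUE,
        max.depth = if (is.null(maxDepth)) 0 else maxDepth,
        seed = seed, num.threads = 1)
    new("ConfidencePredictor", mode = "CLASSIFIER",
        model = list(rf = rf, featureNames = colnames(features)),
        channel = NA_character_, fn = NULL, featureConfig = config)
}

#' Maximum tree depth of a trained forest
#'
#' @param predictor a CLASSIFIER-mode predictor.
#' @return the depth of the deepest tree (root at depth 0).
#' @export
forestMaxDepth <- function(predictor) {
    rf <- predictor@model$rf
    depths <- vapply(seq_len(rf$num.trees), function(t) {
        ti <- ranger::treeInfo(rf, t)
        # depth by walking parents: root row has nodeID 0
        depth <- integer(nrow(ti))
        parent <- rep(NA_integer_, max(ti$nodeID) + 1L)
        for (r in seq_len(nrow(ti))) {
            if (!is.na(ti$leftChild[r]))
                parent[ti$leftChild[r] + 1L] <- ti$nodeID[r]
            if (!is.na(ti$rightChild[r]))
                parent[ti$rightChild[r] + 1L] <- ti$nodeID[r]
        }
        dep <- integer(max(ti$nodeID) + 1L)
        for (nid in ti$nodeID) {
            d <- 0L; p <- parent[nid + 1L]
            while (!is.na(p)) { d <- d + 1L; p <- parent[p + 1L] }
            dep[nid + 1L] <- d
        }
        max(dep)
    }, integer(1))
    max(depths)
}

#' Ground-truth body assignment of current regions
#'
#' Assigns every live region the ground-truth body with maximal pixel
#' overlap, from per-superpixel overlap counts (so the assignment stays
#' exact after merges). Regions overlapping only ground-truth background
#' get NA and are excluded from training.
#'
#' @param graph a [RegionGraph-class].
#' @param original superpixel [LabelVolume-class] the graph was built from.
#' @param gt ground-truth [LabelVolume-class] aligned with `original`.
#' @return a `gt_assignment` object; see [regionGTBodies()].
#' @export
gtAssignment <- function(graph, original, gt) {
    if (!is(original, "LabelVolume")) original <- LabelVolume(original)
    if (!is(gt, "LabelVolume")) gt <- LabelVolume(gt)
    if (!identical(dim(original@data), dim(gt@data)))
        stop("superpixel map and ground truth shapes differ")
    sp <- as.vector(original@data)
    g <- as.vector(gt@data)
    keep <- sp != original@backgroundLabel & g != gt@backgroundLabel
    dt <- data.table(sp = sp[keep], g = g[keep])[, .(n = .N), by = .(sp, g)]
    structure(list(overlap = dt), class = "gt_assignment")
}

#' @rdname gtAssignment
#' @param ids region ids to assign (default: all live regions).
#' @param assignment a `gt_assignment` from [gtAssignment()].
#' @return `regionGTBodies`: data.frame with columns id, body (NA when the
#'   region overlaps no ground-truth body), majority (fraction of the
#'   region's counted pixels in that body).
#' @export
regionGTBodies <- function(graph, assignment, ids = NULL) {
    ids <- ids %||% as.integer(names(graph@nodes))
    ov <- assignment$overlap
    out <- data.frame(id = ids, body = NA_integer_, majority = NA_real_)
    for (i in seq_along(ids)) {
        node <- graph@nodes[[as.character(ids[i])]]
        sub <- ov[sp %in% node$members, .(n = sum(n)), by = g]
        if (nrow(sub) == 0) next
        j <- which.max(sub$n)
        out$body[i] <- sub$g[j]
        out$majority[i] <- sub$n[j] / sum(sub$n)
    }
    out
}

#' Ground-truth label of one edge
#'
#' The training label convention: an edge is a true boundary (label 1) if
#' its two regions map to different ground-truth bodies, or if it joins a
#' mitochondria region to a cytoplasm region (mitochondria-cytoplasm borders
#' are treated the same way as cell membrane during classifier training).
#' Regions without ground-truth overlap, or whose majority fraction falls
#' below `overlapThreshold`, yield NA (row excluded from training).
#'
#' @param graph a [RegionGraph-class] with kind tags.
#' @param key edge key.
#' @param assignment a `gt_assignment` from [gtAssignment()].
#' @param overlapThreshold minimum majority fraction to accept a region's
#'   assignment (default 0 = always accept).
#' @return 0, 1 or NA.
#' @export
gtEdgeLabel <- function(graph, key, assignment, overlapThreshold = 0) {
    e <- graph@edges[[key]]
    if (is.null(e)) stop("unknown edge: ", key)
    bodies <- regionGTBodies(graph, assignment, c(e$a, e$b))
    if (anyNA(bodies$body)) return(NA_integer_)
    if (any(bodies$majority < overlapThreshold)) return(NA_integer_)
    ka <- graph@nodes[[as.character(e$a)]]$kind
    kb <- graph@nodes[[as.character(e$b)]]$kind
    if (ka != kb) return(1L)
    if (bodies$body[1] != bodies$body[2]) 1L else 0L
}

# labels for many edges at once (vector of 0/1/NA)
#' @noRd
gtEdgeLabels <- function(graph, keys, assignment, overlapThreshold = 0) {
    if (length(keys) == 0) return(integer(0))
    ends <- t(vapply(keys, function(k) {
        e <- graph@edges[[k]]; c(e$a, e$b)
    }, integer(2)))
    ids <- unique(as.vector(ends))
    bodies <- regionGTBodies(graph, assignment, ids)
    body <- setNames(bodies$body, bodies$id)
    maj <- setNames(bodies$majority, bodies$id)
    kind <- vapply(as.character(ids),
                   function(i) graph@nodes[[i]]$kind, character(1))
    ba <- body[as.character(ends[, 1])]; bb <- body[as.character(ends[, 2])]
    ma <- maj[as.character(ends[, 1])]; mb <- maj[as.character(ends[, 2])]
    ka <- kind[as.character(ends[, 1])]; kb <- kind[as.character(ends[, 2])]
    lab <- ifelse(ka != kb, 1L, ifelse(ba != bb, 1L, 0L))
    lab[is.na(ba) | is.na(bb)] <- NA_integer_
    if (overlapThreshold > 0)
        lab[!is.na(ma) & !is.na(mb) &
            (ma < overlapThreshold | mb < overlapThreshold)] <- NA_integer_
    as.integer(lab)
}

#' Build a boundary-classifier training set
#'
#' Three regimes. `single`: one pass over the eligible edges of the initial
#' region graph (mitochondria-mitochondria edges are never eligible).
#' `iterative`: after training on pass k, delayed agglomeration is run on
#' the training volume with the current classifier; every edge popped for a
#' merge decision is harvested with its ground-truth label at that moment,
#' and only the newest pass's rows are kept for the next classifier.
#' `accumulated`: the same loop, but the union of all passes' rows is kept.
#' Rows are deduplicated within a pass.
#'
#' @param labels superpixel [LabelVolume-class].
#' @param probs aligned [ProbabilityMaps-class].
#' @param gt aligned ground-truth [LabelVolume-class].
#' @param regime "single", "iterative" or "accumulated".
#' @param kIters number of harvest passes (>= 1) for the iterative and
#'   accumulated regimes; ignored for "single".
#' @param delta stopping threshold for the harvest agglomerations.
#' @param mitoProbThreshold mean-mitochondria-probability threshold for the
#'   kind partition.
#' @param overlapThreshold see [gtEdgeLabel()].
#' @param numTrees,maxDepth,seed classifier settings for the intermediate
#'   passes.
#' @param config feature layout ([featureConfig()]).
#' @return list with `features` (matrix), `labels` (0/1), `pass` (integer
#'   provenance per row: 0 = initial, k = harvested in pass k), and
#'   `excluded` (rows dropped for missing ground-truth overlap).
#' @export
buildTrainingSet <- function(labels, probs, gt,
                             regime = c("single", "iterative", "accumulated"),
                             kIters = 2L, delta = 0.14,
                             mitoProbThreshold = 0.5, overlapThreshold = 0,
                             numTrees = 100L, maxDepth = 20L, seed = 1L,
                             config = featureConfig()) {
    regime <- match.arg(regime)
    if (regime != "single" && kIters < 1)
        stop("kIters must be >= 1 for the ", regime, " regime")
    graph <- buildRAG(labels, probs)
    graph <- partitionKinds(graph, mitoProbThreshold = mitoProbThreshold)
    assignment <- gtAssignment(graph, labels, gt)

    eligibleEdge <- function(g, k) {
        e <- g@edges[[k]]
        !(g@nodes[[as.character(e$a)]]$kind == "MITO" &&
          g@nodes[[as.character(e$b)]]$kind == "MITO")
    }

    harvestPass <- function(g, keys, pass) {
        X <- edgeFeatureMatrix(g, keys, config)
        y <- gtEdgeLabels(g, keys, assignment, overlapThreshold)
        ok <- !is.na(y)
        dup <- duplicated(cbind(X, y))
        keep <- ok & !dup
        list(features = X[keep, , drop = FALSE], labels = y[keep],
             pass = rep(as.integer(pass), sum(keep)),
             excluded = sum(!ok))
    }

    keys0 <- Filter(function(k) eligibleEdge(graph, k), edgeKeys(graph))
    rows <- harvestPass(graph, keys0, 0L)
    if (regime == "single") return(rows)

    allRows <- rows
    current <- rows
    for (k in seq_len(kIters)) {
        clf <- trainBoundaryClassifier(current$features, current$labels,
                                       numTrees = numTrees,
                                       maxDepth = maxDepth,
                                       seed = seed + k, config = config)
        popped <- new.env()
        popped$keys <- character(0)
        popped$feat <- list()
        popped$lab <- integer(0)
        onPop <- function(g, key) {
            popped$feat[[length(popped$feat) + 1]] <-
                edgeFeatureMatrix(g, key, config)
            popped$lab <- c(popped$lab,
                            gtEdgeLabels(g, key, assignment,
                                         overlapThreshold))
        }
        delayedAgglomerate(graph, clf, delta, eligible = eligibleEdge,
                           onPop = onPop)
        if (length(popped$feat) > 0) {
            X <- do.call(rbind, popped$feat)
            y <- popped$lab
            ok <- !is.na(y)
            dup <- duplicated(cbind(X, y))
            keep <- ok & !dup
            passRows <- list(features = X[keep, , drop = FALSE],
                             labels = y[keep],
                             pass = rep(k, sum(keep)),
                             excluded = sum(!ok))
        } else {
            passRows <- list(features = rows$features[0, , drop = FALSE],
                             labels = integer(0), pass = integer(0),
                             excluded = 0L)
        }
        allRows <- list(
            features = rbind(allRows$features, passRows$features),
            labels = c(allRows$labels, passRows$labels),
            pass = c(allRows$pass, passRows$pass),
            excluded = allRows$excluded + passRows$excluded)
        current <- if (regime == "iterative" &&
                       length(passRows$labels) > 0 &&
                       length(unique(passRows$labels)) == 2)
            passRows else allRows
    }
    if (regime == "iterative") current else allRows
}
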