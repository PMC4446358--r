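#' Train a boundary classifier on one scene
#'
#' Single-pass training in one of two conventions. Context-aware: regions
#' are partitioned into kinds, mitochondria-mitochondria boundaries are
#' excluded and mitochondria-cytoplasm boundaries are labelled true (the
#' depth-limited single-pass variant of the two-phase pipeline).
#' Context-oblivious: every boundary is labelled purely by ground-truth
#' body identity (0 = false cell membrane, 1 = true cell membrane), with no
#' kind information -- the convention of the single-phase baselines.
#'
#' @param scene a [Scene-class], or a list of scenes whose edge rows are
#'   pooled (more scenes cover more of the rare boundary geometries, e.g.
#'   small fragments squeezed against cell walls).
#' @param contextAware training convention (see above).
#' @param mitoProbThreshold kind-partition threshold (context-aware only).
#' @param numTrees,maxDepth,seed forest settings.
#' @return a CLASSIFIER-mode [ConfidencePredictor-class].
#' @export
trainSceneClassifier <- function(scene, contextAware = TRUE,
                                 mitoProbThreshold = 0.5, numTrees = 100L,
                                 maxDepth = 20L, seed) {
    if (missing(seed)) stop("a seed is required")
    scenes <- if (is.list(scene)) scene else list(scene)
    X <- NULL
    y <- integer(0)
    for (sc in scenes) {
        graph <- buildRAG(sc@superpixels, sc@probs)
        assignment <- gtAssignment(graph, sc@superpixels, sc@gtCells)
        if (contextAware) {
            graph <- partitionKinds(graph,
                                    mitoProbThreshold = mitoProbThreshold)
            keys <- Filter(function(k) {
                e <- graph@edges[[k]]
                !(graph@nodes[[as.character(e$a)]]$kind == "MITO" &&
                  graph@nodes[[as.character(e$b)]]$kind == "MITO")
            }, edgeKeys(graph))
        } else {
            keys <- edgeKeys(graph)
        }
        Xs <- edgeFeatureMatrix(graph, keys)
        ys <- if (contextAware) gtEdgeLabels(graph, keys, assignment)
              else {
                  # kind-blind labels: body identity only
                  ends <- t(vapply(keys, function(k) {
                      e <- graph@edges[[k]]; c(e$a, e$b)
                  }, integer(2)))
                  bodies <- regionGTBodies(graph, assignment)
                  body <- setNames(bodies$body, bodies$id)
                  as.integer(body[as.character(ends[, 1])] !=
                             body[as.character(ends[, 2])])
              }
        X <- rbind(X, Xs)
        y <- c(y, ys)
    }
    ok <- !is.na(y)
    trainBoundaryClassifier(X[ok, , drop = FALSE], y[ok],
                            numTrees = numTrees, maxDepth = maxDepth,
                            seed = seed)
}

#' Segment one scene with one method
#'
#' @param scene a [Scene-class].
#' @param method "standard" or "delayed" (context-oblivious single phase
#'   over all boundaries), or "cada" (two-phase context-aware).
#' @param hc boundary classifier appropriate for the method's convention.
#' @param delta stopping threshold (cytoplasm threshold for "cada").
#' @param deltaM mitochondria threshold ("cada" only).
#' @param mitoProbThreshold kind-partition threshold ("cada" only).
#' @return list with `labels` and `graph`.
#' @export
segmentScene <- function(scene, method = c("delayed", "standard", "cada"),
                         hc, delta = 0.14, deltaM = 0.5,
                         mitoProbThreshold = 0.5) {
    method <- match.arg(method)
    if (method == "cada") {
        res <- cadaSegment(scene@superpixels, scene@probs, hc,
                           deltaC = delta, deltaM = deltaM,
                           mitoProbThreshold = mitoProbThreshold)
        return(res[c("labels", "graph")])
    }
    graph <- buildRAG(scene@superpixels, scene@probs)
    graph <- if (method == "standard") standardAgglomerate(graph, hc, delta)
             else delayedAgglomerate(graph, hc, delta)
    list(labels = exportLabels(graph, scene@superpixels), graph = graph)
}

#' Benchmark a set of methods across seeded scenes
#'
#' For every seed, one training scene and one held-out test scene are
#' generated; method-appropriate classifiers are trained on the training
#' scene and every (method, delta) combination segments the test scene.
#' Split-VI, split-RE and raw false-merge/false-split pair counts against
#' the known ground truth are tabulated.
#'
#' @param seeds integer vector of scene seeds.
#' @param deltas stopping thresholds to sweep.
#' @param methods subset of c("standard", "delayed", "cada").
#' @param specArgs list of [sceneSpec()] overrides applied to both scenes.
#' @param deltaM,mitoProbThreshold phase-2 settings for "cada".
#' @param numTrees,maxDepth forest settings.
#' @return data.frame, one row per (seed, method, delta).
#' @export
benchmarkSuite <- function(seeds, deltas = 0.14,
                           methods = c("standard", "delayed", "cada"),
                           specArgs = list(), deltaM = 0.5,
                           mitoProbThreshold = 0.5, numTrees = 100L,
                           maxDepth = 20L) {
    rows <- list()
    for (seed in seeds) {
        trainScene <- generateScene(
            do.call(sceneSpec, c(specArgs, list(seed = 2L * seed))))
        testScene <- generateScene(
            do.call(sceneSpec, c(specArgs, list(seed = 2L * seed + 1L))))
        needOblivious <- any(methods %in% c("standard", "delayed"))
        hcObl <- if (needOblivious)
            trainSceneClassifier(trainScene, contextAware = FALSE,
                                 numTrees = numTrees, maxDepth = maxDepth,
                                 seed = seed)
        hcCtx <- if ("cada" %in% methods)
            trainSceneClassifier(trainScene, contextAware = TRUE,
                                 mitoProbThreshold = mitoProbThreshold,
                                 numTrees = numTrees, maxDepth = maxDepth,
                                 seed = seed)
        for (method in methods) {
            hc <- if (method == "cada") hcCtx else hcObl
            for (delta in deltas) {
                out <- segmentScene(testScene, method, hc, delta = delta,
                                    deltaM = deltaM,
                                    mitoProbThreshold = mitoProbThreshold)
                ct <- contingencyTable(testScene@gtCells, out$labels)
                vi <- splitVI(ct)
                re <- splitRand(ct)
                rows[[length(rows) + 1]] <- data.frame(
                    seed = seed, method = method, delta = delta,
                    viOE = vi[["viOE"]], viUE = vi[["viUE"]],
                    reOE = re[["reOE"]], reUE = re[["reUE"]],
                    falseMergePairs = falseMergePairs(ct),
                    falseSplitPairs = falseSplitPairs(ct),
                    nRegions = length(out$graph@nodes))
            }
        }
    }
    do.call(rbind, rows)
}

#' Delayed vs standard agglomeration: false-merge comparison
#'
#' The head-to-head comparison of the two engines at a matched threshold:
#' for each seed, a context-oblivious classifier is trained on one scene
#' and both engines segment a held-out scene; falsely merged pixel pairs
#' against ground truth are counted. The scenes carry the generator's
#' detector-failure modes (strong probability noise and membrane gaps) so
#' that boundary-classifier errors actually occur at this scale.
#'
#' @param nScenes number of seeded scene pairs (default 20).
#' @param delta matched stopping threshold (default 0.14).
#' @param baseSeed root seed; scene seeds derive from it.
#' @param specArgs extra [sceneSpec()] overrides.
#' @return data.frame with per-seed false-merge pair counts for both
#'   engines.
#' @export
compareEnginesFalseMerges <- function(nScenes = 20L, delta = 0.14,
                                      baseSeed = 1L, specArgs = list()) {
    args <- modifyList(list(noiseSigma = 0.30, gapPerCell = 2), specArgs)
    seeds <- baseSeed * 1000L + seq_len(nScenes)
    df <- benchmarkSuite(seeds, deltas = delta,
                         methods = c("standard", "delayed"),
                         specArgs = args)
    std <- df[df$method == "standard", ]
    dly <- df[df$method == "delayed", ]
    data.frame(seed = std$seed,
               standardFalseMerges = std$falseMergePairs,
               delayedFalseMerges = dly$falseMergePairs,
               standardViUE = std$viUE, delayedViUE = dly$viUE)
}

#' Context-aware vs context-oblivious segmentation
#'
#' On mitochondria-rich noisy scenes, the two-phase context-aware pipeline
#' is compared against context-oblivious delayed agglomeration: the
#' oblivious method is swept over thresholds and, per seed, its operating
#' point with under-segmentation (viUE) closest to the context-aware run is
#' compared on over-segmentation (viOE). Also counts phase-2 merges that
#' fused mitochondria from different ground-truth cells (zero by
#' construction, since phase 2 never merges two MITO regions).
#'
#' @param nScenes number of seeded scene pairs.
#' @param deltaC context-aware cytoplasm threshold.
#' @param deltaM mitochondria absorption threshold.
#' @param obliviousDeltas threshold sweep for the oblivious baseline.
#' @param baseSeed root seed.
#' @param specArgs extra [sceneSpec()] overrides (defaults: 4 mitochondria
#'   per cell, noiseSigma 0.30).
#' @return data.frame, one row per seed.
#' @export
compareContextAware <- function(nScenes = 20L, deltaC = 0.14, deltaM = 0.5,
                                obliviousDeltas = c(0.1, 0.14, 0.2, 0.3,
                                                    0.4),
                                baseSeed = 1L, specArgs = list()) {
    args <- modifyList(list(noiseSigma = 0.30, mitoPerCell = 4,
                            gapPerCell = 1, channelConfusion = 0.4),
                       specArgs)
    rows <- list()
    for (i in seq_len(nScenes)) {
        seed <- baseSeed * 1000L + 500L + i
        trainScene <- generateScene(
            do.call(sceneSpec, c(args, list(seed = 2L * seed))))
        testScene <- generateScene(
            do.call(sceneSpec, c(args, list(seed = 2L * seed + 1L))))
        hcCtx <- trainSceneClassifier(trainScene, contextAware = TRUE,
                                      seed = seed)
        hcObl <- trainSceneClassifier(trainScene, contextAware = FALSE,
                                      seed = seed)
        cada <- segmentScene(testScene, "cada", hcCtx, delta = deltaC,
                             deltaM = deltaM)
        cadaSM <- splitMetrics(testScene@gtCells, cada$labels)
        log <- mergeLog(cada$graph)
        mitoMitoCross <- sum(log$survivorKind == "MITO" &
                             log$absorbedKind == "MITO")
        best <- NULL
        for (delta in obliviousDeltas) {
            obl <- segmentScene(testScene, "delayed", hcObl, delta = delta)
            sm <- splitMetrics(testScene@gtCells, obl$labels)
            if (is.null(best) ||
                abs(sm@viUE - cadaSM@viUE) < abs(best$viUE - cadaSM@viUE))
                best <- list(delta = delta, viOE = sm@viOE, viUE = sm@viUE)
        }
        rows[[length(rows) + 1]] <- data.frame(
            seed = seed, cadaViOE = cadaSM@viOE, cadaViUE = cadaSM@viUE,
            obliviousViOE = best$viOE, obliviousViUE = best$viUE,
            obliviousDelta = best$delta, mitoMitoCrossMerges = mitoMitoCross)
    }
    do.call(rbind, rows)
}
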