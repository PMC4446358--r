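# Construct a probability array from per-pixel class indices
indicatorProbs <- function(classIdx, nChannels = 4) {
    d <- dim(classIdx)
    arr <- array(0, c(d, nChannels))
    m <- matrix(0, length(classIdx), nChannels)
    m[cbind(seq_along(classIdx), as.vector(classIdx))] <- 1
    ProbabilityMaps(array(m, c(d, nChannels)))
}

test_that("regions are tagged by mean mitochondria probability", {
    # label 2 is pure mitochondria signal, label 1 pure cytoplasm
    lab <- matrix(rep(1:2, each = 8), 4, 4)
    cls <- matrix(rep(c(2L, 3L), each = 8), 4, 4)
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g, mitoProbThreshold = 0.5)
    expect_equal(regionNode(g, 1)$kind, "CYTO")
    expect_equal(regionNode(g, 2)$kind, "MITO")
    gAll <- partitionKinds(g, mitoProbThreshold = 1)
    expect_true(all(vapply(gAll@nodes, `[[`, character(1),
                           "kind") == "CYTO"))
    expect_error(partitionKinds(g, channel = "absent"), "missing")
})

test_that("kind tags match a raw-pixel oracle on a random scene", {
    scene <- generateScene(sceneSpec(seed = 91))
    g <- buildRAG(scene@superpixels, scene@probs)
    g <- partitionKinds(g, mitoProbThreshold = 0.5)
    lab <- as.vector(labelData(scene@superpixels))
    mp <- as.vector(probChannel(scene@probs, "mitochondria"))
    for (id in regionIds(g)) {
        oracle <- if (mean(mp[lab == id]) > 0.5) "MITO" else "CYTO"
        expect_equal(regionNode(g, id)$kind, oracle)
    }
})

test_that("overlap ratio is face size over total face size", {
    # mito region 4 with neighbours of face sizes 30 (cyto), 10 (cyto),
    # 20 (mito)
    g <- makeSyntheticGraph(4, list(c(1, 4), c(2, 4), c(3, 4)))
    g@edges[["1-4"]]$faceSize <- 30
    g@edges[["2-4"]]$faceSize <- 10
    g@edges[["3-4"]]$faceSize <- 20
    g@nodes[["4"]]$kind <- "MITO"
    g@nodes[["3"]]$kind <- "MITO"
    expect_equal(overlapRatio(g, 4, 1), 0.5)
    expect_equal(overlapRatio(g, 4, 2), 10 / 60)
    rhos <- c(overlapRatio(g, 4, 1), overlapRatio(g, 4, 2),
              overlapRatio(g, 4, 3))
    expect_equal(sum(rhos), 1)
    expect_error(overlapRatio(g, 4, 99), "not adjacent")
})

test_that("overlap ratio matches brute-force face counting on a label grid", {
    # mito blob (label 9) straddling two cyto regions unevenly
    lab <- matrix(1L, 8, 8)
    lab[, 5:8] <- 2L
    lab[3:5, 3:6] <- 9L
    cls <- array(2L, dim = dim(lab)); cls[lab == 9L] <- 3L
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g)
    expect_equal(regionNode(g, 9)$kind, "MITO")
    oracle <- bruteAdjacency(lab)
    total <- oracle[["1-9"]] + oracle[["2-9"]]
    expect_equal(overlapRatio(g, 9, 1), oracle[["1-9"]] / total)
    expect_equal(overlapRatio(g, 9, 2), oracle[["2-9"]] / total)
})

test_that("an enclosed mitochondrion is absorbed at confidence zero", {
    lab <- matrix(1L, 8, 8)
    lab[3:5, 3:5] <- 2L
    cls <- array(2L, dim = dim(lab)); cls[lab == 2L] <- 3L
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g)
    expect_equal(overlapRatio(g, 2, 1), 1)
    out <- absorbMitochondria(g, deltaM = 0.5)
    expect_length(out@nodes, 1)
    log <- mergeLog(out)
    expect_equal(log$confidence, 0)
    expect_equal(regionNode(out, 1)$kind, "CYTO")
})

test_that("stacked mitochondria are absorbed stepwise through the chain", {
    # ring blob A (label 2) encloses blob B (label 3): B touches only A,
    # so B can only be absorbed after A has joined the cytoplasm
    lab <- matrix(1L, 12, 10)
    lab[3:9, 3:8] <- 2L
    lab[5:7, 5:6] <- 3L
    cls <- array(2L, dim = dim(lab)); cls[lab >= 2L] <- 3L
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g)
    expect_equal(regionNode(g, 2)$kind, "MITO")
    expect_equal(regionNode(g, 3)$kind, "MITO")
    expect_setequal(neighbourIds(g, 3), 2)   # B touches only A
    out <- absorbMitochondria(g, deltaM = 0.6)
    expect_length(out@nodes, 1)
    log <- mergeLog(out)
    expect_equal(log$absorbed, c(2, 3))      # A first, then B
    expect_equal(log$absorbedKind, c("MITO", "MITO"))
    expect_equal(log$survivorKind, c("CYTO", "CYTO"))
})

test_that("a mitochondrion merges only into the larger-overlap cell", {
    # blob overlaps cell 1 with ~70% of its boundary, cell 2 with ~30%
    lab <- matrix(1L, 10, 10)
    lab[, 8:10] <- 2L
    lab[4:6, 5:8] <- 9L     # straddles the 1|2 border unevenly
    cls <- array(2L, dim = dim(lab)); cls[lab == 9L] <- 3L
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g)
    rho1 <- overlapRatio(g, 9, 1)
    rho2 <- overlapRatio(g, 9, 2)
    expect_gt(rho1, rho2)
    expect_gt(rho1, 0.5)
    out <- absorbMitochondria(g, deltaM = 0.5)
    # merged into cell 1 only; cells 1 and 2 remain separate
    expect_length(out@nodes, 2)
    log <- mergeLog(out)
    expect_equal(nrow(log), 1)
    expect_setequal(c(log$survivor, log$absorbed), c(1, 9))
})

test_that("mitochondria above the stopping threshold stay intact and reported", {
    lab <- matrix(1L, 10, 10)
    lab[, 6:10] <- 2L
    lab[4:6, 4:7] <- 9L
    cls <- array(2L, dim = dim(lab)); cls[lab == 9L] <- 3L
    g <- buildRAG(lab, indicatorProbs(cls))
    g <- partitionKinds(g)
    out <- absorbMitochondria(g, deltaM = 0.05)  # nothing reaches 1 - rho <= 0.05
    expect_length(out@nodes, 3)
    kinds <- vapply(out@nodes, `[[`, character(1), "kind")
    expect_equal(sum(kinds == "MITO"), 1)
})

test_that("phase candidates respect the kind restrictions throughout", {
    scene <- generateScene(sceneSpec(seed = 93, mitoPerCell = 3,
                                     noiseSigma = 0, blurSigma = 0))
    hc <- trainSceneClassifier(scene, seed = 2)
    res <- cadaSegment(scene@superpixels, scene@probs, hc)
    log <- mergeLog(res$graph)
    phase1 <- log[seq_len(res$phase1$merges), ]
    phase2 <- log[-seq_len(res$phase1$merges), ]
    expect_true(all(phase1$survivorKind == "CYTO"))
    expect_true(all(phase1$absorbedKind == "CYTO"))
    if (nrow(phase2) > 0) {
        expect_true(all(phase2$survivorKind != phase2$absorbedKind))
        expect_true(all(phase2$confidence <= 0.5 + 1e-12))
    }
})

test_that("a scene without mitochondria reduces to plain delayed clustering", {
    scene <- generateScene(sceneSpec(seed = 94, mitoPerCell = 0))
    hc <- trainSceneClassifier(scene, seed = 2)
    res <- cadaSegment(scene@superpixels, scene@probs, hc)
    g <- buildRAG(scene@superpixels, scene@probs)
    plain <- delayedAgglomerate(g, hc, 0.14)
    expect_identical(graphPartition(res$graph), graphPartition(plain))
    expect_equal(res$phase2$merges, 0)
})

test_that("noiseless scenes are recovered exactly end to end", {
    train <- generateScene(sceneSpec(seed = 95, noiseSigma = 0,
                                     blurSigma = 0))
    test <- generateScene(sceneSpec(seed = 96, noiseSigma = 0,
                                    blurSigma = 0))
    hc <- trainSceneClassifier(train, seed = 2)
    res <- cadaSegment(test@superpixels, test@probs, hc)
    sm <- splitMetrics(test@gtCells, res$labels)
    expect_equal(sm@viOE, 0, tolerance = 1e-12)
    expect_equal(sm@viUE, 0, tolerance = 1e-12)
    expect_equal(sm@reOE, 0)
    expect_equal(sm@reUE, 0)
    expect_length(res$unabsorbedMito, 0)
})

test_that("overlap ratios stay normalized for every mito node during phase 2", {
    scene <- generateScene(sceneSpec(seed = 97, mitoPerCell = 3,
                                     noiseSigma = 0, blurSigma = 0))
    g <- buildRAG(scene@superpixels, scene@probs)
    g <- partitionKinds(g)
    # instrument the engine through onPop: at every decision, check
    # normalization for all current MITO nodes and that the popped edge
    # carries the maximal rho among active mito-cyto candidates
    checkState <- function(gr, key) {
        kinds <- vapply(gr@nodes, `[[`, character(1), "kind")
        for (id in as.integer(names(kinds)[kinds == "MITO"])) {
            nbr <- neighbourIds(gr, id)
            if (length(nbr) == 0) next
            rhos <- vapply(nbr, function(b)
                boundaryEdgeBetween(gr, id, b)$faceSize, numeric(1))
            expect_equal(sum(rhos / sum(rhos)), 1, tolerance = 1e-12)
        }
        # popped edge has minimal h_m = maximal rho among ACTIVE candidates
        cand <- Filter(function(k) {
            e <- gr@edges[[k]]
            ka <- gr@nodes[[as.character(e$a)]]$kind
            kb <- gr@nodes[[as.character(e$b)]]$kind
            ka != kb && e$flag == "ACTIVE" && !is.na(e$conf)
        }, edgeKeys(gr))
        confs <- vapply(cand, function(k) gr@edges[[k]]$conf, numeric(1))
        expect_equal(gr@edges[[key]]$conf, min(confs), tolerance = 1e-12)
    }
    out <- delayedAgglomerate(g, mitoOverlapPredictor(), 0.5,
                              eligible = cadaSeg:::mitoCytoEdge,
                              onPop = checkState, mergedKind = "CYTO")
    expect_gt(out@report$merges, 0)
})
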