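flatProbs <- function(shape, nChannels = 4) {
    arr <- array(1 / nChannels, dim = c(shape, nChannels))
    ProbabilityMaps(arr)
}

test_that("two stacked labels give one edge with face size 2", {
    lab <- matrix(c(1, 1, 2, 2), 2, 2)   # column-major: rows 1,1 / 2,2
    g <- buildRAG(lab, flatProbs(c(2, 2)))
    expect_length(g@nodes, 2)
    expect_length(g@edges, 1)
    expect_equal(boundaryEdgeBetween(g, 1, 2)$faceSize, 2)
})

test_that("a centre pixel inside a 3x3 frame has face size 4", {
    lab <- matrix(1L, 3, 3); lab[2, 2] <- 2L
    g <- buildRAG(lab, flatProbs(c(3, 3)))
    expect_length(g@edges, 1)
    expect_equal(boundaryEdgeBetween(g, 1, 2)$faceSize, 4)
})

test_that("edge set and face sizes equal brute-force pair enumeration", {
    set.seed(21)
    for (rep in 1:5) {
        lab <- randomLabelMap(c(32, 32), 10)
        g <- buildRAG(lab, flatProbs(c(32, 32)))
        oracle <- bruteAdjacency(lab)
        expect_setequal(edgeKeys(g), names(oracle))
        for (k in edgeKeys(g))
            expect_equal(g@edges[[k]]$faceSize, oracle[[k]])
    }
    # 3D volume
    lab <- randomLabelMap(c(8, 8, 8), 6)
    g <- buildRAG(lab, ProbabilityMaps(array(0.25, c(8, 8, 8, 4))))
    oracle <- bruteAdjacency(lab)
    expect_setequal(edgeKeys(g), names(oracle))
})

test_that("diagonal contacts count only under full connectivity", {
    lab <- matrix(c(1, 1, 1, 2), 2, 2)   # single 2 in the corner
    gFace <- buildRAG(lab, flatProbs(c(2, 2)), connectivity = "face")
    gFull <- buildRAG(lab, flatProbs(c(2, 2)), connectivity = "full")
    expect_equal(boundaryEdgeBetween(gFace, 1, 2)$faceSize, 2)
    expect_equal(boundaryEdgeBetween(gFull, 1, 2)$faceSize, 3)
    # diagonal-only contact: no edge under face connectivity
    lab2 <- matrix(c(1, 0, 0, 2), 2, 2)
    arr <- array(0.25, c(2, 2, 4))
    expect_error(buildRAG(lab2, arr, connectivity = "face"), NA)
    expect_length(buildRAG(lab2, arr, connectivity = "face")@edges, 0)
    expect_length(buildRAG(lab2, arr, connectivity = "full")@edges, 1)
})

test_that("background pixels contribute to no node and no edge", {
    lab <- matrix(c(1, 0, 2, 1, 0, 2, 1, 0, 2), 3, 3)
    g <- buildRAG(lab, flatProbs(c(3, 3)))
    expect_setequal(regionIds(g), c(1, 2))
    expect_length(g@edges, 0)  # separated by a background column
    expect_equal(sum(vapply(g@nodes, `[[`, numeric(1), "size")),
                 sum(lab != 0))
})

test_that("malformed inputs are rejected with explicit messages", {
    lab <- matrix(1:4, 2, 2)
    expect_error(buildRAG(lab, flatProbs(c(3, 3))), "2x2.*3x3")
    expect_error(buildRAG(matrix(1L, 4, 4), flatProbs(c(4, 4))),
                 "at least 2")
    g <- buildRAG(matrix(c(1, 1, 2, 2), 2, 2), flatProbs(c(2, 2)))
    expect_error(mergeRegions(g, 1, 5), "unknown region")
    lab3 <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3)
    g3 <- buildRAG(lab3, flatProbs(c(2, 3)))
    expect_error(mergeRegions(g3, 1, 3), "not adjacent")
})

test_that("merging on a path removes the middle node and keeps the chain", {
    lab <- matrix(rep(1:3, each = 2), 2, 3)
    g <- buildRAG(lab, flatProbs(c(2, 3)))
    g <- mergeRegions(g, 1, 2)
    expect_setequal(regionIds(g), c(1, 3))
    expect_setequal(edgeKeys(g), "1-3")
})

test_that("parallel edges combine with summed face sizes and stats", {
    # triangle: three vertical stripes all touching via an extra row
    lab <- rbind(c(1, 2, 3), c(1, 1, 3), c(1, 3, 3))
    set.seed(3)
    probs <- uniformProbs(c(3, 3))
    g <- buildRAG(lab, probs)
    f13 <- boundaryEdgeBetween(g, 1, 3)$faceSize
    f23 <- boundaryEdgeBetween(g, 2, 3)$faceSize
    c13 <- boundaryEdgeBetween(g, 1, 3)$stats$count
    g <- mergeRegions(g, 1, 2)
    e <- boundaryEdgeBetween(g, 1, 3)
    expect_equal(e$faceSize, f13 + f23)
    expect_gt(e$stats$count, 0)
    expect_length(g@edges, 1)
})

test_that("random merge sequences match union-find relabelling", {
    set.seed(31)
    for (rep in 1:3) {
        lab <- randomLabelMap(c(24, 24), 30)
        present <- sort(unique(as.vector(lab)))
        g <- buildRAG(lab, flatProbs(c(24, 24)))
        merges <- list()
        for (i in 1:50) {
            if (length(g@edges) == 0) break
            key <- sample(edgeKeys(g), 1)
            e <- g@edges[[key]]
            g <- mergeRegions(g, e$a, e$b)
            merges[[length(merges) + 1]] <- c(e$a, e$b)
        }
        out <- exportLabels(g, LabelVolume(lab))
        oracle <- ufRelabel(lab, merges)
        # same partition: regions must coincide pixel-wise up to label names
        expect_equal(splitVI(contingencyTable(oracle, labelData(out),
                                              ignoreBackground = FALSE)),
                     c(viOE = 0, viUE = 0), tolerance = 1e-12)
        # pixel conservation
        expect_equal(sum(vapply(g@nodes, `[[`, numeric(1), "size")),
                     length(lab))
    }
})

test_that("no-merge export is the identity and full merge yields one label", {
    lab <- matrix(rep(1:4, each = 4), 4, 4)
    g <- buildRAG(lab, flatProbs(c(4, 4)))
    expect_identical(labelData(exportLabels(g, LabelVolume(lab))), lab)
    for (i in 2:4) g <- mergeRegions(g, 1, i)
    out <- labelData(exportLabels(g, LabelVolume(lab)))
    expect_equal(unique(as.vector(out)), 1L)
})

test_that("adjacency stays sound under merges: rebuilt RAG matches", {
    set.seed(41)
    lab <- randomLabelMap(c(20, 20), 12)
    probs <- flatProbs(c(20, 20))
    g <- buildRAG(lab, probs)
    for (i in 1:6) {
        key <- sample(edgeKeys(g), 1)
        e <- g@edges[[key]]
        g <- mergeRegions(g, e$a, e$b)
    }
    rebuilt <- buildRAG(exportLabels(g, LabelVolume(lab)), probs)
    expect_setequal(edgeKeys(rebuilt), edgeKeys(g))
    for (k in edgeKeys(g))
        expect_equal(g@edges[[k]]$faceSize, rebuilt@edges[[k]]$faceSize)
})

test_that("export rejects superpixels missing from the graph", {
    lab <- matrix(c(1, 1, 2, 2), 2, 2)
    g <- buildRAG(lab, flatProbs(c(2, 2)))
    lab2 <- lab; lab2[1, 1] <- 9L
    expect_error(exportLabels(g, LabelVolume(lab2)), "absent")
})
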