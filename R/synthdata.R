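#' Specification of a synthetic benchmark scene
#'
#' Defines the study conditions for one generated scene: image extents, the
#' number of cells, mitochondria density and size, wall thickness, the
#' probability-map degradation (blur then truncated additive noise), the
#' expected number of cytoplasm fragments per cell, and the RNG seed.
#' Identical specs produce bit-identical scenes.
#'
#' @param shape 2D or 3D extents in pixels (default 256 x 256).
#' @param nCells target cell count (default 15).
#' @param mitoPerCell mean mitochondria count per cell (Poisson; default 2).
#' @param mitoRadiusRange min/max mitochondria semi-axis in pixels.
#' @param boundaryWidth cell-wall indicator thickness in pixels.
#' @param noiseSigma sd of the truncated Gaussian probability noise.
#' @param blurSigma Gaussian blur of the clean class indicators (pixels).
#' @param fragmentation expected cytoplasm superpixels per cell.
#' @param gapPerCell mean number of membrane gaps per cell (Poisson,
#'   default 0): disc-shaped blemishes on cell walls where the boundary
#'   signal is replaced by cytoplasm signal, emulating the dominant failure
#'   mode of pixelwise membrane detectors.
#' @param gapRadiusRange min/max gap radius in pixels.
#' @param channelConfusion mixing fraction kappa in [0, 0.5] between the
#'   cell-boundary and mitochondria-boundary indicators (default 0),
#'   emulating a pixel detector that cannot tell membranes from
#'   mitochondria rims.
#' @param seed integer RNG seed (mandatory).
#' @return a validated scene specification (list).
#' @export
sceneSpec <- function(shape = c(256L, 256L), nCells = 15L, mitoPerCell = 2,
                      mitoRadiusRange = c(4, 7), boundaryWidth = 2,
                      noiseSigma = 0.15, blurSigma = 1, fragmentation = 8,
                      gapPerCell = 0, gapRadiusRange = c(3, 6),
                      channelConfusion = 0, seed) {
    if (missing(seed)) stop("a seed is required")
    if (!(length(shape) %in% c(2L, 3L)) || any(shape < 16))
        stop("infeasible spec: shape must be 2D/3D with extents >= 16")
    if (nCells < 2) stop("infeasible spec: need at least 2 cells")
    cellScale <- min(shape) / ceiling(sqrt(nCells))
    if (2 * (max(mitoRadiusRange) + boundaryWidth + 2) >= cellScale)
        stop(sprintf(
            "infeasible spec: mitochondria radius %g too large for ~%d cells in a %s image",
            max(mitoRadiusRange), nCells, paste(shape, collapse = "x")))
    if (noiseSigma < 0 || blurSigma < 0) stop("infeasible spec: negative sigma")
    if (channelConfusion < 0 || channelConfusion > 0.5)
        stop("infeasible spec: channelConfusion must lie in [0, 0.5]")
    list(shape = as.integer(shape), nCells = as.integer(nCells),
         mitoPerCell = mitoPerCell, mitoRadiusRange = mitoRadiusRange,
         boundaryWidth = boundaryWidth, noiseSigma = noiseSigma,
         blurSigma = blurSigma, fragmentation = fragmentation,
         gapPerCell = gapPerCell, gapRadiusRange = gapRadiusRange,
         channelConfusion = channelConfusion, seed = as.integer(seed))
}

# Pixelation of a Voronoi diagram can strand isolated pixels of a cell at
# cell corners; reassign every pixel outside its cell's main component to a
# face-neighbouring cell so all cells are connected.
#' @noRd
repairCellComponents <- function(cellOf, shape, nCells) {
    for (pass in seq_len(20)) {
        lab <- array(cellOf, dim = shape)
        bad <- logical(length(cellOf))
        for (i in seq_len(nCells)) {
            cc <- connectedComponents(lab == i)
            if (max(cc) <= 1) next
            main <- which.max(tabulate(cc[cc > 0]))
            bad[as.vector(cc) != main & cellOf == i] <- TRUE
        }
        if (!any(bad)) return(cellOf)
        nd <- length(shape)
        for (p in which(bad)) {
            ind <- arrayInd(p, shape)
            for (axis in seq_len(nd)) {
                for (step in c(-1L, 1L)) {
                    q <- ind
                    q[axis] <- q[axis] + step
                    if (q[axis] < 1 || q[axis] > shape[axis]) next
                    qi <- sum((q - 1) * cumprod(c(1, shape[-nd]))) + 1
                    if (!bad[qi]) {
                        cellOf[p] <- cellOf[qi]
                        bad[p] <- FALSE
                        break
                    }
                }
                if (!bad[p]) break
            }
        }
    }
    stop("internal error: could not repair cell connectivity")
}

# pixel coordinate matrices for a 2D/3D shape (one column per axis)
#' @noRd
pixelCoords <- function(shape) {
    nd <- length(shape)
    grids <- lapply(seq_len(nd), function(a) {
        rep(rep(seq_len(shape[a]),
                each = prod(shape[seq_len(a - 1)])),
            times = prod(shape[seq_len(nd)][-seq_len(a)]))
    })
    do.call(cbind, grids)
}

#' Generate a synthetic scene
#'
#' Builds, from one seed: (1) a ground-truth cell partition (Voronoi of
#' well-separated random seed points, so every pixel belongs to a cell);
#' (2) elliptical mitochondria blobs strictly inside cells, never touching
#' a wall or each other; (3) four clean class-indicator channels (cell
#' boundary = wall band around cell borders, mitochondria interior,
#' mitochondria boundary = one-pixel rim, cytoplasm = the rest) degraded by
#' Gaussian blur and truncated additive noise, then renormalized to sum to
#' one per pixel; (4) a superpixel over-segmentation that exactly refines
#' the ground truth -- each cell's cytoplasm is fragmented by a flat
#' multi-source flood (BFS Voronoi) from random interior seeds confined to
#' the region, and each mitochondria blob forms its own superpixel; and (5)
#' the true (cell, kind) assignment of every superpixel.
#'
#' @param spec a [sceneSpec()].
#' @return a [Scene-class].
#' @export
generateScene <- function(spec) {
    withLocalSeed(spec$seed, {
        shape <- spec$shape
        nd <- length(shape)
        npix <- prod(shape)
        coords <- pixelCoords(shape)

        # --- ground-truth cells: Voronoi of separated random points ------
        minSep <- 0.55 * min(shape) / ceiling(sqrt(spec$nCells))
        seeds <- matrix(NA_real_, nrow = spec$nCells, ncol = nd)
        placed <- 0
        for (try in seq_len(5000)) {
            cand <- vapply(shape, function(s) runif(1, 2, s - 1), numeric(1))
            if (placed == 0 ||
                min(sqrt(colSums((t(seeds[seq_len(placed), , drop = FALSE]) -
                                  cand)^2))) >= minSep) {
                placed <- placed + 1
                seeds[placed, ] <- cand
            }
            if (placed == spec$nCells) break
        }
        if (placed < spec$nCells)
            stop("infeasible spec: could not place ", spec$nCells,
                 " separated cell seeds")
        best <- rep(Inf, npix)
        cellOf <- integer(npix)
        for (i in seq_len(spec$nCells)) {
            d2 <- rowSums((coords -
                           matrix(seeds[i, ], npix, nd, byrow = TRUE))^2)
            upd <- d2 < best
            best[upd] <- d2[upd]
            cellOf[upd] <- i
        }
        cellOf <- repairCellComponents(cellOf, shape, spec$nCells)
        gtArr <- array(cellOf, dim = shape)

        # --- cell wall band ---------------------------------------------
        wall <- differingNeighbourMask(gtArr)
        extra <- max(0L, ceiling((spec$boundaryWidth - 2) / 2))
        if (extra > 0) wall <- dilateMask(wall, extra)

        # --- mitochondria blobs -----------------------------------------
        mitoId <- array(0L, dim = shape)
        nextMito <- 0L
        rr <- spec$mitoRadiusRange
        for (cell in seq_len(spec$nCells)) {
            nBlobs <- rpois(1, spec$mitoPerCell)
            if (nBlobs == 0) next
            cellPix <- which(cellOf == cell & !as.vector(wall))
            for (b in seq_len(nBlobs)) {
                if (length(cellPix) == 0) break
                for (attempt in seq_len(25)) {
                    centre <- coords[cellPix[sample.int(length(cellPix), 1)], ]
                    ax <- runif(nd, rr[1], rr[2])
                    theta <- runif(1, 0, pi)
                    # candidate pixels in the bounding box of the ellipse
                    rmax <- max(ax) + 1
                    boxSel <- rep(TRUE, npix)
                    for (a in seq_len(nd))
                        boxSel <- boxSel & abs(coords[, a] - centre[a]) <= rmax
                    box <- which(boxSel)
                    rel <- coords[box, , drop = FALSE] -
                        matrix(centre, length(box), nd, byrow = TRUE)
                    if (nd == 2) {
                        u <- rel[, 1] * cos(theta) + rel[, 2] * sin(theta)
                        v <- -rel[, 1] * sin(theta) + rel[, 2] * cos(theta)
                        inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
                    } else {
                        u <- rel[, 1] * cos(theta) + rel[, 2] * sin(theta)
                        v <- -rel[, 1] * sin(theta) + rel[, 2] * cos(theta)
                        w <- rel[, 3]
                        inside <- (u / ax[1])^2 + (v / ax[2])^2 +
                            (w / ax[min(nd, 3)])^2 <= 1
                    }
                    blob <- box[inside]
                    if (length(blob) < 5) next
                    # keep blobs off the image border: a blob touching the
                    # border can pinch the cell's cytoplasm in two
                    if (any(coords[blob, , drop = FALSE] <= 2) ||
                        any(t(coords[blob, , drop = FALSE]) > shape - 2))
                        next
                    blobMask <- array(FALSE, dim = shape)
                    blobMask[blob] <- TRUE
                    ring <- dilateMask(blobMask, 2) & !blobMask
                    ok <- all(cellOf[blob] == cell) &&
                        !any(wall[blob]) && !any(mitoId[blob] > 0) &&
                        all(cellOf[ring] == cell) && !any(wall[ring]) &&
                        !any(mitoId[ring] > 0)
                    if (ok) {
                        nextMito <- nextMito + 1L
                        mitoId[blob] <- nextMito
                        break
                    }
                }
            }
        }
        mitoMask <- mitoId > 0

        # --- clean indicators -> degraded probability maps --------------
        rim <- mitoMask & differingNeighbourMask(mitoId)
        cb <- wall & !mitoMask
        mitoInt <- mitoMask & !rim
        cyto <- !(cb | mitoInt | rim)
        idx <- function(k) (k - 1) * npix + seq_len(npix)
        flat <- numeric(npix * 4)
        flat[idx(1)] <- as.numeric(cb)
        flat[idx(2)] <- as.numeric(cyto)
        flat[idx(3)] <- as.numeric(mitoInt)
        flat[idx(4)] <- as.numeric(rim)

        # membrane gaps: the detector "misses" membrane in small discs on
        # cell walls; boundary mass becomes cytoplasm mass there. The
        # ground truth is unchanged.
        nGaps <- rpois(1, spec$gapPerCell * spec$nCells)
        if (nGaps > 0) {
            wallPix <- which(as.vector(cb) > 0)
            if (length(wallPix) > 0) {
                for (gpix in wallPix[sample.int(length(wallPix),
                                                min(nGaps,
                                                    length(wallPix)))]) {
                    r <- runif(1, spec$gapRadiusRange[1],
                               spec$gapRadiusRange[2])
                    centre <- coords[gpix, ]
                    d2 <- rowSums((coords -
                                   matrix(centre, npix, nd,
                                          byrow = TRUE))^2)
                    hit <- d2 <= r^2 & flat[idx(1)] > 0
                    flat[idx(2)][hit] <- flat[idx(2)][hit] +
                        flat[idx(1)][hit]
                    flat[idx(1)][hit] <- 0
                }
            }
        }

        # membrane / mitochondria-rim confusion of the pixel detector
        if (spec$channelConfusion > 0) {
            k <- spec$channelConfusion
            cbv <- flat[idx(1)]; rimv <- flat[idx(4)]
            flat[idx(1)] <- (1 - k) * cbv + k * rimv
            flat[idx(4)] <- (1 - k) * rimv + k * cbv
        }
        chan <- array(flat, dim = c(shape, 4))
        if (spec$blurSigma > 0) {
            for (k in 1:4) {
                sl <- if (nd == 2) chan[, , k] else chan[, , , k]
                sl <- gaussianBlur(sl, spec$blurSigma)
                if (nd == 2) chan[, , k] <- sl else chan[, , , k] <- sl
            }
        }
        if (spec$noiseSigma > 0)
            chan <- chan + rnorm(length(chan), sd = spec$noiseSigma)
        chan[chan < 0] <- 0
        chan[chan > 1] <- 1
        m <- matrix(chan, ncol = 4)
        s <- rowSums(m)
        bad <- s < 1e-12
        if (any(bad)) { m[bad, ] <- 1 / 4; s[bad] <- 1 }
        m <- m / s
        probs <- ProbabilityMaps(array(m, dim = c(shape, 4)))

        # --- superpixels: exact refinement of the ground truth ----------
        # region code: (cell, mito-blob-or-cytoplasm); fragments are carved
        # inside each region by a flat flood from random seeds, so every
        # superpixel lies wholly inside one ground-truth region
        regionCode <- cellOf * (nextMito + 1L) + as.vector(mitoId)
        markers <- integer(npix)
        spCell <- integer(0)
        spKind <- character(0)
        spMito <- integer(0)
        nextSp <- 0L
        for (cell in seq_len(spec$nCells)) {
            cytoPix <- which(cellOf == cell & as.vector(mitoId) == 0L)
            k <- max(2L, rpois(1, spec$fragmentation))
            k <- min(k, length(cytoPix))
            pts <- cytoPix[sample.int(length(cytoPix), k)]
            markers[pts] <- nextSp + seq_len(k)
            spCell <- c(spCell, rep(cell, k))
            spKind <- c(spKind, rep("CYTO", k))
            spMito <- c(spMito, rep(0L, k))
            nextSp <- nextSp + k
        }
        for (mb in seq_len(nextMito)) {
            blob <- which(as.vector(mitoId) == mb)
            markers[blob[sample.int(length(blob), 1)]] <- nextSp + 1L
            spCell <- c(spCell, cellOf[blob[1]])
            spKind <- c(spKind, "MITO")
            spMito <- c(spMito, mb)
            nextSp <- nextSp + 1L
        }
        sp <- seededWatershed(array(0, dim = shape),
                              array(markers, dim = shape),
                              region = array(regionCode, dim = shape))
        if (any(sp == 0)) {
            # a region component with no carving seed (rare pinched
            # geometry): each leftover component becomes its own
            # superpixel, preserving the exact-refinement property
            left <- connectedComponents(sp == 0)
            for (comp in seq_len(max(left))) {
                pix <- which(as.vector(left) == comp)
                nextSp <- nextSp + 1L
                sp[pix] <- nextSp
                spCell <- c(spCell, cellOf[pix[1]])
                mb <- as.vector(mitoId)[pix[1]]
                spKind <- c(spKind, if (mb > 0) "MITO" else "CYTO")
                spMito <- c(spMito, mb)
            }
        }

        new("Scene",
            gtCells = LabelVolume(gtArr),
            gtMitoMask = array(mitoMask, dim = shape),
            probs = probs,
            superpixels = LabelVolume(sp),
            gtRegionMap = data.frame(superpixel = seq_len(nextSp),
                                     cell = spCell, kind = spKind,
                                     mito = spMito),
            spec = spec)
    })
}

#' Check the internal consistency of a generated scene
#'
#' Re-derives the superpixel-to-ground-truth map by brute-force pixel
#' overlap, asserts mitochondria containment, probability normalization and
#' the refinement property (every superpixel's majority ground-truth body
#' covers at least 90 percent of it).
#'
#' @param scene a [Scene-class].
#' @return list of logical checks (all TRUE for a valid scene).
#' @export
verifyScene <- function(scene) {
    sp <- as.vector(scene@superpixels@data)
    gt <- as.vector(scene@gtCells@data)
    dt <- data.table(sp = sp, gt = gt)[, .(n = .N), by = .(sp, gt)]
    major <- dt[, .SD[which.max(n)], by = sp]
    setorder(major, sp)
    frac <- major$n / tabulate(sp)[major$sp]
    mapOK <- identical(as.integer(major$gt),
                       as.integer(scene@gtRegionMap$cell))
    mito <- scene@gtMitoMask
    contained <- all(vapply(
        setdiff(unique(as.vector(scene@superpixels@data[mito])), 0L),
        function(s) {
            pix <- sp == s
            all(mito[pix]) && length(unique(gt[pix])) == 1
        }, logical(1)))
    m <- matrix(scene@probs@data, ncol = 4)
    list(gtMapConsistent = mapOK,
         mitoContained = contained,
         probsNormalized = max(abs(rowSums(m) - 1)) < 1e-9,
         refinement90 = all(frac >= 0.9),
         minMajorityFraction = min(frac))
}
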