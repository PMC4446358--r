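#' Contingency table of a segmentation against ground truth
#'
#' Exact overlap counts |g_i n r_j| between ground-truth bodies and
#' segmentation regions, over all pixels (optionally excluding ground-truth
#' background, the default).
#'
#' @param gt,sg [LabelVolume-class] objects (or arrays) of the same shape.
#' @param ignoreBackground exclude pixels carrying the ground-truth
#'   background label (default TRUE).
#' @return a [ContingencyTable-class].
#' @export
contingencyTable <- function(gt, sg, ignoreBackground = TRUE) {
    if (!is(gt, "LabelVolume")) gt <- LabelVolume(gt)
    if (!is(sg, "LabelVolume")) sg <- LabelVolume(sg)
    if (!identical(dim(gt@data), dim(sg@data)))
        stop(sprintf("shape mismatch: ground truth %s vs segmentation %s",
                     paste(dim(gt@data), collapse = "x"),
                     paste(dim(sg@data), collapse = "x")))
    g <- as.vector(gt@data)
    r <- as.vector(sg@data)
    if (ignoreBackground) {
        keep <- g != gt@backgroundLabel
        g <- g[keep]; r <- r[keep]
    }
    if (length(g) == 0) stop("no counted pixels")
    dt <- data.table(g = g, r = r)[, .(n = .N), by = .(g, r)]
    setorder(dt, g, r)
    new("ContingencyTable",
        counts = as.data.frame(dt), Z = as.numeric(sum(dt$n)))
}

#' Split variation of information
#'
#' Decomposes VI(GT, SG) into an over-segmentation term (conditional entropy
#' of the segmentation given ground truth bodies -- how fragmented each true
#' body is) and an under-segmentation term (how many true bodies each
#' segment spans):
#' \deqn{VI_{OE} = -\sum_{i,j} \frac{|g_i \cap r_j|}{Z}
#'       \log\frac{|g_i \cap r_j|}{|g_i|}, \qquad
#'       VI_{UE} = -\sum_{i,j} \frac{|g_i \cap r_j|}{Z}
#'       \log\frac{|g_i \cap r_j|}{|r_j|}.}
#' Natural logarithm (nats); empty cells contribute nothing.
#'
#' @param ct a [ContingencyTable-class].
#' @return named numeric vector `c(viOE, viUE)`.
#' @export
splitVI <- function(ct) {
    cnt <- ct@counts
    if (nrow(cnt) == 0) stop("empty contingency table")
    Z <- ct@Z
    gSize <- tapply(cnt$n, cnt$g, sum)
    rSize <- tapply(cnt$n, cnt$r, sum)
    p <- cnt$n / Z
    viOE <- -sum(p * log(cnt$n / gSize[as.character(cnt$g)]))
    viUE <- -sum(p * log(cnt$n / rSize[as.character(cnt$r)]))
    # "+ 0" turns IEEE negative zero into plain zero
    c(viOE = max(viOE, 0) + 0, viUE = max(viUE, 0) + 0)
}

#' @noRd
choose2 <- function(n) n * (n - 1) / 2

#' Split Rand error
#'
#' Fraction of pixel pairs falsely split (same ground-truth body, different
#' segments; over-segmentation) and falsely merged (same segment, different
#' ground-truth bodies; under-segmentation), out of all Z(Z-1)/2 pairs of
#' counted pixels. Computed in closed form from the contingency table via
#' sums of binomial coefficients.
#'
#' @param ct a [ContingencyTable-class] with Z >= 2.
#' @return named numeric vector `c(reOE, reUE)`.
#' @export
splitRand <- function(ct) {
    cnt <- ct@counts
    Z <- ct@Z
    if (Z < 2) stop("need at least 2 counted pixels")
    gSize <- tapply(cnt$n, cnt$g, sum)
    rSize <- tapply(cnt$n, cnt$r, sum)
    sameBoth <- sum(choose2(cnt$n))
    total <- choose2(Z)
    c(reOE = (sum(choose2(gSize)) - sameBoth) / total,
      reUE = (sum(choose2(rSize)) - sameBoth) / total)
}

#' All four split error numbers at once
#'
#' @inheritParams contingencyTable
#' @return a [SplitMetrics-class].
#' @export
splitMetrics <- function(gt, sg, ignoreBackground = TRUE) {
    ct <- contingencyTable(gt, sg, ignoreBackground)
    vi <- splitVI(ct)
    re <- splitRand(ct)
    new("SplitMetrics", viOE = unname(vi[1]), viUE = unname(vi[2]),
        reOE = unname(re[1]), reUE = unname(re[2]), table = ct)
}

#' False-merge / false-split pixel-pair counts
#'
#' Raw (unnormalized) numerators of the split Rand error: the number of
#' pixel pairs placed in one segment although they belong to different
#' ground-truth bodies (`falseMergePairs`) and the number split although
#' they share a body (`falseSplitPairs`).
#'
#' @param ct a [ContingencyTable-class].
#' @return pair count (numeric).
#' @export
falseMergePairs <- function(ct) {
    cnt <- ct@counts
    rSize <- tapply(cnt$n, cnt$r, sum)
    sum(choose2(rSize)) - sum(choose2(cnt$n))
}

#' @rdname falseMergePairs
#' @export
falseSplitPairs <- function(ct) {
    cnt <- ct@counts
    gSize <- tapply(cnt$n, cnt$g, sum)
    sum(choose2(gSize)) - sum(choose2(cnt$n))
}

#' Under-/over-segmentation curve over a threshold sweep
#'
#' Runs one agglomeration per stopping threshold and tabulates the four
#' split errors, mirroring UE/OE curve plots.
#'
#' @param graph an initial [RegionGraph-class].
#' @param original the superpixel map the graph was built from.
#' @param gt ground-truth [LabelVolume-class].
#' @param h a [ConfidencePredictor-class].
#' @param deltas stopping thresholds to sweep.
#' @param mode "standard" or "delayed".
#' @return data.frame with one row per threshold.
#' @export
sweepThresholds <- function(graph, original, gt, h, deltas,
                            mode = c("delayed", "standard")) {
    mode <- match.arg(mode)
    rows <- lapply(deltas, function(delta) {
        g2 <- if (mode == "standard") standardAgglomerate(graph, h, delta)
              else delayedAgglomerate(graph, h, delta)
        sm <- splitMetrics(gt, exportLabels(g2, original))
        data.frame(delta = delta, viOE = sm@viOE, viUE = sm@viUE,
                   reOE = sm@reOE, reUE = sm@reUE,
                   nRegions = length(g2@nodes))
    })
    do.call(rbind, rows)
}
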