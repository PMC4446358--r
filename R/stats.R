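#' Mergeable statistics
#'
#' A moment-and-histogram summary of probability values over a pixel set,
#' kept per channel. The union of two summaries is field-wise addition and is
#' exact, so region and boundary statistics can be updated in constant time
#' after a merge instead of revisiting pixels. Quartiles are recovered from a
#' fixed-bin histogram over [0, 1] with linear interpolation inside the bin,
#' which bounds their error by one bin width.
#'
#' Internally a summary is a list with fields `count` (pixels), `s` and `ss`
#' (per-channel sum and sum of squares) and `hist` (channels x bins counts).
#'
#' @param nChannels number of probability channels.
#' @param nBins histogram bins over [0, 1] (default 64).
#' @return an empty `mergeable_stats` object.
#' @seealso [statsFromValues()], [statsUnion()], [statsQuartiles()]
#' @export
statsEmpty <- function(nChannels, nBins = 64L) {
    structure(list(count = 0L,
                   s = numeric(nChannels),
                   ss = numeric(nChannels),
                   hist = matrix(0L, nrow = nChannels, ncol = nBins)),
              class = "mergeable_stats")
}

#' Build mergeable statistics from raw values
#'
#' @param values numeric matrix, one row per pixel, one column per channel
#'   (a plain vector is treated as a single channel). Values must lie in
#'   [0, 1].
#' @param nBins histogram bins.
#' @return a `mergeable_stats` summary of the sample.
#' @export
statsFromValues <- function(values, nBins = 64L) {
    if (is.null(dim(values))) values <- matrix(values, ncol = 1)
    nc <- ncol(values)
    s <- statsEmpty(nc, nBins)
    if (nrow(values) == 0) return(s)
    if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
        stop("values must lie in [0, 1]")
    s$count <- nrow(values)
    s$s <- colSums(values)
    s$ss <- colSums(values^2)
    bin <- floor(values * nBins) + 1L
    bin[bin > nBins] <- nBins
    for (c in seq_len(nc))
        s$hist[c, ] <- tabulate(bin[, c], nbins = nBins)
    s
}

#' Exact union of two mergeable summaries
#'
#' Field-wise addition; the result summarizes the concatenation of the two
#' underlying samples exactly.
#'
#' @param a,b `mergeable_stats` with identical channel count and bin layout.
#' @return their union.
#' @export
statsUnion <- function(a, b) {
    if (!identical(dim(a$hist), dim(b$hist)))
        stop("bin layout mismatch: ", paste(dim(a$hist), collapse = "x"),
             " vs ", paste(dim(b$hist), collapse = "x"))
    a$count <- a$count + b$count
    a$s <- a$s + b$s
    a$ss <- a$ss + b$ss
    a$hist <- a$hist + b$hist
    a
}

#' @rdname statsFromValues
#' @param s a `mergeable_stats` object.
#' @return `statsMean`/`statsSd`: numeric vector, one value per channel.
#' @export
statsMean <- function(s) {
    if (s$count == 0) stop("empty statistics")
    s$s / s$count
}

#' @rdname statsFromValues
#' @details The standard deviation is the population form
#'   sqrt(E[x^2] - E[x]^2), clamped at zero against roundoff; a single
#'   sample has sd 0.
#' @export
statsSd <- function(s) {
    if (s$count == 0) stop("empty statistics")
    m <- s$s / s$count
    v <- s$ss / s$count - m^2
    sqrt(pmax(v, 0))
}

#' Histogram-interpolated quartiles
#'
#' Percentiles recovered from the fixed-bin histogram: within the bin that
#' contains the target rank the value is linearly interpolated, so each
#' quartile lies within one bin width of the exact sample percentile.
#'
#' @param s a `mergeable_stats` object with `count >= 1`.
#' @param probs percentile levels; the default reports the 25/50/75/100
#'   percentiles ("4 quartiles").
#' @return numeric matrix, channels x length(probs).
#' @export
statsQuartiles <- function(s, probs = c(0.25, 0.5, 0.75, 1)) {
    if (s$count == 0) stop("empty statistics")
    nb <- ncol(s$hist)
    width <- 1 / nb
    out <- matrix(0, nrow = nrow(s$hist), ncol = length(probs))
    for (c in seq_len(nrow(s$hist))) {
        h <- s$hist[c, ]
        cum <- cumsum(h)
        total <- cum[nb]
        for (j in seq_along(probs)) {
            target <- probs[j] * total
            if (target <= 0) {
                k <- which(h > 0)[1]
                out[c, j] <- (k - 1) * width
                next
            }
            k <- which(cum >= target - 1e-12)[1]
            below <- if (k == 1) 0 else cum[k - 1]
            frac <- (target - below) / h[k]
            out[c, j] <- (k - 1) * width + frac * width
        }
    }
    dimnames(out) <- list(NULL, paste0("q", round(probs * 100)))
    out
}
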