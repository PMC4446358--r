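`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
edgeKey <- function(a, b) {
    ifelse(a < b, paste0(a, "-", b), paste0(b, "-", a))
}

#' @noRd
keyEnds <- function(key) {
    as.integer(unlist(strsplit(key, "-", fixed = TRUE)))
}

# Evaluate a deterministic expression under a local RNG seed, restoring the
# caller's RNG state afterwards.
#' @noRd
withLocalSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Separable Gaussian smoothing of a 2D/3D array
#'
#' Reflection padding at the borders; a no-op when `sigma` is zero.
#'
#' @param arr numeric array (2D or 3D).
#' @param sigma smoothing scale in pixels.
#' @return array of the same shape.
#' @export
gaussianBlur <- function(arr, sigma) {
    if (sigma <= 0) return(arr)
    r <- max(1L, ceiling(3 * sigma))
    w <- dnorm(seq(-r, r), sd = sigma)
    w <- w / sum(w)
    d <- dim(arr)
    nd <- length(d)
    out <- arr
    for (axis in seq_len(nd)) {
        n <- d[axis]
        # reflected index for each shifted copy
        acc <- array(0, dim = d)
        for (k in seq(-r, r)) {
            idx <- seq_len(n) + k
            idx[idx < 1] <- 2 - idx[idx < 1]
            idx[idx > n] <- 2 * n - idx[idx > n]
            shifted <- switch(as.character(nd),
                "2" = if (axis == 1) out[idx, , drop = FALSE]
                      else out[, idx, drop = FALSE],
                "3" = if (axis == 1) out[idx, , , drop = FALSE]
                      else if (axis == 2) out[, idx, , drop = FALSE]
                      else out[, , idx, drop = FALSE])
            acc <- acc + w[k + r + 1] * shifted
        }
        out <- acc
    }
    out
}

# Binary dilation with the face-connectivity structuring element.
#' @noRd
dilateMask <- function(mask, rounds = 1L) {
    d <- dim(mask)
    nd <- length(d)
    out <- mask
    for (r in seq_len(rounds)) {
        acc <- out
        for (axis in seq_len(nd)) {
            n <- d[axis]
            for (k in c(-1L, 1L)) {
                idx <- pmin(pmax(seq_len(n) + k, 1L), n)
                shifted <- switch(as.character(nd),
                    "2" = if (axis == 1) out[idx, , drop = FALSE]
                          else out[, idx, drop = FALSE],
                    "3" = if (axis == 1) out[idx, , , drop = FALSE]
                          else if (axis == 2) out[, idx, , drop = FALSE]
                          else out[, , idx, drop = FALSE])
                acc <- acc | shifted
            }
        }
        out <- acc
    }
    out
}

# Pixels having at least one face neighbour with a different value.
#' @noRd
differingNeighbourMask <- function(arr) {
    d <- dim(arr)
    nd <- length(d)
    out <- array(FALSE, dim = d)
    for (axis in seq_len(nd)) {
        n <- d[axis]
        for (k in c(-1L, 1L)) {
            # clamped shifts make border comparisons self-comparisons (FALSE),
            # so pixels never count a neighbour beyond the image border
            idx <- pmin(pmax(seq_len(n) + k, 1L), n)
            shifted <- switch(as.character(nd),
                "2" = if (axis == 1) arr[idx, , drop = FALSE]
                      else arr[, idx, drop = FALSE],
                "3" = if (axis == 1) arr[idx, , , drop = FALSE]
                      else if (axis == 2) arr[, idx, , drop = FALSE]
                      else arr[, , idx, drop = FALSE])
            out <- out | (shifted != arr)
        }
    }
    out
}
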