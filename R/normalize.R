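#' Inter-sample quantile normalization
#'
#' Forces every sample (column) onto a common reference distribution:
#' the per-rank mean of the sorted columns. After normalization the
#' sorted value vectors of all samples are identical; ties within a
#' column receive the mean of the reference values across their tied
#' rank span. Gene and sample ordering are preserved, and the grand
#' mean of the matrix is unchanged by construction. The operation is
#' idempotent.
#'
#' For a \code{CoexPathExperiment} the raw \code{counts} assay is
#' normalized and stored as a new \code{normalized} assay; downstream
#' differential-expression testing consumes that assay with all size
#' factors implicitly 1 (quantile normalization replaces size-factor
#' estimation, so library-size correction is not applied twice).
#'
#' On tie-free data the postconditions are exact: every sorted column
#' equals the reference and re-normalizing changes nothing. Tied values
#' (frequent in low counts) share their span mean instead of distinct
#' reference values, so those two properties then hold only up to the
#' within-span spread; the grand mean is preserved exactly in all
#' cases, since each tied span redistributes but does not change its
#' total.
#'
#' @param x a numeric matrix (genes x samples) or a
#'   [CoexPathExperiment-class].
#' @param ... unused.
#' @return An object of the same class as \code{x}; for a matrix, the
#'   normalized matrix. A single-sample input is returned unchanged
#'   with a warning; an empty matrix is an error.
#' @examples
#' m <- matrix(c(1, 3, 4, 2), nrow = 2)
#' quantileNormalize(m)   # reference quantiles (1.5, 3.5)
#' @export
setGeneric("quantileNormalize",
           function(x, ...) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
    if (nrow(x) == 0L || ncol(x) == 0L)
        stop("cannot quantile-normalize an empty matrix")
    if (anyNA(x)) stop("counts contain NA")
    if (ncol(x) == 1L) {
        warning("single sample: quantile normalization is the identity")
        return(x + 0)    # raw integers promote to double
    }
    ref <- rowMeans(apply(x, 2, sort))
    cs <- cumsum(ref)
    out <- apply(x, 2, function(col) {
        lo <- rank(col, ties.method = "min")
        hi <- rank(col, ties.method = "max")
        ## mean of the reference values across each value's tied rank span
        (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
    })
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "CoexPathExperiment", function(x, ...) {
    assay(x, "normalized") <- quantileNormalize(assay(x, "counts"))
    x
})

#' Drop unexpressed genes
#'
#' Removes genes whose total count across all samples is below
#' \code{minTotal}; the order of surviving genes is preserved. The
#' default (\code{minTotal = 1}) drops all-zero genes only.
#'
#' @param x a counts matrix or [CoexPathExperiment-class].
#' @param minTotal minimum total count for a gene to be retained
#'   (\code{>= 0}).
#' @param ... unused.
#' @return object of the same class with low-count genes removed.
#' @export
setGeneric("filterUnexpressed",
           function(x, minTotal = 1, ...) standardGeneric("filterUnexpressed"))

#' @rdname filterUnexpressed
#' @export
setMethod("filterUnexpressed", "matrix", function(x, minTotal = 1, ...) {
    stopifnot(minTotal >= 0)
    x[rowSums(x) >= minTotal, , drop = FALSE]
})

#' @rdname filterUnexpressed
#' @export
setMethod("filterUnexpressed", "CoexPathExperiment",
          function(x, minTotal = 1, ...) {
    stopifnot(minTotal >= 0)
    x[rowSums(assay(x, "counts")) >= minTotal, ]
})
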