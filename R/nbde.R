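#' Estimate per-gene negative-binomial dispersion
#'
#' Method-of-moments estimation under the parameterisation
#' \eqn{\mathrm{Var} = \mu + \alpha \mu^2}: within-group residual sums
#' of squares are pooled across the design groups into a per-gene
#' variance \eqn{s^2} (degrees of freedom \eqn{n - G}), and the raw
#' estimate is \eqn{\hat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)}
#' with \eqn{\bar\mu} the mean of the group means. Raw estimates are
#' then shrunk toward a mean--dispersion trend (a \code{lowess} fit of
#' \eqn{\hat\alpha} against \eqn{\log \bar\mu}) with weight
#' \code{shrink}: \eqn{\hat\alpha_{shr} = (1 - w)\hat\alpha_{raw} +
#' w\,\hat\alpha_{trend}}. This trades the per-gene noise of a
#' small-replicate moment estimate against the information shared
#' across genes of similar expression; it is a deliberately simple
#' stand-in for full empirical-Bayes dispersion machinery.
#'
#' Genes with zero mean everywhere get \eqn{\hat\alpha = 0} and are
#' flagged in the \code{"zeroMean"} attribute.
#'
#' @param x a [CoexPathExperiment-class] (groups taken from its
#'   condition factor) or a numeric matrix.
#' @param groups factor of group membership per column (matrix method
#'   only).
#' @param shrink weight of the trend in the shrunken estimate, in
#'   \code{[0, 1]}; 0 disables shrinkage.
#' @param assayName assay to use for a \code{CoexPathExperiment}
#'   (\code{"normalized"} if present, else \code{"counts"}).
#' @param ... unused.
#' @return named numeric vector of dispersions, with attributes
#'   \code{"raw"} (unshrunken estimates) and \code{"zeroMean"}
#'   (logical flags).
#' @export
setGeneric("estimateDispersion",
           function(x, ...) standardGeneric("estimateDispersion"))

#' @rdname estimateDispersion
#' @export
setMethod("estimateDispersion", "matrix",
          function(x, groups, shrink = 0.5, ...) {
    stopifnot(length(groups) == ncol(x), shrink >= 0, shrink <= 1)
    groups <- droplevels(as.factor(groups))
    reps <- table(groups)
    if (!any(reps >= 2))
        stop("dispersion estimation needs >= 2 replicates in some group")
    idx <- split(seq_len(ncol(x)), groups)
    grpMeans <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]),
                       numeric(nrow(x)))
    if (nrow(x) == 1L)
        grpMeans <- matrix(grpMeans, nrow = 1,
                           dimnames = list(NULL, names(idx)))
    ss <- 0
    df <- 0L
    for (g in names(idx)) {
        j <- idx[[g]]
        ss <- ss + rowSums((x[, j, drop = FALSE] - grpMeans[, g])^2)
        df <- df + length(j) - 1L
    }
    s2 <- ss / df
    mbar <- rowMeans(grpMeans)
    zero <- mbar == 0
    raw <- numeric(nrow(x))
    raw[!zero] <- pmax(0, (s2[!zero] - mbar[!zero]) / mbar[!zero]^2)

    fit <- raw
    ok <- !zero
    if (sum(ok) >= 10) {    # too few genes to fit a trend otherwise
        lo <- stats::lowess(log(mbar[ok]), raw[ok], f = 0.5)
        trend <- stats::approx(lo$x, lo$y, xout = log(mbar[ok]), rule = 2,
                               ties = mean)$y
        fit[ok] <- pmax(0, (1 - shrink) * raw[ok] + shrink * pmax(0, trend))
    }
    names(fit) <- rownames(x)
    attr(fit, "raw") <- stats::setNames(raw, rownames(x))
    attr(fit, "zeroMean") <- stats::setNames(zero, rownames(x))
    attr(fit, "df") <- df
    fit
})

#' @rdname estimateDispersion
#' @export
setMethod("estimateDispersion", "CoexPathExperiment",
          function(x, shrink = 0.5, assayName = NULL, ...) {
    if (is.null(assayName))
        assayName <- if ("normalized" %in% assayNames(x)) "normalized"
                     else "counts"
    estimateDispersion(assay(x, assayName),
                       groups = sampleConditions(x), shrink = shrink)
})

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input indexing. A thin validated front end to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}; \code{NaN} or
#'   \code{NA} is an error.
#' @return adjusted values \code{q}, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
    if (anyNA(p)) stop("p-values contain NA/NaN")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Test one condition against the baseline
#'
#' Per-gene negative-binomial Wald test of a treated condition against
#' the shared baseline. With a log link and a two-group design the
#' maximum-likelihood group means are the sample means, so the log fold
#' change is estimated as
#' \eqn{\log\{(\bar y_c + c_0)/(\bar y_b + c_0)\}} with pseudocount
#' \eqn{c_0 = 0.5} (which keeps it finite), and its Wald standard error
#' follows from the Fisher information of the NB log-likelihood at
#' fixed dispersion:
#' \deqn{SE^2 = \frac{1}{n_c}\Big(\frac{1}{\bar y_c + c_0} + \alpha\Big)
#'            + \frac{1}{n_b}\Big(\frac{1}{\bar y_b + c_0} + \alpha\Big).}
#' Two-sided p-values come from the standard normal reference;
#' Benjamini-Hochberg adjustment is applied within the contrast.
#'
#' @param x a [CoexPathExperiment-class]; the \code{"normalized"} assay
#'   is used when present (see [quantileNormalize()]), otherwise raw
#'   counts.
#' @param contrast one of \code{"NC"} (non-injured + drug), \code{"IV"}
#'   (injured + vehicle), \code{"IC"} (injured + drug), each vs
#'   baseline.
#' @param dispersions per-gene dispersion vector as returned by
#'   [estimateDispersion()]; estimated internally when \code{NULL}.
#' @param pseudocount \eqn{c_0} added to group means (default 0.5).
#' @param assayName override the assay choice.
#' @return \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{contrast}, \code{baseMean_baseline},
#'   \code{baseMean_condition}, \code{log2FC}, \code{pvalue},
#'   \code{padj}, \code{dispersion}.
#' @examples
#' cpe <- quantileNormalize(simulateCounts(nGenes = 100, nReps = 3,
#'                                         seed = 7))
#' head(testContrast(cpe, "IV"))
#' @export
testContrast <- function(x, contrast = c("NC", "IV", "IC"),
                         dispersions = NULL, pseudocount = 0.5,
                         assayName = NULL) {
    contrast <- match.arg(contrast)
    condLevel <- .CONTRASTS[[contrast]]
    cond <- as.character(sampleConditions(x))
    for (lev in c("baseline", condLevel))
        if (sum(cond == lev) < 2L)
            stop(sprintf("condition '%s' needs >= 2 samples in the design",
                         lev))
    if (is.null(assayName))
        assayName <- if ("normalized" %in% assayNames(x)) "normalized"
                     else "counts"
    m <- assay(x, assayName)
    if (is.null(dispersions))
        dispersions <- estimateDispersion(x, assayName = assayName)
    stopifnot(length(dispersions) == nrow(m))

    nB <- sum(cond == "baseline")
    nC <- sum(cond == condLevel)
    mB <- rowMeans(m[, cond == "baseline", drop = FALSE])
    mC <- rowMeans(m[, cond == condLevel, drop = FALSE])
    a <- as.numeric(dispersions)

    lfcNat <- log((mC + pseudocount) / (mB + pseudocount))
    se <- sqrt((1 / nC) * (1 / (mC + pseudocount) + a) +
               (1 / nB) * (1 / (mB + pseudocount) + a))
    z <- lfcNat / se
    p <- 2 * stats::pnorm(-abs(z))

    data.frame(gene_id = rownames(m), contrast = contrast,
               baseMean_baseline = unname(mB),
               baseMean_condition = unname(mC),
               log2FC = unname(lfcNat / log(2)),
               pvalue = unname(p), padj = bhAdjust(unname(p)),
               dispersion = unname(a), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Differential expression for all three contrasts
#'
#' Runs [testContrast()] for NC, IV and IC against the shared baseline
#' with a single dispersion estimate. Adjustment is within each
#' contrast separately, since expression states are called per
#' contrast.
#'
#' @inheritParams testContrast
#' @return named list of three \code{data.frame}s (\code{NC},
#'   \code{IV}, \code{IC}).
#' @export
deAnalysis <- function(x, dispersions = NULL, pseudocount = 0.5,
                       assayName = NULL) {
    if (is.null(dispersions))
        dispersions <- estimateDispersion(x, assayName = assayName)
    res <- lapply(names(.CONTRASTS), function(ct)
        testContrast(x, ct, dispersions = dispersions,
                     pseudocount = pseudocount, assayName = assayName))
    names(res) <- names(.CONTRASTS)
    res
}
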