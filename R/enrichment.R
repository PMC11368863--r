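#' Hypergeometric over-representation test
#'
#' Upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}: the chance that a
#' random draw of \eqn{n} genes from a universe of \eqn{N}, of which
#' \eqn{K} belong to the set, contains \eqn{k} or more set members.
#'
#' @param k observed overlap between the path's genes and the set.
#' @param n number of genes in the path (the draw).
#' @param K number of set members in the universe.
#' @param N universe size.
#' @return the upper-tail p-value, in \code{(0, 1]}. Arguments may be
#'   vectors of a common length.
#' @examples
#' hypergeomTest(2, 3, 4, 10)   # 1/3
#' @export
hypergeomTest <- function(k, n, K, N) {
    if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 0))
        stop("all arguments must be non-negative")
    if (any(k > pmin(n, K)))
        stop("overlap k cannot exceed min(n, K)")
    if (any(n > N) || any(K > N))
        stop("draw and set sizes cannot exceed the universe size N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation for one path
#'
#' Tests each gene set for over-representation in a path's gene list
#' with [hypergeomTest()] against a fixed universe (by default all
#' genes that survived expression filtering and are annotatable).
#' Path genes outside the universe are dropped (with a message); set
#' members are intersected with the universe; sets overlapping the path
#' in fewer than \code{minOverlap} genes are not reported.
#' Benjamini-Hochberg adjustment is across the reported sets within the
#' path. The enrichment confidence is \eqn{-10 \log_{10} p} on the raw
#' p-value, the score conventionally plotted per path.
#'
#' @param genes character vector of the path's gene ids.
#' @param sets named list of gene-id vectors (see [readGmt()]).
#' @param universe character vector of all annotatable gene ids.
#' @param minOverlap minimum overlap for a set to be reported
#'   (default 2, suppressing singleton noise).
#' @return \code{data.frame} sorted by confidence (descending):
#'   \code{set_name}, \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{pvalue}, \code{padj}, \code{confidence}.
#' @examples
#' sets <- list(A = paste0("g", 1:5), B = paste0("g", 6:10))
#' enrichPath(paste0("g", 1:4), sets, paste0("g", 1:20))
#' @export
enrichPath <- function(genes, sets, universe, minOverlap = 2) {
    universe <- unique(universe)
    if (length(universe) == 0) stop("empty gene universe")
    dropped <- setdiff(genes, universe)
    if (length(dropped))
        message(length(dropped), " path gene(s) outside the universe ",
                "dropped")
    genes <- unique(intersect(genes, universe))
    sets <- lapply(sets, intersect, universe)
    empty <- lengths(sets) == 0
    if (any(empty)) {
        warning("dropping ", sum(empty),
                " gene set(s) with no members in the universe")
        sets <- sets[!empty]
    }
    n <- length(genes)
    N <- length(universe)
    k <- vapply(sets, function(s) length(intersect(genes, s)), integer(1))
    K <- lengths(sets)
    keep <- which(k >= minOverlap)
    res <- data.frame(set_name = names(sets)[keep], k = k[keep],
                      n = rep(n, length(keep)), K = K[keep],
                      N = rep(N, length(keep)), stringsAsFactors = FALSE)
    if (nrow(res) == 0) {
        res$pvalue <- numeric(0)
        res$padj <- numeric(0)
        res$confidence <- numeric(0)
        return(res)
    }
    res$pvalue <- hypergeomTest(res$k, res$n, res$K, res$N)
    res$padj <- bhAdjust(res$pvalue)
    res$confidence <- -10 * log10(res$pvalue)
    res <- res[order(-res$confidence, res$set_name), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Gene-set over-representation across paths
#'
#' Runs [enrichPath()] on each path's gene list from an assignment
#' table, by default on the ligand-informative (selected) paths only.
#'
#' @param assignments output of [assignGenes()].
#' @param catalog the matching [PathCatalog-class].
#' @inheritParams enrichPath
#' @param selectedOnly restrict to [selectedPaths()] (default);
#'   \code{FALSE} tests every non-empty path.
#' @return combined \code{data.frame} with a leading \code{path_id}
#'   column.
#' @export
enrichPaths <- function(assignments, catalog, sets, universe,
                        minOverlap = 2, selectedOnly = TRUE) {
    ids <- if (selectedOnly) selectedPaths(catalog)
           else pathEvents(catalog)$path_id
    res <- lapply(ids, function(pid) {
        g <- assignments$gene_id[assignments$path_id == pid]
        if (length(g) == 0) return(NULL)
        tab <- enrichPath(g, sets, universe, minOverlap = minOverlap)
        if (nrow(tab) == 0) return(NULL)
        cbind(path_id = pid, tab, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        res <- data.frame(path_id = character(), set_name = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), pvalue = numeric(),
                          padj = numeric(), confidence = numeric(),
                          stringsAsFactors = FALSE)
    res
}
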