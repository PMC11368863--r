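## Small builders shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

## minimal four-condition experiment from an explicit matrix
makeTinyExperiment <- function(counts, nReps = 2) {
    cond <- rep(c("baseline", "noninjured_drug", "injured_vehicle",
                  "injured_drug"), each = nReps)
    stopifnot(ncol(counts) == length(cond))
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
    CoexPathExperiment(counts, cond)
}

## the standard strong-effect planting used by several end-to-end tests:
## the four anchor paths at |log2FC| = 2
anchorPlanting <- function(nPerPath = 50, lfc = 2) {
    data.frame(triple = c("0+0", "00+", "0-0", "00-"),
               nGenes = nPerPath, lfc = lfc)
}

## independent brute-force upper-tail hypergeometric probability by
## exhaustive enumeration of all size-n subsets of 1..N (set = 1..K)
enumHyperTail <- function(k, n, K, N) {
    if (n == 0) return(as.numeric(k <= 0))
    subsets <- utils::combn(N, n)
    overlap <- apply(subsets, 2, function(s) sum(s <= K))
    mean(overlap >= k)
}

## write a small GMT file and return its path
writeTestGmt <- function(sets) {
    path <- tempfile(fileext = ".gmt")
    writeGmt(sets, path)
    path
}
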