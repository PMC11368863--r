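#' Read and write count matrices and sample sheets
#'
#' The counts file is a TSV whose first column is \code{gene_id} and
#' whose remaining columns are samples (integer cells for raw counts).
#' The sample sheet is a CSV with columns \code{sample_id} and
#' \code{condition}, the latter drawn from \code{baseline},
#' \code{noninjured_drug}, \code{injured_vehicle}, \code{injured_drug}.
#'
#' @param countsPath path to the counts TSV.
#' @param samplesPath path to the sample-sheet CSV.
#' @return \code{readCounts} returns a [CoexPathExperiment-class];
#'   writers return their output path invisibly.
#' @examples
#' cpe <- simulateCounts(nGenes = 50, nReps = 2, seed = 1)
#' tf <- tempfile(); sf <- tempfile()
#' writeCounts(cpe, tf, sf)
#' cpe2 <- readCounts(tf, sf)
#' all.equal(assay(cpe, "counts"), assay(cpe2, "counts"))
#' @export
readCounts <- function(countsPath, samplesPath) {
    if (!file.exists(countsPath)) stop("counts file not found: ", countsPath)
    if (!file.exists(samplesPath))
        stop("sample sheet not found: ", samplesPath)
    tab <- utils::read.table(countsPath, sep = "\t", header = TRUE,
                             check.names = FALSE,
                             colClasses = c(gene_id = "character"),
                             stringsAsFactors = FALSE)
    if (names(tab)[1] != "gene_id")
        stop("counts file ", countsPath, ", line 1: first column must be ",
             "'gene_id', got '", names(tab)[1], "'")
    if (anyDuplicated(tab$gene_id))
        stop("counts file ", countsPath, ": duplicate gene_id '",
             tab$gene_id[anyDuplicated(tab$gene_id)], "'")
    cts <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(cts)) {
        bad <- which(!apply(tab[, -1, drop = FALSE], 1,
                            function(r) all(!is.na(suppressWarnings(
                                as.numeric(r))))))[1]
        stop(sprintf("counts file %s, line %d: non-numeric count",
                     countsPath, bad + 1L))
    }
    rownames(cts) <- tab$gene_id

    sheet <- utils::read.csv(samplesPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "condition") %in% names(sheet)))
        stop("sample sheet ", samplesPath,
             ": needs columns sample_id, condition")
    bad <- which(!(sheet$condition %in% .CONDITIONS))
    if (length(bad))
        stop(sprintf("sample sheet %s, line %d: unknown condition '%s'",
                     samplesPath, bad[1] + 1L, sheet$condition[bad[1]]))
    miss <- setdiff(colnames(cts), sheet$sample_id)
    if (length(miss))
        stop("sample sheet ", samplesPath, ": no condition for sample(s) ",
             paste(miss, collapse = ", "))
    cond <- sheet$condition[match(colnames(cts), sheet$sample_id)]
    CoexPathExperiment(cts, cond)
}

#' @rdname readCounts
#' @param x a [CoexPathExperiment-class].
#' @param assayName which assay to write (raw \code{"counts"} by
#'   default; the \code{"normalized"} assay is written with 6 decimal
#'   places).
#' @export
writeCounts <- function(x, countsPath, samplesPath = NULL,
                        assayName = "counts") {
    m <- assay(x, assayName)
    vals <- if (assayName == "counts") format(m, trim = TRUE,
                                              scientific = FALSE)
            else sprintf("%.6f", m)
    out <- data.frame(gene_id = rownames(m),
                      matrix(vals, nrow = nrow(m),
                             dimnames = list(NULL, colnames(m))),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(samplesPath))
        utils::write.csv(data.frame(sample_id = colnames(x),
                                    condition = as.character(
                                        sampleConditions(x))),
                         samplesPath, row.names = FALSE, quote = FALSE)
    invisible(countsPath)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, member gene ids. Parsing is
#' delegated to \code{fgsea}; empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    sets <- fgsea::gmtPathways(path)
    empty <- lengths(sets) == 0
    if (any(empty)) {
        warning("dropping ", sum(empty), " empty gene set(s): ",
                paste(utils::head(names(sets)[empty], 3), collapse = ", "))
        sets <- sets[!empty]
    }
    sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
    stopifnot(!is.null(names(sets)), length(descriptions) == length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
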