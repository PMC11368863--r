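#' Simulate replicated negative-binomial counts with planted paths
#'
#' Generates a four-condition count experiment in which chosen numbers
#' of genes are planted into specified co-expression state triples at
#' specified log2 fold changes, and records the ground truth per gene.
#' Counts for gene \eqn{g} in sample \eqn{s} of condition \eqn{c} are
#' drawn from a negative binomial with mean
#' \deqn{\mu_{gs} = \mu_g \cdot 2^{L_{gc}} \cdot f_s}
#' where \eqn{\mu_g} is the gene's baseline mean (log-uniform over
#' \code{meanRange}), \eqn{L_{gc}} the planted log2 fold change for the
#' sample's condition (0 for the baseline and for every unplanted
#' position), and \eqn{f_s} the sample's library size factor. The
#' variance is \eqn{\mu + \alpha \mu^2} with per-gene dispersion
#' \eqn{\alpha}; \code{dispersion = 0} degenerates to Poisson.
#'
#' Genes not covered by \code{plantedPaths} are null genes and carry the
#' triple \code{(0,0,0)} explicitly in the truth table, so recovery
#' scoring is a comparison of two total partitions.
#'
#' @param nGenes total number of genes.
#' @param nReps replicates per condition. The design has four
#'   conditions, so \code{4 * nReps} samples are generated.
#' @param meanRange length-2 range of baseline mean counts; means are
#'   drawn log-uniformly over it.
#' @param dispersion NB dispersion \eqn{\alpha \ge 0}, scalar or
#'   per-gene vector of length \code{nGenes}.
#' @param plantedPaths \code{data.frame} with columns \code{triple}
#'   (3-character string over \code{+ 0 -}, positions = contrasts NC,
#'   IV, IC), \code{nGenes} and \code{lfc} (log2 fold-change magnitude,
#'   must be > 0; the sign is taken from the triple). \code{NULL}
#'   plants nothing.
#' @param sizeFactors per-sample positive multipliers, length
#'   \code{4 * nReps}; default all 1.
#' @param seed integer seed; identical seed and configuration reproduce
#'   identical output.
#'
#' @return A [CoexPathExperiment-class] whose \code{rowData} holds the
#'   truth table (see [truthTable()]).
#' @examples
#' cpe <- simulateCounts(nGenes = 200, nReps = 4,
#'                       plantedPaths = data.frame(triple = "0+0",
#'                                                 nGenes = 10, lfc = 2),
#'                       seed = 1)
#' table(truthTable(cpe)$state_IV)
#' @export
simulateCounts <- function(nGenes = 2000, nReps = 4,
                           meanRange = c(20, 2000), dispersion = 0.1,
                           plantedPaths = NULL, sizeFactors = NULL,
                           seed = NULL) {
    stopifnot(nGenes >= 1, nReps >= 1, length(meanRange) == 2,
              all(meanRange > 0), all(dispersion >= 0))
    nSamples <- 4L * as.integer(nReps)
    if (is.null(sizeFactors)) sizeFactors <- rep(1, nSamples)
    stopifnot(length(sizeFactors) == nSamples, all(sizeFactors > 0))
    if (length(dispersion) == 1L) dispersion <- rep(dispersion, nGenes)
    stopifnot(length(dispersion) == nGenes)

    planted <- .checkPlanted(plantedPaths, nGenes)
    if (!is.null(seed)) set.seed(seed)

    wid <- max(4L, nchar(as.character(nGenes)))
    geneIds <- sprintf(paste0("gene%0", wid, "d"), seq_len(nGenes))
    condition <- factor(rep(.CONDITIONS, each = nReps),
                        levels = .CONDITIONS)
    sampleIds <- paste(condition, rep(seq_len(nReps), times = 4),
                       sep = "_")

    baseMean <- exp(stats::runif(nGenes, log(meanRange[1]),
                                 log(meanRange[2])))

    ## per-gene true lfc for the three contrasts (columns NC, IV, IC)
    lfc <- matrix(0, nGenes, 3, dimnames = list(geneIds, names(.CONTRASTS)))
    state <- matrix("0", nGenes, 3,
                    dimnames = list(geneIds, names(.CONTRASTS)))
    if (nrow(planted)) {
        at <- 0L
        for (i in seq_len(nrow(planted))) {
            idx <- at + seq_len(planted$nGenes[i])
            st <- .parseTriple(planted$triple[i])
            sgn <- c(`+` = 1, `0` = 0, `-` = -1)[st]
            lfc[idx, ] <- rep(sgn * planted$lfc[i], each = length(idx))
            state[idx, ] <- rep(st, each = length(idx))
            at <- at + planted$nGenes[i]
        }
    }

    ## per-sample mean = baseline mean x 2^lfc(condition) x size factor;
    ## the baseline condition always has lfc 0
    condLfc <- cbind(baseline = 0, lfc[, match(.CONDITIONS[-1],
                                               .CONTRASTS[colnames(lfc)]),
                                       drop = FALSE])
    colnames(condLfc) <- .CONDITIONS
    mu <- baseMean * 2^condLfc[, as.character(condition), drop = FALSE]
    mu <- sweep(mu, 2, sizeFactors, `*`)

    counts <- matrix(0L, nGenes, nSamples,
                     dimnames = list(geneIds, sampleIds))
    pois <- dispersion == 0
    for (j in seq_len(nSamples)) {
        col <- numeric(nGenes)
        if (any(pois))
            col[pois] <- stats::rpois(sum(pois), mu[pois, j])
        if (any(!pois))
            col[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois, j],
                                         size = 1 / dispersion[!pois])
        counts[, j] <- as.integer(col)
    }

    truth <- DataFrame(state_NC = state[, "NC"], state_IV = state[, "IV"],
                       state_IC = state[, "IC"], lfc_NC = lfc[, "NC"],
                       lfc_IV = lfc[, "IV"], lfc_IC = lfc[, "IC"],
                       baseMean = baseMean, dispersion = dispersion,
                       row.names = geneIds)
    cpe <- CoexPathExperiment(counts, condition, rowData = truth)
    metadata(cpe)$simulation <- list(nGenes = nGenes, nReps = nReps,
                                     meanRange = meanRange,
                                     sizeFactors = sizeFactors,
                                     seed = seed)
    cpe
}

.parseTriple <- function(x) {
    st <- strsplit(x, "")[[1]]
    if (length(st) != 3L || !all(st %in% .STATES))
        stop(sprintf("malformed state triple '%s' (expect 3 chars over + 0 -)",
                     x))
    names(st) <- names(.CONTRASTS)
    st
}

.checkPlanted <- function(plantedPaths, nGenes) {
    if (is.null(plantedPaths))
        return(data.frame(triple = character(), nGenes = integer(),
                          lfc = numeric()))
    stopifnot(is.data.frame(plantedPaths),
              all(c("triple", "nGenes", "lfc") %in% names(plantedPaths)))
    if (sum(plantedPaths$nGenes) > nGenes)
        stop(sprintf("planted genes (%d) exceed nGenes (%d)",
                     sum(plantedPaths$nGenes), nGenes))
    nonNull <- plantedPaths$triple != "000"
    if (any(plantedPaths$lfc[nonNull] <= 0))
        stop("log2 fold-change magnitude must be > 0 for planted states")
    invisible(lapply(plantedPaths$triple, .parseTriple))
    plantedPaths
}

#' Extract the simulation truth table
#'
#' @param x a [CoexPathExperiment-class] produced by [simulateCounts()],
#'   or any object carrying the truth columns in its \code{rowData}.
#' @return \code{data.frame} with columns \code{gene_id},
#'   \code{state_NC}, \code{state_IV}, \code{state_IC}, \code{lfc_NC},
#'   \code{lfc_IV}, \code{lfc_IC}: the planted state triple and log2
#'   fold change per contrast for every simulated gene.
#' @export
truthTable <- function(x) {
    rd <- as.data.frame(rowData(x))
    need <- c("state_NC", "state_IV", "state_IC",
              "lfc_NC", "lfc_IV", "lfc_IC")
    if (!all(need %in% names(rd)))
        stop("no truth columns in rowData; was this object simulated?")
    data.frame(gene_id = rownames(rd), rd[, need], row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Write / read a truth table as TSV
#'
#' Plain TSV with columns \code{gene_id, state_NC, state_IV, state_IC,
#' lfc_NC, lfc_IV, lfc_IC}. \code{readTruth} validates states and
#' numeric fold changes and reports the offending file line on failure.
#'
#' @param truth a truth \code{data.frame} as returned by [truthTable()].
#' @param path file path.
#' @return \code{readTruth} returns the truth \code{data.frame};
#'   \code{writeTruth} returns \code{path} invisibly.
#' @export
writeTruth <- function(truth, path) {
    need <- c("gene_id", "state_NC", "state_IV", "state_IC",
              "lfc_NC", "lfc_IV", "lfc_IC")
    stopifnot(all(need %in% names(truth)))
    utils::write.table(truth[, need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    if (!file.exists(path)) stop("truth file not found: ", path)
    truth <- utils::read.table(path, sep = "\t", header = TRUE,
                               colClasses = c(gene_id = "character",
                                              state_NC = "character",
                                              state_IV = "character",
                                              state_IC = "character"),
                               stringsAsFactors = FALSE)
    need <- c("gene_id", "state_NC", "state_IV", "state_IC",
              "lfc_NC", "lfc_IV", "lfc_IC")
    if (!all(need %in% names(truth)))
        stop("truth file ", path, ": missing columns ",
             paste(setdiff(need, names(truth)), collapse = ", "))
    for (col in c("state_NC", "state_IV", "state_IC")) {
        bad <- which(!(truth[[col]] %in% .STATES))
        if (length(bad))
            stop(sprintf("truth file %s, line %d: invalid state '%s' in %s",
                         path, bad[1] + 1L, truth[[col]][bad[1]], col))
    }
    for (col in c("lfc_NC", "lfc_IV", "lfc_IC")) {
        bad <- which(is.na(suppressWarnings(as.numeric(truth[[col]]))))
        if (length(bad))
            stop(sprintf("truth file %s, line %d: non-numeric %s",
                         path, bad[1] + 1L, col))
        truth[[col]] <- as.numeric(truth[[col]])
    }
    if (anyDuplicated(truth$gene_id))
        stop("truth file ", path, ": duplicate gene_id")
    truth
}
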