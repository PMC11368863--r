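#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- colData colData<-
NULL

## The four-condition design: a shared baseline (non-injured, vehicle-treated)
## and three treated conditions, each contrasted against that baseline.
.CONDITIONS <- c("baseline", "noninjured_drug", "injured_vehicle",
                 "injured_drug")

## Contrast name -> treated condition level. NC = non-injured + drug,
## IV = injured + vehicle, IC = injured + drug (all vs baseline).
.CONTRASTS <- c(NC = "noninjured_drug", IV = "injured_vehicle",
                IC = "injured_drug")

## Discrete expression states, in display order: induced > unchanged >
## repressed.
.STATES <- c("+", "0", "-")

#' CoexPathExperiment: container for a four-condition count experiment
#'
#' A thin extension of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding a gene x
#' sample count matrix (assay \code{"counts"}) and a \code{condition}
#' column in \code{colData} over the four-condition design: a
#' \code{baseline} (non-injured, vehicle-treated) group plus
#' \code{noninjured_drug}, \code{injured_vehicle} and
#' \code{injured_drug}. All differential expression is computed against
#' the baseline group.
#'
#' @slot ... see \link[SummarizedExperiment]{SummarizedExperiment}.
#'
#' @section Validity:
#' \itemize{
#'   \item an assay named \code{"counts"} exists, is numeric and has no
#'     negative or missing values;
#'   \item gene and sample identifiers are present and unique;
#'   \item \code{colData(x)$condition} is a factor with levels drawn
#'     from the four design conditions, and the \code{baseline} level is
#'     represented by at least one sample.
#' }
#'
#' @seealso [CoexPathExperiment()] for the constructor,
#'   [simulateCounts()] to generate one with planted path structure.
#' @exportClass CoexPathExperiment
setClass("CoexPathExperiment", contains = "SummarizedExperiment")

setValidity("CoexPathExperiment", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (!is.numeric(cts))
            msg <- c(msg, "assay 'counts' must be numeric")
        else if (anyNA(cts) || any(cts < 0))
            msg <- c(msg, "assay 'counts' must be non-negative with no NAs")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cond <- colData(object)$condition
    if (is.null(cond)) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        if (!is.factor(cond))
            msg <- c(msg, "'condition' must be a factor")
        else {
            if (!all(levels(cond) %in% .CONDITIONS))
                msg <- c(msg, sprintf(
                    "condition levels must be drawn from: %s",
                    paste(.CONDITIONS, collapse = ", ")))
            if (!("baseline" %in% cond))
                msg <- c(msg, "at least one 'baseline' sample is required")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CoexPathExperiment
#'
#' @param counts gene x sample matrix of non-negative counts, with row
#'   (gene) and column (sample) names. Raw counts are integers;
#'   normalized values may be added later as the \code{"normalized"}
#'   assay.
#' @param condition character or factor of length \code{ncol(counts)}
#'   giving each sample's condition; values must be among
#'   \code{"baseline"}, \code{"noninjured_drug"},
#'   \code{"injured_vehicle"}, \code{"injured_drug"}.
#' @param rowData optional \link[S4Vectors]{DataFrame} of per-gene
#'   annotation (e.g. simulation truth).
#'
#' @return A [CoexPathExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(40, 50), nrow = 5,
#'               dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' cpe <- CoexPathExperiment(cts, rep(c("baseline", "injured_vehicle"),
#'                                    each = 4))
#' cpe
#' @export
CoexPathExperiment <- function(counts, condition, rowData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        stop("'counts' must have sample (column) names")
    condition <- factor(as.character(condition),
                        levels = intersect(.CONDITIONS,
                                           unique(as.character(condition))))
    if (length(condition) != ncol(counts))
        stop("'condition' must have one entry per sample")
    cd <- DataFrame(condition = condition, row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    if (!is.null(rowData)) rowData(se) <- rowData
    new("CoexPathExperiment", se)
}

#' @describeIn CoexPathExperiment sample condition factor, one entry
#'   per sample.
#' @param x a \code{CoexPathExperiment}.
#' @export
sampleConditions <- function(x) {
    stopifnot(is(x, "SummarizedExperiment"))
    colData(x)$condition
}

setMethod("show", "CoexPathExperiment", function(object) {
    callNextMethod()
    tab <- table(sampleConditions(object))
    cat("condition:", paste(sprintf("%s(%d)", names(tab), tab),
                            collapse = " "), "\n")
})

#' PathCatalog: the catalog of combinatorial co-expression events
#'
#' Holds the enumeration of all non-null state triples (one discrete
#' state per treated-vs-baseline contrast) as stable path identifiers,
#' together with the subset currently flagged as ligand-informative and
#' the literature aliases of the four anchor paths.
#'
#' With the standard three-state alphabet \code{+ / 0 / -} there are
#' \eqn{3^3 - 1 = 26} events; the all-null triple \code{(0,0,0)} is
#' excluded by construction.
#'
#' @slot events \code{data.frame} with columns \code{path_id},
#'   \code{s_NC}, \code{s_IV}, \code{s_IC}, \code{triple},
#'   \code{alias}; one row per event, lexicographically ordered.
#' @slot selected character vector of \code{path_id}s flagged
#'   ligand-informative (possibly empty before [selectLigandPaths()]).
#' @slot alphabet the state alphabet used for enumeration.
#'
#' @seealso [enumerateEvents()], [selectLigandPaths()], [assignGenes()]
#' @exportClass PathCatalog
setClass("PathCatalog",
         representation(events = "data.frame", selected = "character",
                        alphabet = "character"))

setValidity("PathCatalog", function(object) {
    msg <- character()
    ev <- object@events
    need <- c("path_id", "s_NC", "s_IV", "s_IC", "triple", "alias")
    if (!all(need %in% names(ev)))
        msg <- c(msg, paste("events must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(ev$triple))
            msg <- c(msg, "duplicate state triples in catalog")
        null <- paste(rep("0", 3), collapse = "")
        if (null %in% ev$triple)
            msg <- c(msg, "the null triple (0,0,0) must not be an event")
        if (!all(object@selected %in% ev$path_id))
            msg <- c(msg, "selected paths must be catalog events")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn PathCatalog the event table (one row per non-null
#'   triple).
#' @param catalog a \code{PathCatalog}.
#' @export
pathEvents <- function(catalog) {
    stopifnot(is(catalog, "PathCatalog"))
    catalog@events
}

#' @describeIn PathCatalog identifiers of the ligand-informative
#'   subset.
#' @export
selectedPaths <- function(catalog) {
    stopifnot(is(catalog, "PathCatalog"))
    catalog@selected
}

setMethod("show", "PathCatalog", function(object) {
    ev <- object@events
    cat(sprintf("PathCatalog: %d co-expression events over alphabet {%s}\n",
                nrow(ev), paste(object@alphabet, collapse = ",")))
    cat(sprintf("  selected (ligand-informative): %d\n",
                length(object@selected)))
    al <- ev[ev$alias != "", , drop = FALSE]
    if (nrow(al))
        cat("  anchors:", paste(sprintf("%s=%s(%s)", al$alias, al$path_id,
                                        al$triple), collapse = " "), "\n")
})
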