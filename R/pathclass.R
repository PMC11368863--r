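## Literature aliases for the four anchor paths: the triples whose
## biological reading the source experiment describes explicitly.
##   path4 (0,+,0): induced by injury, returned to basal by the drug
##   path2 (0,0,+): specifically induced by the drug in injured tissue
##   path5 (0,-,0): repressed by injury, returned to basal by the drug
##   path7 (0,0,-): specifically repressed by the drug in injured tissue
.ANCHORS <- c("00+" = "path2", "0+0" = "path4", "0-0" = "path5",
              "00-" = "path7")

#' Call a discrete expression state from a DE result
#'
#' A gene is \code{"+"} (induced) when \code{q <= qThreshold} and
#' \code{log2FC >= lfcThreshold}; \code{"-"} (repressed) when
#' \code{q <= qThreshold} and \code{log2FC <= -lfcThreshold}; otherwise
#' \code{"0"} (not differentially expressed). Both thresholds are
#' deliberate analysis knobs: the discretisation into states is what
#' makes the combinatorial path classification possible, and moving
#' either threshold redraws every path boundary.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param q matching vector of adjusted p-values.
#' @param qThreshold significance cutoff on the adjusted p (default
#'   0.05).
#' @param lfcThreshold minimum absolute log2 fold change (default 1,
#'   i.e. two-fold).
#' @return character vector of states over \code{+ 0 -}.
#' @examples
#' callState(c(2, -0.2, -1.5), c(0.01, 0.001, 0.04))
#' @export
callState <- function(log2fc, q, qThreshold = 0.05, lfcThreshold = 1) {
    stopifnot(length(log2fc) == length(q), qThreshold > 0, qThreshold < 1,
              lfcThreshold >= 0)
    if (anyNA(log2fc) || anyNA(q)) stop("NA in log2fc or q")
    st <- rep("0", length(log2fc))
    st[q <= qThreshold & log2fc >= lfcThreshold] <- "+"
    st[q <= qThreshold & log2fc <= -lfcThreshold] <- "-"
    st
}

#' Combine per-contrast DE results into per-gene state triples
#'
#' @param de named list of DE tables for contrasts \code{NC}, \code{IV},
#'   \code{IC} as produced by [deAnalysis()]; all three must cover the
#'   same genes.
#' @inheritParams callState
#' @return \code{data.frame} with columns \code{gene_id},
#'   \code{state_NC}, \code{state_IV}, \code{state_IC}.
#' @export
callStates <- function(de, qThreshold = 0.05, lfcThreshold = 1) {
    stopifnot(all(names(.CONTRASTS) %in% names(de)))
    ids <- de$NC$gene_id
    for (ct in c("IV", "IC")) {
        other <- de[[ct]]$gene_id
        if (!identical(sort(ids), sort(other)))
            stop("contrast ", ct, " is missing gene(s): ",
                 paste(utils::head(setdiff(ids, other), 3), collapse = ", "))
    }
    out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (ct in names(.CONTRASTS)) {
        tab <- de[[ct]][match(ids, de[[ct]]$gene_id), ]
        bad <- is.na(tab$log2FC) | is.na(tab$padj)
        if (any(bad))
            stop("missing ", ct, " call for gene(s): ",
                 paste(utils::head(ids[bad], 3), collapse = ", "))
        out[[paste0("state_", ct)]] <-
            callState(tab$log2FC, tab$padj, qThreshold, lfcThreshold)
    }
    out
}

#' Enumerate the combinatorial co-expression events
#'
#' All state triples over the alphabet, excluding the all-null triple,
#' in lexicographic order over \code{(s_NC, s_IV, s_IC)} with the
#' alphabet order \code{+ < 0 < -}. With the standard three-state
#' alphabet this yields the \eqn{3^3 - 1 = 26} candidate events, with
#' stable identifiers \code{path01} ... \code{path26}; the four anchor
#' triples carry their literature aliases (paths 2, 4, 5, 7).
#'
#' @param alphabet state alphabet (a test hook; e.g. \code{c("+", "0")}
#'   yields \eqn{2^3 - 1 = 7} events). Must contain \code{"0"}.
#' @return a [PathCatalog-class] with no paths selected yet.
#' @examples
#' enumerateEvents()
#' @export
enumerateEvents <- function(alphabet = c("+", "0", "-")) {
    stopifnot(!anyDuplicated(alphabet), "0" %in% alphabet)
    g <- expand.grid(s_IC = alphabet, s_IV = alphabet, s_NC = alphabet,
                     stringsAsFactors = FALSE)   # s_NC varies slowest
    ev <- data.frame(s_NC = g$s_NC, s_IV = g$s_IV, s_IC = g$s_IC,
                     stringsAsFactors = FALSE)
    ev$triple <- paste0(ev$s_NC, ev$s_IV, ev$s_IC)
    ev <- ev[ev$triple != "000", , drop = FALSE]
    ev$path_id <- sprintf("path%02d", seq_len(nrow(ev)))
    ev$alias <- ifelse(is.na(.ANCHORS[ev$triple]), "",
                       .ANCHORS[ev$triple])
    rownames(ev) <- NULL
    new("PathCatalog",
        events = ev[, c("path_id", "s_NC", "s_IV", "s_IC", "triple",
                        "alias")],
        selected = character(), alphabet = alphabet)
}

#' Flag the ligand-informative subset of paths
#'
#' Selects the events from which an effect of the drug in injured
#' tissue can be inferred. The default rule takes the triples with no
#' drug response in non-injured tissue but discordant injury responses
#' with and without the drug (\code{s_NC = 0} and \code{s_IV != s_IC};
#' 6 triples, containing all four anchor paths), plus the two triples
#' with a consistent injury-independent drug response
#' (\code{(+,0,+)} and \code{(-,0,-)}) — 8 paths in total. The rule is
#' a reconstruction and is fully configurable: pass \code{triples} to
#' select an explicit list instead.
#'
#' @param catalog a [PathCatalog-class] from [enumerateEvents()].
#' @param rule \code{"ligand-default"} (8 paths, above) or
#'   \code{"divergent"} (\code{s_IV != s_IC} alone; 18 paths).
#' @param triples optional explicit character vector of 3-character
#'   triples (e.g. \code{c("0+0", "00+")}); overrides \code{rule}.
#'   Selecting the null triple \code{"000"} is an error.
#' @return the catalog with its \code{selected} slot set.
#' @examples
#' cat26 <- selectLigandPaths(enumerateEvents())
#' selectedPaths(cat26)
#' @export
selectLigandPaths <- function(catalog,
                              rule = c("ligand-default", "divergent"),
                              triples = NULL) {
    stopifnot(is(catalog, "PathCatalog"))
    ev <- pathEvents(catalog)
    if (!is.null(triples)) {
        if ("000" %in% triples)
            stop("the null triple (0,0,0) cannot be selected")
        miss <- setdiff(triples, ev$triple)
        if (length(miss))
            stop("unknown triple(s): ", paste(miss, collapse = ", "))
        sel <- ev$path_id[ev$triple %in% triples]
    } else {
        rule <- match.arg(rule)
        sel <- switch(rule,
            "ligand-default" = ev$path_id[
                (ev$s_NC == "0" & ev$s_IV != ev$s_IC) |
                ev$triple %in% c("+0+", "-0-")],
            "divergent" = ev$path_id[ev$s_IV != ev$s_IC])
    }
    catalog@selected <- sel
    validObject(catalog)
    catalog
}

#' Assign genes to co-expression paths
#'
#' Partitions genes by their state triple: every gene with a non-null
#' triple belongs to exactly one catalog path; genes with the null
#' triple \code{(0,0,0)} go to the \code{"unchanged"} bucket. The
#' partition identity (path counts plus unchanged equals genes tested)
#' is asserted on every run.
#'
#' @param states per-gene state calls from [callStates()].
#' @param catalog a [PathCatalog-class].
#' @return \code{data.frame} with columns \code{gene_id},
#'   \code{state_NC}, \code{state_IV}, \code{state_IC}, \code{triple},
#'   \code{path_id} (\code{"unchanged"} for null triples),
#'   \code{alias}.
#' @export
assignGenes <- function(states, catalog) {
    stopifnot(is(catalog, "PathCatalog"))
    need <- c("gene_id", "state_NC", "state_IV", "state_IC")
    stopifnot(all(need %in% names(states)))
    for (col in need[-1]) {
        bad <- is.na(states[[col]]) | !(states[[col]] %in% .STATES)
        if (any(bad))
            stop("missing or invalid ", col, " for gene(s): ",
                 paste(utils::head(states$gene_id[bad], 3), collapse = ", "))
    }
    if (anyDuplicated(states$gene_id))
        stop("duplicate gene_id in state calls")
    ev <- pathEvents(catalog)
    triple <- paste0(states$state_NC, states$state_IV, states$state_IC)
    hit <- match(triple, ev$triple)
    out <- data.frame(states[, need], triple = triple,
                      path_id = ifelse(is.na(hit), "unchanged",
                                       ev$path_id[hit]),
                      alias = ifelse(is.na(hit), "", ev$alias[hit]),
                      stringsAsFactors = FALSE)
    ## partition identity: every gene in exactly one bucket
    stopifnot(sum(table(out$path_id)) == nrow(states),
              all(out$path_id != "unchanged" | out$triple == "000"))
    out
}

#' Per-path gene counts
#'
#' @param assignments output of [assignGenes()].
#' @param catalog the matching [PathCatalog-class].
#' @return \code{data.frame} with one row per catalog event plus an
#'   \code{"unchanged"} row: \code{path_id}, \code{triple},
#'   \code{alias}, \code{selected}, \code{n_genes}.
#' @export
pathSummary <- function(assignments, catalog) {
    ev <- pathEvents(catalog)
    counts <- table(factor(assignments$path_id,
                           levels = c(ev$path_id, "unchanged")))
    data.frame(path_id = names(counts),
               triple = c(ev$triple, "000"),
               alias = c(ev$alias, ""),
               selected = c(ev$path_id %in% selectedPaths(catalog), FALSE),
               n_genes = as.integer(counts),
               row.names = NULL, stringsAsFactors = FALSE)
}
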