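#' Run the full co-expression path pipeline
#'
#' Orchestrates normalize, differential expression, state/path
#' classification and (optionally) per-path gene-set enrichment as one
#' reproducible run: reads the counts TSV and sample-sheet CSV,
#' quantile-normalizes, tests the three contrasts against the baseline,
#' calls per-gene state triples, assigns genes to the 26-event catalog
#' with the ligand-informative subset flagged, and writes all result
#' tables plus a JSON manifest (configuration snapshot, input digests,
#' per-stage row counts) into \code{outDir}. Re-running with identical
#' inputs reproduces byte-identical outputs.
#'
#' @param countsPath counts TSV (first column \code{gene_id}).
#' @param samplesPath sample-sheet CSV (\code{sample_id, condition}).
#' @param gmtPath optional GMT file of gene sets; enrichment is skipped
#'   when \code{NULL}.
#' @param outDir output directory (created if needed); input files are
#'   never modified.
#' @param qThreshold,lfcThreshold state-call thresholds (see
#'   [callState()]).
#' @param minTotal expression filter (see [filterUnexpressed()]).
#' @param minOverlap enrichment reporting threshold (see
#'   [enrichPath()]).
#' @param selectionRule,selectedTriples path selection (see
#'   [selectLigandPaths()]).
#' @param configPath optional YAML file whose keys (\code{q_threshold},
#'   \code{lfc_threshold}, \code{min_total}, \code{min_overlap},
#'   \code{selection_rule}, \code{selected_triples}) override the
#'   corresponding arguments.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) a list with the result objects and the manifest.
#' @export
runPipeline <- function(countsPath, samplesPath, gmtPath = NULL,
                        outDir = "coexpaths_run", qThreshold = 0.05,
                        lfcThreshold = 1, minTotal = 1, minOverlap = 2,
                        selectionRule = "ligand-default",
                        selectedTriples = NULL, configPath = NULL,
                        quiet = FALSE) {
    log <- function(stage, ...) if (!quiet)
        message(sprintf("[%s] %s", stage, sprintf(...)))
    if (!is.null(configPath)) {
        if (!file.exists(configPath))
            stop("config file not found: ", configPath)
        cfg <- yaml::read_yaml(configPath)
        known <- c(q_threshold = "qThreshold",
                   lfc_threshold = "lfcThreshold", min_total = "minTotal",
                   min_overlap = "minOverlap",
                   selection_rule = "selectionRule",
                   selected_triples = "selectedTriples")
        bad <- setdiff(names(cfg), names(known))
        if (length(bad))
            stop("config file ", configPath, ": unknown key(s) ",
                 paste(bad, collapse = ", "))
        for (key in names(cfg)) assign(known[[key]], cfg[[key]])
        if (!is.null(cfg$selected_triples))
            selectedTriples <- as.character(cfg$selected_triples)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    cpe <- readCounts(countsPath, samplesPath)
    miss <- setdiff(.CONDITIONS, as.character(sampleConditions(cpe)))
    if (length(miss))
        stop("design is missing condition(s): ", paste(miss, collapse = ", "))
    nIn <- nrow(cpe)
    log("input", "%d genes x %d samples", nIn, ncol(cpe))

    cpe <- filterUnexpressed(cpe, minTotal = minTotal)
    log("filter", "%d genes with total count >= %g", nrow(cpe), minTotal)
    cpe <- quantileNormalize(cpe)
    writeCounts(cpe, file.path(outDir, "normalized_counts.tsv"),
                assayName = "normalized")
    log("normalize", "quantile-normalized %d samples", ncol(cpe))

    disp <- estimateDispersion(cpe)
    de <- deAnalysis(cpe, dispersions = disp)
    for (ct in names(de)) {
        tab <- de[[ct]]
        out <- data.frame(tab[, c("gene_id", "baseMean_baseline",
                                  "baseMean_condition")],
                          log2FC = sprintf("%.6f", tab$log2FC),
                          pvalue = format(tab$pvalue, digits = 6),
                          padj = format(tab$padj, digits = 6),
                          stringsAsFactors = FALSE)
        out$baseMean_baseline <- sprintf("%.6f", tab$baseMean_baseline)
        out$baseMean_condition <- sprintf("%.6f", tab$baseMean_condition)
        utils::write.table(out, file.path(outDir,
                                          sprintf("de_%s.tsv", ct)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log("de", "%s vs baseline: %d genes, %d at padj <= %g", ct,
            nrow(tab), sum(tab$padj <= qThreshold), qThreshold)
    }

    states <- callStates(de, qThreshold = qThreshold,
                         lfcThreshold = lfcThreshold)
    catalog <- selectLigandPaths(enumerateEvents(), rule = selectionRule,
                                 triples = selectedTriples)
    assignments <- assignGenes(states, catalog)
    summary <- pathSummary(assignments, catalog)
    utils::write.table(assignments, file.path(outDir, "gene_paths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(outDir, "path_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("paths", "%d/%d genes in a non-null path; %d paths selected",
        sum(assignments$path_id != "unchanged"), nrow(assignments),
        length(selectedPaths(catalog)))

    enr <- NULL
    if (!is.null(gmtPath)) {
        sets <- readGmt(gmtPath)
        universe <- intersect(assignments$gene_id,
                              unique(unlist(sets, use.names = FALSE)))
        enr <- enrichPaths(assignments, catalog, sets, universe,
                           minOverlap = minOverlap)
        out <- enr
        if (nrow(out)) {
            out$pvalue <- format(out$pvalue, digits = 6)
            out$padj <- format(out$padj, digits = 6)
            out$confidence <- sprintf("%.4f", enr$confidence)
        }
        utils::write.table(out, file.path(outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log("enrich", "%d (path, set) results over %d selected paths",
            nrow(enr), length(selectedPaths(catalog)))
    }

    manifest <- list(
        tool = "coexPaths",
        version = as.character(utils::packageVersion("coexPaths")),
        config = list(qThreshold = qThreshold,
                      lfcThreshold = lfcThreshold, minTotal = minTotal,
                      minOverlap = minOverlap,
                      selectionRule = selectionRule,
                      selectedTriples = selectedTriples),
        inputs = .fileDigests(c(counts = countsPath,
                                samples = samplesPath,
                                gmt = if (is.null(gmtPath)) NULL
                                      else gmtPath)),
        stages = list(genes_in = nIn, genes_filtered = nrow(cpe),
                      samples = ncol(cpe),
                      de_rows = vapply(de, nrow, integer(1)),
                      genes_assigned = nrow(assignments),
                      paths_selected = length(selectedPaths(catalog)),
                      enrichment_rows = if (is.null(enr)) 0L
                                        else nrow(enr)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ## conservation check: genes in = genes out across stages
    stopifnot(nrow(assignments) == nrow(cpe))
    invisible(list(experiment = cpe, de = de, states = states,
                   catalog = catalog, assignments = assignments,
                   summary = summary, enrichment = enr,
                   manifest = manifest))
}

.fileDigests <- function(paths) {
    paths <- unlist(paths)
    stats::setNames(as.list(unname(tools::md5sum(paths))), names(paths))
}

#' Score path recovery against a simulation truth table
#'
#' Compares predicted path assignments with the planted truth: for each
#' planted (non-null) path, precision, recall and F1 of the predicted
#' gene list; overall, the fraction of genes whose full state triple is
#' called exactly (a total-partition accuracy, since null genes carry
#' the explicit triple \code{(0,0,0)}). Paths with no planted and no
#' predicted genes report \code{NA} metrics.
#'
#' @param assignments output of [assignGenes()] (columns \code{gene_id},
#'   \code{triple}, \code{path_id}).
#' @param truth a truth \code{data.frame} from [truthTable()] or
#'   [readTruth()].
#' @return list with \code{perPath} (\code{data.frame}: \code{path_id},
#'   \code{triple}, \code{n_true}, \code{n_pred}, \code{tp},
#'   \code{precision}, \code{recall}, \code{f1}) and \code{accuracy}.
#' @export
scoreRecovery <- function(assignments, truth) {
    mism <- c(setdiff(assignments$gene_id, truth$gene_id),
              setdiff(truth$gene_id, assignments$gene_id))
    if (length(mism))
        stop("gene ids differ between assignments and truth, e.g.: ",
             paste(utils::head(mism, 5), collapse = ", "))
    truth <- truth[match(assignments$gene_id, truth$gene_id), ]
    trueTriple <- paste0(truth$state_NC, truth$state_IV, truth$state_IC)
    predTriple <- assignments$triple
    accuracy <- mean(predTriple == trueTriple)

    catalog <- enumerateEvents()
    ev <- pathEvents(catalog)
    paths <- unique(c(ev$triple[ev$triple %in% trueTriple]))
    perPath <- do.call(rbind, lapply(paths, function(tr) {
        isTrue <- trueTriple == tr
        isPred <- predTriple == tr
        tp <- sum(isTrue & isPred)
        prec <- if (sum(isPred)) tp / sum(isPred) else NA_real_
        rec <- if (sum(isTrue)) tp / sum(isTrue) else NA_real_
        f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
                  2 * prec * rec / (prec + rec) else NA_real_
        data.frame(path_id = ev$path_id[ev$triple == tr], triple = tr,
                   n_true = sum(isTrue), n_pred = sum(isPred), tp = tp,
                   precision = prec, recall = rec, f1 = f1,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(perPath))
        perPath <- data.frame(path_id = character(), triple = character(),
                              n_true = integer(), n_pred = integer(),
                              tp = integer(), precision = numeric(),
                              recall = numeric(), f1 = numeric(),
                              stringsAsFactors = FALSE)
    list(perPath = perPath, accuracy = accuracy)
}
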