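test_that("state calls follow the significance-and-effect rule", {
    expect_equal(callState(2.0, 0.01), "+")
    expect_equal(callState(-0.2, 0.001), "0")  # significant, small effect
    expect_equal(callState(-1.5, 0.04), "-")
    expect_equal(callState(1.5, 0.2), "0")     # large effect, not significant
    ## thresholds are inclusive
    expect_equal(callState(1, 0.05), "+")
    expect_equal(callState(-1, 0.05), "-")
})

test_that("state calling is monotone in effect size at fixed q", {
    set.seed(55)
    for (i in 1:50) {
        lfc <- runif(1, -3, 3)
        q <- runif(1, 0, 1)
        st <- callState(lfc, q)
        if (st %in% c("+", "-")) {
            expect_equal(callState(lfc * 2, q), st)  # never back to 0
        }
    }
})

test_that("the catalog enumerates exactly the 26 non-null triples", {
    catalog <- enumerateEvents()
    ev <- pathEvents(catalog)
    expect_equal(nrow(ev), 26)
    expect_false("000" %in% ev$triple)
    expect_equal(ev$path_id, sprintf("path%02d", 1:26))
    ## lexicographic over (s_NC, s_IV, s_IC) with + < 0 < -
    expect_equal(ev$triple[1:4], c("+++", "++0", "++-", "+0+"))
    expect_equal(ev$triple[26], "---")
    ## deterministic and order-stable
    expect_identical(ev, pathEvents(enumerateEvents()))
})

test_that("the generic alphabet hook gives 2^3 - 1 events", {
    ev <- pathEvents(enumerateEvents(alphabet = c("+", "0")))
    expect_equal(nrow(ev), 7)
    expect_false("000" %in% ev$triple)
})

test_that("anchor aliases attach to the described expression patterns", {
    ev <- pathEvents(enumerateEvents())
    ## drug-specific induction in injury; return to basal (up);
    ## return to basal (down); drug-specific repression in injury
    expect_equal(ev$triple[ev$alias == "path2"], "00+")
    expect_equal(ev$triple[ev$alias == "path4"], "0+0")
    expect_equal(ev$triple[ev$alias == "path5"], "0-0")
    expect_equal(ev$triple[ev$alias == "path7"], "00-")
})

test_that("the default ligand-informative rule selects 8 paths with all anchors", {
    catalog <- selectLigandPaths(enumerateEvents())
    sel <- selectedPaths(catalog)
    expect_length(sel, 8)
    ev <- pathEvents(catalog)
    selTriples <- ev$triple[ev$path_id %in% sel]
    expect_true(all(c("0+0", "00+", "0-0", "00-") %in% selTriples))
    expect_true(all(c("+0+", "-0-") %in% selTriples))
})

test_that("the divergent rule selects the 18 triples with s_IV != s_IC", {
    ## brute-force expectation over all 27 triples: 3 * (9 - 3) = 18
    grid <- expand.grid(a = c("+", "0", "-"), b = c("+", "0", "-"),
                        c = c("+", "0", "-"), stringsAsFactors = FALSE)
    expected <- sum(grid$b != grid$c)
    catalog <- selectLigandPaths(enumerateEvents(), rule = "divergent")
    expect_equal(length(selectedPaths(catalog)), expected)
    expect_equal(expected, 18)
})

test_that("explicit triple selection is validated", {
    catalog <- enumerateEvents()
    sel <- selectLigandPaths(catalog, triples = c("0+0", "00-"))
    expect_length(selectedPaths(sel), 2)
    expect_error(selectLigandPaths(catalog, triples = c("0+0", "000")),
                 "null triple")
    expect_error(selectLigandPaths(catalog, triples = "0*0"), "unknown")
})

test_that("gene assignment is a partition of all genes", {
    catalog <- selectLigandPaths(enumerateEvents())
    states <- data.frame(gene_id = paste0("g", 1:8),
                         state_NC = c("0", "0", "0", "0", "+", "0", "0", "0"),
                         state_IV = c("+", "+", "+", "+", "0", "0", "-", "0"),
                         state_IC = c("0", "0", "0", "0", "0", "0", "-", "0"),
                         stringsAsFactors = FALSE)
    asg <- assignGenes(states, catalog)
    ## 4 genes all (0,+,0) -> the path4 anchor; none elsewhere in it
    expect_equal(sum(asg$alias == "path4"), 4)
    summary <- pathSummary(asg, catalog)
    expect_equal(summary$n_genes[summary$alias == "path4"], 4)
    ## partition identity: path counts + unchanged = genes tested
    expect_equal(sum(summary$n_genes), nrow(states))
    expect_equal(summary$n_genes[summary$path_id == "unchanged"], 2)
    ## each non-null gene in exactly one path
    expect_false(any(duplicated(asg$gene_id)))
})

test_that("missing state calls are reported with the gene name", {
    catalog <- enumerateEvents()
    states <- data.frame(gene_id = c("gA", "gB"), state_NC = c("0", "0"),
                         state_IV = c("+", NA), state_IC = c("0", "0"),
                         stringsAsFactors = FALSE)
    expect_error(assignGenes(states, catalog), "gB")
})

test_that("negating fold changes mirrors calls and path assignments", {
    set.seed(77)
    n <- 300
    lfc <- runif(n, -3, 3)
    q <- runif(n, 0, 0.2)
    mkStates <- function(l) data.frame(
        gene_id = paste0("g", 1:n),
        state_NC = callState(l, q),
        state_IV = callState(rev(l), rev(q)),
        state_IC = callState(l * 0.7, q),
        stringsAsFactors = FALSE)
    flip <- function(s) chartr("+-", "-+", s)
    catalog <- enumerateEvents()
    a1 <- assignGenes(mkStates(lfc), catalog)
    a2 <- assignGenes(mkStates(-lfc), catalog)
    ## states mirror + <-> - elementwise, so triples map to the
    ## sign-mirrored triple and genes land in the mirrored path
    expect_equal(a2$triple, flip(a1$triple))
    ev <- pathEvents(catalog)
    mirroredPath <- ev$path_id[match(flip(a1$triple), ev$triple)]
    mirroredPath[is.na(mirroredPath)] <- "unchanged"
    expect_equal(a2$path_id, mirroredPath)
})
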