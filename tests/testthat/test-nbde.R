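test_that("method-of-moments dispersion is consistent on Poisson data", {
    ## true alpha = 0: estimate within 0.01 of zero given many replicates
    set.seed(31)
    m <- matrix(rpois(1000, 100), nrow = 1)
    a <- estimateDispersion(m, groups = rep("g1", 1000))
    expect_lt(attr(a, "raw")[1], 0.01)
})

test_that("method-of-moments dispersion recovers a large NB dispersion", {
    ## alpha = 0.5 at mu = 100, many replicates: within 10%
    set.seed(32)
    m <- matrix(rnbinom(10000, mu = 100, size = 2), nrow = 1)
    a <- estimateDispersion(m, groups = rep("g1", 10000))
    expect_equal(unname(attr(a, "raw")[1]), 0.5, tolerance = 0.1)
})

test_that("degenerate genes get zero raw dispersion and a flag", {
    m <- rbind(const = rep(7, 8), zero = rep(0, 8),
               var = c(1, 9, 3, 7, 2, 8, 4, 6))
    a <- estimateDispersion(m, groups = rep(c("A", "B"), each = 4),
                            shrink = 0)
    expect_equal(unname(attr(a, "raw")["const"]), 0)  # zero within-group var
    expect_equal(unname(a["zero"]), 0)
    expect_true(attr(a, "zeroMean")["zero"])
    expect_false(attr(a, "zeroMean")["const"])
    expect_error(estimateDispersion(m, groups = as.character(1:8)),
                 ">= 2 replicates")
})

test_that("trend shrinkage pulls outlying dispersions toward the consensus", {
    set.seed(33)
    n <- 200
    m <- matrix(rnbinom(n * 8, mu = 100, size = 10), nrow = n)
    raw <- estimateDispersion(m, groups = rep(c("A", "B"), each = 4),
                              shrink = 0)
    shr <- estimateDispersion(m, groups = rep(c("A", "B"), each = 4),
                              shrink = 0.5)
    ## shrinkage reduces spread around the common truth (alpha = 0.1)
    expect_lt(sd(shr), sd(raw))
})

test_that("BH adjustment follows the step-up rule and rejects bad input", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)           # single p unchanged
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    ## order-preserving with input indexing
    p <- c(0.04, 0.001, 0.9, 0.02)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    expect_error(bhAdjust(c(0.1, NaN)), "NA")
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("identical groups give log2FC exactly 0 and p = 1", {
    base <- matrix(rpois(20, 50), nrow = 5)
    cts <- cbind(base, base, base, base)  # every condition duplicates baseline
    cpe <- makeTinyExperiment(cts, nReps = 4)
    de <- testContrast(cpe, "NC", dispersions = rep(0.1, 5))
    expect_equal(de$log2FC, rep(0, 5))
    expect_equal(de$pvalue, rep(1, 5))
})

test_that("test is invariant to sample column order", {
    cpe <- simulateCounts(nGenes = 50, nReps = 3, seed = 8)
    cpe <- quantileNormalize(cpe)
    perm <- sample(ncol(cpe))
    de1 <- testContrast(cpe, "IV")
    de2 <- testContrast(cpe[, perm], "IV")
    expect_equal(de1, de2)
})

test_that("a missing condition is reported by name", {
    cts <- matrix(rpois(24, 20), nrow = 3,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
    cpe <- CoexPathExperiment(cts, rep(c("baseline", "injured_vehicle"),
                                       each = 4))
    expect_error(testContrast(cpe, "NC"), "noninjured_drug")
})

test_that("with zero dispersion and large counts the Wald test matches a Poisson GLM", {
    set.seed(41)
    n <- 100
    cts <- matrix(rpois(n * 8, 1000), nrow = n,
                  dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:8)))
    cpe <- makeTinyExperiment(cts, nReps = 2)
    de <- testContrast(cpe, "IV", dispersions = rep(0, n),
                       assayName = "counts")
    grp <- factor(rep(c("b", "c"), each = 2))
    pGlm <- vapply(seq_len(n), function(i) {
        y <- cts[i, c(1, 2, 5, 6)]
        summary(glm(y ~ grp, family = poisson))$coefficients[2, 4]
    }, numeric(1))
    expect_lt(max(abs(de$pvalue - pGlm)), 0.01)
})

test_that("null p-values are approximately uniform", {
    cpe <- simulateCounts(nGenes = 2000, nReps = 4, dispersion = 0.1,
                          seed = 19)
    cpe <- quantileNormalize(cpe)
    de <- testContrast(cpe, "IC")
    ks <- suppressWarnings(ks.test(de$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("planted effects are detected with high power", {
    ## log2FC = 2 at mu = 200, alpha = 0.1, 4 vs 4, 500 planted genes
    cpe <- simulateCounts(nGenes = 2000, nReps = 4,
                          meanRange = c(200, 200), dispersion = 0.1,
                          plantedPaths = data.frame(triple = "0+0",
                                                    nGenes = 500, lfc = 2),
                          seed = 23)
    de <- testContrast(cpe, "IV", assayName = "counts")
    planted <- truthTable(cpe)$state_IV == "+"
    power <- mean(de$padj[planted] <= 0.05)
    expect_gt(power, 0.9)
})

test_that("fold-change estimates agree with an independent NB fit (DESeq2)", {
    skip_if_not_installed("DESeq2")
    cpe <- simulateCounts(nGenes = 200, nReps = 4,
                          meanRange = c(50, 1000),
                          plantedPaths = anchorPlanting(nPerPath = 15),
                          seed = 13)
    de <- testContrast(quantileNormalize(cpe), "IV")
    suppressMessages({
        dds <- DESeq2::DESeqDataSetFromMatrix(
            assay(cpe, "counts"),
            S4Vectors::DataFrame(condition = sampleConditions(cpe)),
            ~condition)
        DESeq2::sizeFactors(dds) <- rep(1, ncol(dds))
        dds <- DESeq2::DESeq(dds, quiet = TRUE)
        ref <- DESeq2::results(dds, contrast = c("condition",
                                                 "injured_vehicle",
                                                 "baseline"))
    })
    expect_gt(cor(de$log2FC, ref$log2FoldChange, use = "complete.obs"),
              0.95)
    ## strong calls agree in direction
    sig <- which(de$padj <= 0.01)
    expect_true(all(sign(de$log2FC[sig]) ==
                    sign(ref$log2FoldChange[sig])))
})
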