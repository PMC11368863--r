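# coexPaths

Combinatorial co-expression **path** analysis for a four-condition bulk
RNA-seq design: a shared baseline (non-injured, vehicle-treated tissue)
plus three treated conditions — drug in non-injured tissue (NC), injury
with vehicle (IV), and injury with drug (IC). The motivating setting is
a regenerative drug tested on injured spinal cord, where the question
is not *whether* a gene responds but *how its responses combine across
conditions*: does the drug return an injury-induced gene to baseline,
induce it only in injured tissue, or act regardless of injury?

The package is for transcriptomics analysts who have a gene × sample
count matrix from such a design and want the per-gene classification,
plus methodologists who want a fully seeded synthetic benchmark for it.

## The method

Each treated condition is tested against the baseline with a
negative-binomial Wald test (Var = μ + αμ², method-of-moments
dispersion shrunk toward a mean–dispersion trend), after inter-sample
quantile normalization. Per contrast, a gene is called induced (`+`),
unchanged (`0`) or repressed (`-`) at q ≤ 0.05 and |log2FC| ≥ 1. The
ordered triple of calls (s_NC, s_IV, s_IC) is the gene's
*co-expression path*; the 3³ − 1 = 26 non-null triples form the
candidate catalog, and a configurable rule flags the 8
*ligand-informative* paths from which a drug effect in injured tissue
can be inferred — including the four anchor paths: return-to-basal up
(`0,+,0`), drug-specific induction (`0,0,+`), return-to-basal down
(`0,-,0`) and drug-specific repression (`0,0,-`). Each path's gene
list is then scored for gene-set over-representation with the
hypergeometric upper tail P(X ≥ k) against an expressed-gene universe,
reported as the enrichment confidence −10·log10(p).

A seeded NB count simulator plants genes into chosen paths at chosen
fold changes and emits a machine-readable truth table, so the entire
chain is testable without external data; `scoreRecovery()` turns a run
into per-path precision/recall and overall triple accuracy.

## Worked example

```r
library(coexPaths)

cpe <- simulateCounts(nGenes = 2000, nReps = 4, meanRange = c(100, 2000),
                      plantedPaths = data.frame(
                          triple = c("0+0", "00+", "0-0", "00-"),
                          nGenes = 50, lfc = 2),
                      seed = 1)
cpe     <- quantileNormalize(cpe)
de      <- deAnalysis(cpe)                 # NC, IV, IC vs baseline
states  <- callStates(de)
catalog <- selectLigandPaths(enumerateEvents())
catalog
#> PathCatalog: 26 co-expression events over alphabet {+,0,-}
#>   selected (ligand-informative): 8
#>   anchors: path4=path11(0+0) path2=path13(00+) path7=path14(00-) path5=path16(0-0)

asg  <- assignGenes(states, catalog)
summ <- pathSummary(asg, catalog)
summ[summ$n_genes > 0, ]
#>    path_id triple alias selected n_genes
#>     path10    0++          FALSE       2
#>     path11    0+0 path4     TRUE      51
#>     path13    00+ path2     TRUE      51
#>     path14    00- path7     TRUE      51
#>     path15    0-+           TRUE       1
#>     path16    0-0 path5     TRUE      48
#>  unchanged    000          FALSE    1796

scoreRecovery(asg, truthTable(cpe))$perPath
#>  path_id triple n_true n_pred tp precision recall        f1
#>   path11    0+0     50     51 49 0.9607843   0.98 0.9702970
#>   path13    00+     50     51 50 0.9803922   1.00 0.9900990
#>   path14    00-     50     51 50 0.9803922   1.00 0.9900990
#>   path16    0-0     50     48 47 0.9791667   0.94 0.9591837
```

Each planted anchor path is recovered nearly completely (recall
0.94–1.00 of the 50 planted genes; the handful of extra genes per path
are borderline null genes crossing the thresholds), and 99.45% of all
2000 genes get their exact state triple back. `runPipeline()` wraps the
same chain around TSV/CSV/GMT files and writes the normalized matrix,
three DE tables, per-gene path assignments, per-path summaries,
enrichment tables and a JSON manifest with input digests;
`inst/scripts/coexpaths-cli.R` exposes `simulate` / `run` / `score`
subcommands over it.

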