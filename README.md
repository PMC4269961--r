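# cytoPrior

Prioritization of candidate genes and copy number variations (CNVs)
from molecular cytogenetic data.

A chromosome imbalance found by array CGH may span dozens of genes, and
a patient's CNV list mixes pathogenic events with common polymorphisms.
cytoPrior is for the analyst who has to turn such segments into a short,
defensible candidate list using only locally available resources: a gene
annotation table, a gene × tissue expression matrix, a protein
interaction network, pathway gene sets, a benign-variant catalog and a
phenotype seed-gene list.

## The method

Genes inside an imbalance are **filtered** by tissue-specific
expression, then **ranked** by network and pathway evidence, and the
evidence is **fused**:

1. **Locus content.** `genesInInterval()` maps a segment (0-based,
   half-open coordinates) to its annotated genes.
2. **Expression filter.** On `y = log2(x + 1)` values, a locus gene is
   kept if its target-tissue expression exceeds the locus Tukey fence
   `Q3 + 1.5·IQR`, or if its cross-tissue robust z-score
   `z = (y_t − median(y)) / max(1.4826·MAD(y), 0.01)` is at least 2.
3. **Network evidence.** Seed proximity `|N(g) ∩ S| / √deg(g)`, pathway
   co-membership with seeds, and a simulated pathway perturbation:
   delete the gene from the interactome and measure
   `1 − L_after/L_before`, where `L` counts seeds held together in the
   seed-dominant connected component.
4. **Fusion.** Per-evidence competition ranks are combined by a
   weighted rank product `exp( Σ w_e·ln(rank_e/N) / Σ w_e )` (lower is
   better). The expression filter is a hard gate; by default the full
   pipeline also demands at least one positive network evidence
   (confirmation).
5. **CNV verdicts.** A CNV is *prioritized* when it contains ≥ 1
   prioritized gene and is not vetoed by a benign-catalog match
   (reciprocal overlap ≥ 0.5 at population frequency ≥ 0.01);
   *benign* on a match; *unranked* otherwise.
6. **Cohort summary.** Per-patient prioritized-CNV counts, their
   histogram, and the diagnostic yield (% of patients with ≥ 1
   prioritized CNV, rounded half-up to one decimal).

A synthetic-study generator (`simulateStudy()`) produces every input
format with planted ground truth — tissue-specific disease genes, a
wired disease module in a scale-free interactome, and a mixed
pathogenic/benign cohort — so the whole pipeline can be evaluated end
to end. See the vignette `vignettes/gene-cnv-prioritization.Rmd` for
the model, parameter rationale and limitations.

## Worked example

```r
library(cytoPrior)

study  <- simulateStudy(simulationConfig(seed = 42))
report <- runAll(study$annotation, study$expression, study$network,
                 study$pathways, study$seeds, tissues = "tissue01",
                 calls = study$calls, catalog = study$catalog,
                 roster = study$roster)

length(report$selectedGenes)
#> [1] 21
head(report$genes[report$genes$selected, c("gene", "fused")], 3)
#>     gene      fused
#> 1 G03008 0.01355403
#> 2 G04027 0.01355403
#> 3 G04004 0.01875583

evaluateRecovery(report$selectedGenes, study$planted,
                 report$cnv, study$truth)[c("genePrecision", "geneRecall",
                                            "cnvBalancedAccuracy")]
#> $genePrecision        [1] 0.952
#> $geneRecall           [1] 1
#> $cnvBalancedAccuracy  [1] 1

report$cohort$yieldPercent
#> [1] 85.9
head(report$cohort$histogram, 4)
#>   count nPatients
#> 1     0        29
#> 2     1        54
#> 3     2        53
#> 4     3        69
```

The study planted 20 disease genes (5 per chromosome, +3 log2 units in
the target tissue); the pipeline recovered all 20 plus one false
positive. Fused scores are rank-product ratios — `0.0136` means the
gene sat essentially at the top of every evidence stream. Of 205
simulated patients, 85.9% carried at least one prioritized CNV, with
the per-patient count concentrated between 1 and 3.

A command-line front end wraps the same functions
(`inst/cli/cytoprior.R`; subcommands `simulate`, `filter-expression`,
`rank-network`, `prioritize-genes`, `prioritize-cnvs`, `summarize`,
`evaluate`, `run-all`; exit codes 0/2/3 for success / validation error /
configuration error):

```sh
Rscript inst/cli/cytoprior.R simulate --seed 1 --out-dir fixtures/
Rscript inst/cli/cytoprior.R run-all \
  --annotation fixtures/annotation.bed --expression fixtures/expression.tsv \
  --network fixtures/network.tsv --genesets fixtures/pathways.gmt \
  --seeds fixtures/seeds.txt --cnv fixtures/cnv_calls.tsv \
  --catalog fixtures/variant_catalog.tsv --roster fixtures/roster.txt \
  --tissue tissue01 --out report.json
```

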