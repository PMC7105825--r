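# tetrasnp

SNP discovery, homoeolog filtering and graphical genotyping for
allotetraploid genomes, on simulated data with known ground truth.

## The problem

Allotetraploids such as cultivated peanut carry two subgenomes (A and B)
that are ~93% identical. Short reads from one subgenome cross-align to the
other, so fixed A-vs-B differences (*homoeologous* SNPs, present in every
individual) masquerade as polymorphisms between individuals (*allelic*
SNPs — the markers genetic mapping needs). The problem is most acute when
genotyping near-isogenic sister recombinant inbred lines (RILs), where true
polymorphisms are rare.

`tetrasnp` is a self-contained re-implementation of an analysis ecosystem
for this setting, aimed at method comparison and pipeline validation:

* **simcore** — a ground-truthed simulator: paired subgenomes at a
  configurable divergence (default 0.07, with a subgenome-specific window
  fraction), homozygous-divergent parents P1/P2, F6-derived sister RIL
  pairs with Poisson-crossover pedigrees, target-enrichment (TES, 100 bp
  PE), RNA-seq (150 bp PE) and GBS (ApeKI digest, 64 bp SE) read sets, and
  an SNP-array genotype table with homoeolog-confounded markers.
* **probekit** — 120 bp non-overlapping probe tiling over gene templates
  (class 1 genes with 2 kb/1 kb flanks, class 2/resistance CDS only),
  uniqueness scoring by *identity score* = alignment length × fractional
  identity (hit cutoff 96 ⇔ 80% of 120 bp), CD-HIT-style greedy
  deduplication, and three-stage panel selection including one probe per
  uncovered 44.3 kb genome fragment.
* **capmetrics** — identity-stratified target regions (hit ± 100 bp over
  the cutoff ladder 96…60) with on-target rate, covered-region and mean
  depth summaries.
* **subalign** — a deterministic exact-seed ungapped aligner supporting
  separate-subgenome ("overall" retention) and concatenated-reference
  ("unique" retention) strategies, plus per-sample pileups.
* **snpcall** — the five pipelines M1–M5 combining reference mode, read
  retention, the 4/2 depth rule, a homoeolog-anchor read-partition filter,
  and a read-haplotype filter that emits only homozygous inter-sample
  differences.
* **concord** — array validation: overlap, concordance, discordance
  classes, pair monomorphism and inter-pipeline sharing, with percentages
  recomputed from integer counts (half-up, two decimals).
* **graphmap** — multi-platform SNP merging, RIL-polymorphism filtering,
  polymorphic-region calling (gap- and phase-aware) and candidate-gene
  annotation; graphical-genotype matrices for plotting.
* **workflow** — `runAll()`: the whole cohort (P1, P2, E4–E7) end to end,
  with a reproducibility manifest (md5 of every output; fixed seed ⇒
  identical manifests).

## Worked example

```r
library(tetrasnp)
cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 150000L,
                 nGenesPerChromosome = 15L, seed = 1L)
truth <- simulateTetraploid(cfg)
truth
#> TetraploidTruth: 2 chromosomes ( 300000 bp )
#>   5301 homoeologous sites, 607 allelic sites, 30 gene models

probes <- deduplicateProbes(tileProbes(geneModels(truth), truthGenome(truth)))
hits   <- mapProbes(probes, truthGenome(truth))
reads  <- simulateReads(truth, c("P1", "P2"), "tes", cfg, depth = 30,
                        seed = 2L, targets = hits)

m2 <- runPipeline("M2", reads, truthGenome(truth))  # A+B, unique, depth rule
m4 <- runPipeline("M4", reads, truthGenome(truth))  # A/B, overall, haplotype
summarizeRecords(list(m2, m4))
#>   pipeline n_total n_heterozygous n_homozygous
#> 1       M2     382             49          333
#> 2       M4     291              0          291

arr <- simulateArray(truth, list(), nMarkers = 200L, errorRate = 0.01,
                     seed = 3L)
overlapAndScore(m4, arr)$report[, c("pipeline", "n_total", "n_overlapped",
                                    "n_concordant", "concordance_pct")]
#>   pipeline n_total n_overlapped n_concordant concordance_pct
#> 1       M4     291           87           86           98.85
```

Reading the output: the depth-rule pipeline (M2) reports both zygosity
classes, while the haplotype pipeline (M4) structurally emits homozygous
records only — a heterozygous or homoeolog-confounded sample never reaches
the required 90% within-partition majority. `concordance_pct` is the
fraction of array-overlapped loci whose unordered genotype pairs match the
sequencing calls for both samples (here one locus disagrees, caused by the
array's simulated 1% miscall rate).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main computation from scratch: it simulates the
six-line cohort on a desk-scale genome, designs and selects the probe
panel, emits TES/RNA-seq/GBS reads, runs all five pipelines, computes
capture metrics across the identity-cutoff ladder, validates against the
simulated array and builds the graphical maps, then writes the acceptance
JSON to `--out`.
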