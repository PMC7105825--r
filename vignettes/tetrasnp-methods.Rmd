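---
title: "SNP discovery in allotetraploids: models, filters and simulation design"
author: "tetrasnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP discovery in allotetraploids: models, filters and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cultivated allotetraploids such as peanut carry two ancestral subgenomes (A
and B) whose sequences are highly similar — around 93% identical overall.
Short reads from one subgenome readily align to the other, so a fixed
difference between the subgenomes (a *homoeologous* SNP, present in every
individual) masquerades as a polymorphism between individuals (an *allelic*
SNP, the marker type genetic mapping needs). The situation is hardest when
the lines to be distinguished are near-isogenic sister recombinant inbred
lines (RILs), where true polymorphisms are rare and false positives dominate
naive call sets.

`tetrasnp` re-implements, on fully synthetic data with known ground truth,
an analysis ecosystem for this problem: capture probe panel design,
identity-stratified capture metrics, two read-alignment strategies, five SNP
calling/filtering pipelines that separate allelic from homoeologous
variation, validation against array genotypes, and graphical genotyping of
the polymorphic regions between sister RILs.

# The simulated world

`simConfig()` fixes the stated world; `simulateTetraploid()` builds it.

**Subgenomes.** Chromosome set A is drawn uniformly at random; B is derived
from A. A small fraction of 5 kb windows (default 5%, capped at
`homoeologDivergence/1.5`) becomes *subgenome-specific*: the B copy is
resampled entirely, emulating presence/absence variation, and no homoeologous
sites are cataloged there (positions of unrelated sequence are not site-wise
comparable). All remaining ("alignable") positions are substituted
independently at a rate calibrated so the *emitted* A-vs-B mismatch fraction
equals `homoeologDivergence` (default 0.07, i.e. ~93% identity) in
expectation: with specific fraction $f$ and substitution rate $r$,
$0.75f + (1-f)r = d$, since unrelated sequence mismatches at 3/4 of
positions. Substituted alignable positions form the homoeologous-site truth
catalog. The specific windows are what gives the probe-design stage genuine
single-hit probes, as real genomes do.

A deliberate simplification: no indels or structural variants are simulated.
The pipelines under study are SNP-only, and the ungapped model keeps the
bespoke aligner exact and fully analyzable.

**Parental lines.** Allelic SNPs between the two parents are drawn per base
at `allelicSnpDensity` (default 0.002, roughly one difference per 500 bp —
a realistic figure for divergent breeding lines). Each site records exactly
two alleles; one random parent carries the alternate homozygously, and a
small fraction (`residualHetFraction`, default 0.02) leaves the carrier
parent heterozygous, as expected for advanced but not fully fixed lines. A
position may be both allelic and homoeologous; both labels are retained.

**RIL pairs.** `simulateRilPair()` models the pedigree behind near-isogenic
sister lines: F1 between the parents, `selfingGenerations - 1` rounds of
self-pollination with Poisson(`crossoversPerChromosome`) crossovers per
chromosome per meiosis (default 2), producing a shared founder plant; each
sister is one further independent selfing of that founder. The founder's
expected heterozygous genome fraction is $2^{-(g-1)}$ ($\approx 0.031$ for an
F6), and `residualHetFraction()` measures exactly that quantity on the
founder mosaic — the sisters themselves are one generation further fixed.
Sister differences can only arise inside founder-heterozygous intervals,
which is what makes the truth polymorphic blocks
(`truthPolymorphicBlocks()`) the reference for the graphical-map checks.
The crossover rate is not published for the real populations; the default is
nominal and configurable.

**Reads.** Three platforms are emulated. Target enrichment (TES, 100 bp
paired): fragments are drawn around probe target loci with capture
probability given by a two-parameter logistic on probe–target identity
(midpoint 0.62, steepness 40). The published account only states the
behaviour qualitatively — capture is efficient down to ~75% similarity — so
the curve is calibrated to give ≥90% of maximal capture at identity 0.75 and
a ≥10-fold drop by identity 0.5. A configurable fraction of fragments
(default 0.3) is drawn genome-wide, giving realistic on-target rates below 1.
RNA-seq (150 bp paired) draws fragments from expressed, single-exon gene
models only. GBS performs an in-silico ApeKI digest (recognition `GCWGC`,
cut after the first base), keeps fragments in a size window and reads the
first 64 bp from a random end. All platforms substitute uniform per-base
errors at `sequencingErrorRate` (default 0.001); quality strings are
uniform, since the error model is. With the error rate at zero every read is
an exact substring of its emitting haplotype and its truth tag relocates it
exactly — an invariant the tests assert.

**Array.** `simulateArray()` genotypes markers sampled from the truth
catalog, with a configurable miscall rate and a fraction of
homoeolog-confounded markers that score heterozygous in every sample —
mirroring the discordance classes real allotetraploid arrays exhibit.

# Alignment

`alignReads()` is a deterministic exact-seed (21-mer, stepped), ungapped
extension aligner. It supports the two reference strategies under
comparison: *separate* (align to A and B independently, keep the best
placement per subgenome — "overall" retention, where homoeologous reads
co-align) and *concatenated* (align to A+B jointly, keep only reads with a
strictly best single placement — "unique" retention, the ungapped analogue of
discarding MAPQ-0/multi-hit reads). Paired reads in concatenated mode must
both be unique, on one chromosome, within the insert window (100–600 bp).

The mismatch budget default is 12% of read length. A 6% budget would
make reads from the ~7% divergent sister subgenome almost never cross-align,
silently disabling the separate-reference pipelines whose entire premise is
that homoeologous reads co-align (the original study used a sensitive local
aligner for exactly this reason). At 12%, ~98% of cross-subgenome 100 bp
reads align, while uniqueness still removes reads from truly duplicated
sequence.

# The five pipelines

`pipelineConfig()` constructs exactly five combinations:

| id | reference | retention | filters |
|----|-----------|-----------|---------|
| M1 | A/B separate | overall | depth rule + homoeolog anchor (+ pass-through in place of the trained classifier) |
| M2 | A+B concatenated | unique | depth rule |
| M3 | A+B concatenated | unique | depth rule + anchor |
| M4 | A/B separate | overall | read-haplotype filter |
| M5 | A+B concatenated | unique | read-haplotype filter |

**Depth rule** (`callGenotypeDepth()`): heterozygous requires ≥2 reads of
each allele; homozygous requires ≥4 reads of the majority allele. The two
published clauses overlap (4 reference + 2 alternate reads satisfies both);
the package resolves the overlap explicitly: the heterozygous clause takes
precedence, and a homozygous call additionally requires the minor allele
below 2 reads. An exhaustive truth table over all counts ≤12 is frozen in
the tests.

**Diagnostic (anchor) sites** (`findDiagnosticSites()`): positions where
every sample shows the same two alleles, each at 20–80% of their combined
depth (≥4 reads) — the invariant balanced signature of co-aligned
homoeologous reads. The 0.2–0.8 band tolerates 30× sampling noise.

**Anchor filter** (`anchorFilter()`): reads covering both a candidate and a
nearby diagnostic site are partitioned by their diagnostic allele — their
subgenome of origin. A candidate is allelic iff its alternate allele is
confined to one partition *and* that partition also carries the reference
allele; a candidate whose two alleles coincide with the two partitions is
homoeologous and removed. Two operationalization details the source text
leaves open, decided here: (1) allele "presence" in a partition requires
max(1, 10% of the partition) reads, for robustness to stray errors; (2) the
informative partition must be the one whose anchor allele equals the
reference base at the anchor — variation living in the *other* partition is
the homoeologous copy's polymorphism and is reported at its own coordinate
on the other subgenome, not duplicated here. Candidates with no anchor
within one read length pass unfiltered, flagged `anchored = FALSE`.

**Haplotype filter** (`haplotypeFilter()`): the re-implementation of
haplotype-based genotyping. Units are read pairs for paired platforms
("long-range": the window is the fragment span, 600 bp) and single reads
otherwise. Units covering the candidate are partitioned by the nearest
diagnostic site as above; within the informative (reference-subgenome)
partition, a sample receives a haplotype genotype only when one allele holds
≥4 of its units and ≥90% of them. Only homozygous inter-sample differences
can be emitted: a heterozygous or homoeolog-confounded sample never reaches
the 90% majority — this is why the haplotype pipelines structurally report
no heterozygous class. Note that although the pipeline table lists the
anchor tool as "No" for M4/M5, the haplotype method must be subgenome-aware
to work on overall-retention alignments; the original haplotype tool carries
that machinery internally, and this package reuses its diagnostic-site
detector for the purpose.

The trained machine-learning post-classifier of the original tool chain is
out of desk scale (no published mechanism) and is a documented no-op
pass-through in M1/M3.

# Probe panel design

`tileProbes()` tiles 120 bp non-overlapping probes over gene templates:
class 1 genes (nodulation-related orthologs and differentially expressed
genes) with 2 kb upstream and 1 kb downstream flanks, class 2 and resistance
genes over the coding sequence only; at most the top four genes per class 1
orthogroup (by supplied similarity rank) contribute. `mapProbes()` scores
every ungapped placement by *identity score* = alignment length × fractional
identity (i.e. matching bases; 96 of 120 ⇔ 80%), the binding criterion the
published design quantifies — the original tool's e-value cutoff adds only a
composition correction and is deliberately not reproduced.
`deduplicateProbes()` performs greedy CD-HIT-EST-style clustering (≥80%
identity over ≥80% mutual coverage, both strands). `selectPanel()` selects
(1) all single-hit class 1/resistance probes, (2) 2–4-hit probes rescuing
genes with no single-hit probe, then (3) one single-hit class 2 probe per
uncovered 44.3 kb genome fragment. Two under-specified choices are made
deterministic: the per-fragment tie-break is the lowest hit coordinate, and
exact panel-size trimming (the published design randomly excluded three
fragments) drops spacing probes from the highest coordinates down, for
reproducibility.

# Capture metrics

`buildTargetRegions()` extends each hit at or above an identity-score cutoff
by 100 bp on both sides, clipped at chromosome ends; the ladder
96, 90, 84, 78, 72, 66, 60 corresponds to 80%→50% probe matches. Overlapping
regions are *not* merged by default, keeping counts interpretable per hit
(merged mode is a flag). `coverageSummary()` defines on-target as ≥1 bp
overlap (the source does not state a fraction), a covered region as ≥1
overlapping read, and mean depth as the mean over regions of within-region
per-base depth. Region sets are nested across the ladder, so covered-region
counts and on-target rates are monotone as the cutoff drops — both are
asserted as invariants.

# Concordance and graphical maps

`overlapAndScore()` validates pipeline SNPs against the array: a locus is
overlapped when chromosome and position match, concordant when the array is
also polymorphic between the compared samples and both unordered genotype
pairs agree. Non-concordant overlapped loci are partitioned into the four
discordance classes observed on real data. Percentages are recomputed from
integer counts and rounded half-up to two decimals, matching report
conventions; an empty overlap yields an explicitly flagged undefined rate.

`mergePlatforms()` unions homozygous parental-polymorphic loci across
platforms (majority vote per sample; ties and allele conflicts drop the
locus with a log message). `filterRilPolymorphic()` keeps loci where both
sisters are homozygous and differ. `callRegions()` merges consecutive
qualifying SNPs within `mergeDistance` into regions, additionally splitting
when the sister phase flips so one region represents one origin contrast.
The merge distance that produced the published region counts is not stated;
it is therefore a required, logged parameter (default 1 Mb) and the region
counts themselves are not asserted anywhere. `annotateRegions()` attaches
overlapping genes labeled DEG, nodulation-ortholog, or both.

# What a green test establishes — and what it does not

The simulation reproduces the *mechanisms* that make allotetraploid SNP
calling hard: co-aligning homoeologous reads, balanced invariant
pseudo-heterozygosity, near-isogenic sisters, capture decay with identity,
homoeolog-confounded array markers. It does not reproduce: indels and
structural variation, splicing (genes are single-exon), base-quality
structure, PCR duplicates, repeat families beyond the two subgenomes, or the
real genome's length and composition. Acceptance-style checks therefore
validate rule arithmetic exactly (worked examples, depth-rule truth table),
and validate detection performance only against this generator's truth at
desk scale (hundreds of kb, 30×, error 0.001 — the stated rates with the
genome length scaled down to fit a single CPU). Detection recall is measured
over sites sequenced at ≥8 reads in every sample: a capture assay cannot
detect variation at loci it does not cover, and the off-target fringe is
sparsely covered by construction.

# Numerical and degenerate-input choices

* Coordinates are 1-based closed throughout (`GRanges`/`IRanges`
  convention); BED export shifts starts by one, VCF is 1-based as required.
* Zero divergence forces the subgenome-specific fraction to zero: identical
  subgenomes, empty homoeolog catalog.
* Empty digests, genomes without expressed genes, and empty alignment sets
  produce valid empty objects with warnings, never errors; an empty overlap
  yields `NA` rates with a flag.
* All randomness flows from a single integer seed; derived stage seeds stay
  below $2^{31}$. Fixed seed ⇒ byte-identical FASTA/FASTQ/TSV/VCF outputs
  and identical run manifests (md5 over every written file).
* Alignment ties are broken by (chromosome, start, strand); ties in best
  score make a read non-unique under unique retention.

# Known limitations

The bespoke aligner's seed-and-extend search can miss placements whose every
seed overlaps a mismatch (relevant only above ~15% divergence); the
haplotype and anchor filters assess candidates against the *nearest*
diagnostic site rather than a full local haplotype graph; RIL pairs share a
single F1 gamete pair per pedigree, so parental residual heterozygosity
segregates only between, not within, pairs. None of these affect the
package's contracts, but they bound how far the simulation should be pushed.
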