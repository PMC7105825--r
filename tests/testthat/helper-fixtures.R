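# Shared fixtures, built once per test session and cached. The "small world"
# is the package's stated simulation world (divergence 0.07, 30x depth,
# error 0.001, depth rules 4/2) scaled down in genome length to keep the
# suite fast; rates, depths and thresholds are unchanged.
.fixtures <- new.env(parent = emptyenv())

smallWorld <- function() {
  if (!is.null(.fixtures$world)) return(.fixtures$world)
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 200000L,
                   nGenesPerChromosome = 20L, seed = 42L)
  truth <- simulateTetraploid(cfg)
  pairs <- list(simulateRilPair(truth, cfg, c("E4", "E5"), seed = 43L),
                simulateRilPair(truth, cfg, c("E6", "E7"), seed = 44L))
  probes <- deduplicateProbes(tileProbes(geneModels(truth), truthGenome(truth)))
  hits <- mapProbes(probes, truthGenome(truth))
  samples <- c("P1", "P2", "E4", "E5", "E6", "E7")
  reads <- simulateReads(truth, samples, "tes", cfg, depth = 30, seed = 7L,
                         pairs = pairs, targets = hits)
  alnSep <- alignReads(reads, truthGenome(truth), mode = "separate")
  alnCat <- alignReads(reads, truthGenome(truth), mode = "concatenated")
  pileSep <- pileupCounts(alnSep, truthGenome(truth))
  pileCat <- pileupCounts(alnCat, truthGenome(truth))
  diagSep <- findDiagnosticSites(pileSep)
  recs <- list(
    M2 = runPipeline("M2", reads, truthGenome(truth), alignments = alnCat),
    M4 = runPipeline("M4", reads, truthGenome(truth), alignments = alnSep),
    M5 = runPipeline("M5", reads, truthGenome(truth), alignments = alnCat))
  .fixtures$world <- list(cfg = cfg, truth = truth, pairs = pairs,
                          probes = probes, hits = hits, reads = reads,
                          alnSep = alnSep, alnCat = alnCat,
                          pileSep = pileSep, pileCat = pileCat,
                          diagSep = diagSep, recs = recs)
  .fixtures$world
}

# two identical tiny end-to-end runs, for determinism and smoke assertions
workflowRuns <- function() {
  if (!is.null(.fixtures$runs)) return(.fixtures$runs)
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 120000L,
                   nGenesPerChromosome = 12L, seed = 11L)
  d1 <- file.path(tempdir(), "tetrasnp_runA")
  d2 <- file.path(tempdir(), "tetrasnp_runB")
  m1 <- suppressMessages(runAll(cfg, d1, platforms = "tes", depth = 15,
                                nMarkers = 200L))
  m2 <- suppressMessages(runAll(cfg, d2, platforms = "tes", depth = 15,
                                nMarkers = 200L))
  .fixtures$runs <- list(cfg = cfg, dir1 = d1, dir2 = d2, m1 = m1, m2 = m2)
  .fixtures$runs
}

# coordinates of every truth homoeologous site on both subgenome references
homoeologKeys <- function(truth) {
  hs <- homoeologSites(truth)
  c(paste(hs$chromA, hs$pos), paste(hs$chromB, hs$pos))
}

# the depth rule restated independently from the published text: a het call
# needs >= 2 reads of each allele (and takes precedence); a hom call needs
# >= 4 reads of the majority allele with the minor allele below 2
depthRuleOracle <- function(refN, altN) {
  if (refN >= 2 && altN >= 2) return("het")
  if (refN >= 4 && altN < 2) return("hom_ref")
  if (altN >= 4 && refN < 2) return("hom_alt")
  "missing"
}

# random DNA string helper for constructed fixtures
rndSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

# a minimal ReadSet-shaped DataFrame for hand-built reads
readFrame <- function(id, sample, seq, chrom = "A01", start = 1L,
                      strand = "+", mate = 0L, pairId = id, hap = 1L) {
  S4Vectors::DataFrame(id = id, sample = sample, seq = seq, mate = mate,
                       pairId = pairId, truthChrom = chrom,
                       truthStart = as.integer(start), truthStrand = strand,
                       hap = hap)
}
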