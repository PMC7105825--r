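test_that("depth rule instantiates the published calls", {
  expect_identical(callGenotypeDepth(5L, 0L), "hom_ref")
  expect_identical(callGenotypeDepth(0L, 4L), "hom_alt")
  expect_identical(callGenotypeDepth(2L, 2L), "het")
  expect_identical(callGenotypeDepth(3L, 1L), "missing")
  expect_identical(callGenotypeDepth(4L, 2L), "het")  # het precedence
  expect_error(callGenotypeDepth(-1L, 2L), "non-negative")
})

test_that("diagnostic sites require balance in every sample", {
  # hand-built pileup: site 100 is a homoeolog signature (balanced A/G in
  # all samples), site 200 is a clean allelic difference
  mk <- function(sample, pos, A, G) data.table::data.table(
    sample = sample, chrom = "A01", pos = pos, ref = "A",
    A = A, C = 0L, G = G, T = 0L, depth = A + G)
  pile <- data.table::rbindlist(list(
    mk("P1", 100L, 14L, 16L), mk("P2", 100L, 15L, 15L),
    mk("P1", 200L, 30L, 0L), mk("P2", 200L, 0L, 28L)))
  d <- findDiagnosticSites(pile)
  expect_identical(d$pos, 100L)
  expect_setequal(c(d$alleleMajor, d$alleleMinor), c("A", "G"))
  # imbalance in one sample disqualifies the site
  pile2 <- data.table::rbindlist(list(
    mk("P1", 100L, 28L, 2L), mk("P2", 100L, 15L, 15L)))
  expect_identical(nrow(findDiagnosticSites(pile2)), 0L)
})

test_that("candidate sites need a non-reference allele in some sample", {
  mk <- function(sample, pos, A, G) data.table::data.table(
    sample = sample, chrom = "A01", pos = pos, ref = "A",
    A = A, C = 0L, G = G, T = 0L, depth = A + G)
  pile <- data.table::rbindlist(list(
    mk("P1", 100L, 10L, 0L), mk("P2", 100L, 9L, 1L),   # below hetMin
    mk("P1", 200L, 10L, 0L), mk("P2", 200L, 1L, 9L)))  # real candidate
  cand <- candidateSites(pile)
  expect_identical(unique(cand$pos), 200L)
  expect_identical(unique(cand$alt), "G")
})

test_that("inter-sample records exist only where compared samples differ", {
  cand <- data.table::data.table(
    chrom = "A01", pos = c(1L, 1L, 2L, 2L, 3L, 3L), ref = "A", alt = "G",
    sample = rep(c("P1", "P2"), 3L),
    refCount = c(10L, 0L, 10L, 10L, 10L, 5L),
    altCount = c(0L, 10L, 0L, 0L, 0L, 5L))
  rec <- depthSnpRecords(cand)
  expect_identical(rec$pos, c(1L, 3L))
  expect_identical(rec$zygosity, c("homozygous", "heterozygous"))
})

test_that("anchor filter separates allelic from homoeologous candidates", {
  set.seed(14)
  # reference chromosome; reads carry a diagnostic site at 150 (ref C /
  # cross-subgenome T) and a candidate at 180
  refSeq <- rndSeq(400)
  substr(refSeq, 150, 150) <- "C"
  genome <- Biostrings::DNAStringSet(c(A01 = refSeq))
  mkRead <- function(base150, base180) {
    s <- substring(refSeq, 101, 220)
    substr(s, 50, 50) <- base150
    substr(s, 80, 80) <- base180
    s
  }
  ref180 <- substring(refSeq, 180, 180)
  altB <- setdiff(c("A", "C", "G", "T"), ref180)[1]
  diag <- data.table::data.table(chrom = "A01", pos = 150L,
                                 alleleMajor = "C", alleleMinor = "T")
  # allelic case: variation within the C (own-subgenome) partition
  reads <- c(replicate(6, mkRead("C", altB)), replicate(6, mkRead("C", ref180)),
             replicate(10, mkRead("T", ref180)))
  rd <- readFrame(sprintf("r%02d", seq_along(reads)),
                  rep(c("P1", "P2", "P2"), c(6, 6, 10)), reads, start = 101L)
  aln <- alignReads(rd, genome, mode = "concatenated",
                    maxMismatchRate = 0.12)
  recAllelic <- data.table::data.table(chrom = "A01", pos = 180L,
                                       ref = ref180, alt = altB)
  kept <- anchorFilter(recAllelic, diag, aln, genome, window = 100L)
  expect_identical(nrow(kept), 1L)
  expect_true(kept$anchored)
  # homoeologous case: the candidate's two "alleles" are the partitions
  # themselves (every sample shows ref with C and alt with T)
  reads2 <- c(replicate(4, mkRead("C", ref180)), replicate(4, mkRead("T", altB)),
              replicate(4, mkRead("C", ref180)), replicate(4, mkRead("T", altB)))
  rd2 <- readFrame(sprintf("s%02d", seq_along(reads2)),
                   rep(c("P1", "P2"), each = 8L), reads2, start = 101L)
  aln2 <- alignReads(rd2, genome, mode = "concatenated",
                     maxMismatchRate = 0.12)
  recHomo <- data.table::data.table(chrom = "A01", pos = 180L,
                                    ref = ref180, alt = altB)
  expect_identical(nrow(anchorFilter(recHomo, diag, aln2, genome,
                                     window = 100L)), 0L)
  # no nearby anchor: passes unfiltered with the flag down
  far <- data.table::data.table(chrom = "A01", pos = 180L,
                                ref = ref180, alt = "G")
  keptFar <- anchorFilter(far, diag[0L], aln, genome, window = 100L)
  expect_identical(nrow(keptFar), 1L)
  expect_false(keptFar$anchored)
})

test_that("haplotype filter emits homozygous differences only", {
  set.seed(15)
  refSeq <- rndSeq(400)
  genome <- Biostrings::DNAStringSet(c(A01 = refSeq))
  ref180 <- substring(refSeq, 180, 180)
  alt <- setdiff(c("A", "C", "G", "T"), ref180)[1]
  mkRead <- function(base180) {
    s <- substring(refSeq, 101, 220)
    substr(s, 80, 80) <- base180
    s
  }
  # P1 all alt, P2 all ref, >= 4 reads each -> homozygous record
  reads <- c(replicate(6, mkRead(alt)), replicate(6, mkRead(ref180)))
  rd <- readFrame(sprintf("r%02d", 1:12), rep(c("P1", "P2"), each = 6L),
                  reads, start = 101L)
  aln <- alignReads(rd, genome, mode = "concatenated")
  pile <- pileupCounts(aln, genome)
  cand <- candidateSites(pile)
  rec <- haplotypeFilter(cand, data.table::data.table(
    chrom = character(), pos = integer(), alleleMajor = character(),
    alleleMinor = character()), aln, genome, paired = FALSE)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$zygosity, "homozygous")
  expect_identical(rec$gt_P1, "hom_alt")
  expect_identical(rec$gt_P2, "hom_ref")
  # a 50/50 sample gets no call, so no record
  reads2 <- c(replicate(5, mkRead(alt)), replicate(5, mkRead(ref180)),
              replicate(8, mkRead(ref180)))
  rd2 <- readFrame(sprintf("s%02d", 1:18),
                   rep(c("P1", "P1", "P2"), c(5, 5, 8)), reads2, start = 101L)
  aln2 <- alignReads(rd2, genome, mode = "concatenated")
  rec2 <- haplotypeFilter(candidateSites(pileupCounts(aln2, genome)),
                          data.table::data.table(
                            chrom = character(), pos = integer(),
                            alleleMajor = character(),
                            alleleMinor = character()),
                          aln2, genome, paired = FALSE)
  expect_identical(nrow(rec2), 0L)
})

test_that("only the five published pipeline configurations exist", {
  for (id in c("M1", "M2", "M3", "M4", "M5")) {
    cfg <- pipelineConfig(id)
    expect_identical(cfg$id, id)
  }
  expect_identical(pipelineConfig("M1")$mode, "separate")
  expect_identical(pipelineConfig("M1")$retention, "overall")
  expect_identical(pipelineConfig("M2")$mode, "concatenated")
  expect_true(pipelineConfig("M3")$anchor)
  expect_true(pipelineConfig("M4")$haplotype)
  expect_error(pipelineConfig("M6"), "unknown pipeline")
})

test_that("pipelines are deterministic", {
  w <- smallWorld()
  r1 <- runPipeline("M2", w$reads, truthGenome(w$truth),
                    alignments = w$alnCat)
  expect_identical(r1, w$recs$M2)
})

test_that("anchor removal is specific for homoeologous candidates", {
  w <- smallWorld()
  cand <- candidateSites(w$pileSep)
  loci <- unique(cand[, list(chrom, pos, ref, alt)])
  kept <- anchorFilter(loci, w$diagSep, w$alnSep, truthGenome(w$truth),
                       window = 100L)
  homoKeys <- homoeologKeys(w$truth)
  homoCand <- loci[paste(chrom, pos) %in% homoKeys]
  expect_gt(nrow(homoCand), 100L)
  removed <- !(paste(homoCand$chrom, homoCand$pos) %in%
                 paste(kept$chrom, kept$pos))
  expect_gte(mean(removed), 0.9)
})

test_that("per-pipeline summaries count zygosity classes", {
  w <- smallWorld()
  s <- summarizeRecords(w$recs)
  expect_identical(s$pipeline, c("M2", "M4", "M5"))
  expect_identical(s$n_total, s$n_heterozygous + s$n_homozygous)
})
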