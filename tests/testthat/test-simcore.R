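test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(homoeologDivergence = 1.2), "rates")
  expect_error(simConfig(sequencingErrorRate = -0.1), "rates")
  expect_error(simConfig(insertMin = 700L, insertMax = 600L), "insertMax")
  expect_s4_class(simConfig(seed = 3L), "SimConfig")
})

test_that("zero divergence gives identical subgenomes and no homoeologous sites", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 30000L,
                   homoeologDivergence = 0, nGenesPerChromosome = 5L,
                   seed = 1L)
  tr <- simulateTetraploid(cfg)
  expect_identical(as.character(genomeA(tr)[[1]]),
                   as.character(genomeB(tr)[[1]]))
  expect_identical(nrow(homoeologSites(tr)), 0L)
})

test_that("emitted A-vs-B identity matches configured divergence at 1 Mb", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 1000000L,
                   nGenesPerChromosome = 50L, seed = 8L)
  tr <- simulateTetraploid(cfg)
  a <- strsplit(as.character(genomeA(tr)[[1]]), "", fixed = TRUE)[[1]]
  b <- strsplit(as.character(genomeB(tr)[[1]]), "", fixed = TRUE)[[1]]
  identity <- mean(a == b)
  # observed identity within +-0.5% of 93%
  expect_gt(identity, 0.925)
  expect_lt(identity, 0.935)
})

test_that("a fixed seed reproduces the truth byte-identically", {
  cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 20000L,
                   nGenesPerChromosome = 3L, seed = 99L)
  t1 <- simulateTetraploid(cfg)
  t2 <- simulateTetraploid(cfg)
  expect_identical(as.character(truthGenome(t1)), as.character(truthGenome(t2)))
  expect_identical(allelicSites(t1), allelicSites(t2))
  expect_identical(homoeologSites(t1), homoeologSites(t2))
})

test_that("undersized chromosomes refuse the requested gene models", {
  expect_error(simulateTetraploid(
    simConfig(nChromosomes = 1L, chromosomeLength = 5000L,
              nGenesPerChromosome = 10L, geneLength = 1200L, seed = 1L)),
    "too small")
})

test_that("allelic sites record exactly two alleles and parental genotypes", {
  tr <- smallWorld()$truth
  s <- allelicSites(tr)
  expect_true(all(s$ref != s$alt))
  expect_true(all(s$P1_1 %in% c(s$ref, s$alt)))
  # every site is polymorphic between the parents at the genotype level
  gt1 <- paste(pmin(s$P1_1, s$P1_2), pmax(s$P1_1, s$P1_2))
  gt2 <- paste(pmin(s$P2_1, s$P2_2), pmax(s$P2_1, s$P2_2))
  expect_true(all(gt1 != gt2))
})

test_that("without recombination each chromosome is entirely one parent", {
  cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 50000L,
                   nGenesPerChromosome = 5L, crossoversPerChromosome = 0,
                   selfingGenerations = 12L, seed = 21L)
  tr <- simulateTetraploid(cfg)
  pr <- simulateRilPair(tr, cfg, seed = 22L)
  for (ln in pr@lines) {
    gr <- lineBlocks(pr, ln)
    perChrom <- split(gr$origin, as.character(GenomicRanges::seqnames(gr)))
    for (o in perChrom) expect_length(unique(o), 1L)
  }
})

test_that("origin blocks tile chromosomes and sisters share the founder", {
  w <- smallWorld()
  pr <- w$pairs[[1]]
  expect_true(validObject(pr))
  tb <- truthPolymorphicBlocks(pr, homOnly = FALSE)
  # sister differences can only arise inside founder-heterozygous intervals
  if (length(tb)) {
    founderHet <- pr@founderBlocks[pr@founderBlocks$origin == "HET"]
    ov <- GenomicRanges::findOverlaps(tb, founderHet, type = "within")
    expect_identical(length(unique(S4Vectors::queryHits(ov))), length(tb))
  }
})

test_that("GBS digest with no recognition motifs yields an empty read set", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 3000L,
                   homoeologDivergence = 0, allelicSnpDensity = 0,
                   nGenesPerChromosome = 1L, geneLength = 500L, seed = 1L)
  tr <- simulateTetraploid(cfg)
  # a genome without G eliminates every GCWGC site
  noG <- Biostrings::DNAStringSet(gsub("G", "A",
                                       as.character(truthGenome(tr))))
  names(noG) <- names(truthGenome(tr))
  tr@genome <- noG
  tr@allelicSites <- tr@allelicSites[0, ]
  expect_warning(rs <- simulateReads(tr, "P1", "gbs", cfg, depth = 5,
                                     seed = 2L),
                 "no reads")
  expect_identical(nrow(rs@reads), 0L)
})

test_that("capture curve is calibrated: >=75% identity captures efficiently", {
  cfg <- simConfig(seed = 1L)
  pMax <- captureProbability(1.0, cfg)
  expect_gte(captureProbability(0.75, cfg) / pMax, 0.9)
  expect_gte(captureProbability(1.0, cfg) / captureProbability(0.5, cfg), 10)
})

test_that("error-free reads are exact substrings of their emitting haplotype", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 40000L,
                   nGenesPerChromosome = 5L, sequencingErrorRate = 0,
                   seed = 31L)
  tr <- simulateTetraploid(cfg)
  rs <- simulateReads(tr, "P2", "gbs", cfg, depth = 2, seed = 32L)
  r <- rs@reads
  haps <- tetrasnp:::haplotypeSequences(tr, "P2")
  ok <- vapply(seq_len(nrow(r)), function(i) {
    s <- as.character(haps[[r$hap[i]]][[r$truthChrom[i]]])
    frag <- substring(s, r$truthStart[i],
                      r$truthStart[i] + nchar(r$seq[i]) - 1L)
    if (r$truthStrand[i] == "+") frag == r$seq[i]
    else tetrasnp:::revCompChar(frag) == r$seq[i]
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(nchar(r$seq) == 64L))
})

test_that("GBS reads start at ApeKI cut sites", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 40000L,
                   nGenesPerChromosome = 5L, sequencingErrorRate = 0,
                   homoeologDivergence = 0, allelicSnpDensity = 0, seed = 33L)
  tr <- simulateTetraploid(cfg)
  rs <- simulateReads(tr, "P1", "gbs", cfg, depth = 2, seed = 34L)
  r <- rs@reads
  chromSeq <- as.character(truthGenome(tr)[[r$truthChrom[1]]])
  # a forward read begins right after the G of a GCWGC motif
  fwd <- r[r$truthStrand == "+", ]
  ctx <- substring(chromSeq, fwd$truthStart - 1L, fwd$truthStart + 3L)
  expect_true(all(ctx %in% c("GCAGC", "GCTGC")))
})

test_that("array simulation honors error rate zero and marker bounds", {
  w <- smallWorld()
  tab0 <- simulateArray(w$truth, w$pairs, nMarkers = 300L, errorRate = 0,
                        seed = 5L, confoundedFraction = 0)
  s <- allelicSites(w$truth)
  keys <- paste(s$chrom, s$pos)
  idx <- match(paste(tab0$chrom, tab0$pos), keys)
  expect_false(anyNA(idx))
  for (smp in c("P1", "P2", "E4", "E5", "E6", "E7")) {
    truthGt <- lineGenotypes(w$truth, smp, w$pairs)[idx]
    expect_identical(tab0[[smp]], truthGt)
  }
  expect_identical(nrow(simulateArray(w$truth, w$pairs, nMarkers = 0L,
                                      seed = 5L)), 0L)
  expect_error(simulateArray(w$truth, w$pairs, nMarkers = 10000000L,
                             seed = 5L), "exceeds")
})

test_that("array miscalls fall within the binomial 99% interval", {
  cfg <- simConfig(nChromosomes = 1L, chromosomeLength = 500000L,
                   allelicSnpDensity = 0.012, nGenesPerChromosome = 10L,
                   seed = 55L)
  tr <- simulateTetraploid(cfg)
  n <- 10000L
  err <- 0.01
  tab <- simulateArray(tr, list(), nMarkers = n, errorRate = err, seed = 56L,
                       confoundedFraction = 0)
  s <- allelicSites(tr)
  idx <- match(paste(tab$chrom, tab$pos), paste(s$chrom, s$pos))
  miscalls <- sum(tab$P1 != lineGenotypes(tr, "P1")[idx]) +
    sum(tab$P2 != lineGenotypes(tr, "P2")[idx])
  entries <- 2L * n
  expect_gte(miscalls, qbinom(0.005, entries, err))
  expect_lte(miscalls, qbinom(0.995, entries, err))
})

test_that("homoeolog-confounded array markers are heterozygous in all samples", {
  w <- smallWorld()
  tab <- simulateArray(w$truth, w$pairs, nMarkers = 200L, errorRate = 0,
                       seed = 6L, confoundedFraction = 0.2)
  conf <- tab[tab$confounded, ]
  expect_gt(nrow(conf), 0L)
  for (smp in c("P1", "P2", "E4", "E5", "E6", "E7")) {
    parts <- strsplit(conf[[smp]], "/", fixed = TRUE)
    expect_true(all(vapply(parts, function(x) x[1] != x[2], logical(1))))
  }
})
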