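mkRecords <- function(pos, gtE4 = "hom_ref", gtE5 = "hom_alt",
                      gtP1 = "hom_ref", gtP2 = "hom_alt", chrom = "A01") {
  data.table::data.table(chrom = chrom, pos = pos, ref = "A", alt = "G",
                         zygosity = "homozygous", gt_P1 = gtP1, gt_P2 = gtP2,
                         gt_E4 = gtE4, gt_E5 = gtE5)
}

test_that("platform merging keeps provenance and resolves conflicts", {
  a <- mkRecords(c(10L, 20L))
  b <- mkRecords(c(10L, 30L))
  d <- mkRecords(10L)
  m <- mergePlatforms(list(tes = a, rnaseq = b, array = d))
  expect_identical(nrow(m), 3L)
  expect_identical(m$platforms[m$pos == 10L], "array,rnaseq,tes")
  # disjoint sets union
  m2 <- mergePlatforms(list(x = mkRecords(1:3 * 10L),
                            y = mkRecords(4:8 * 10L)))
  expect_identical(nrow(m2), 8L)
  # majority resolution and tie dropping
  conflA <- mkRecords(50L, gtE4 = "hom_ref")
  conflB <- mkRecords(50L, gtE4 = "hom_alt")
  conflC <- mkRecords(50L, gtE4 = "hom_ref")
  m3 <- suppressMessages(mergePlatforms(list(a = conflA, b = conflB,
                                             c = conflC)))
  expect_identical(m3$gt_E4, "hom_ref")
  expect_message(m4 <- mergePlatforms(list(a = conflA, b = conflB)), "tied")
  expect_identical(nrow(m4), 0L)
  # allele-incompatible duplicates dropped
  other <- data.table::copy(conflA)[, alt := "T"]
  expect_message(m5 <- mergePlatforms(list(a = conflA, b = other)),
                 "incompatible alleles")
  expect_identical(nrow(m5), 0L)
})

test_that("merged row count equals the brute-force distinct-locus union", {
  set.seed(16)
  sets <- lapply(1:4, function(i)
    mkRecords(sort(sample.int(200L, 60L)) * 5L))
  names(sets) <- paste0("pf", 1:4)
  m <- mergePlatforms(sets)
  allLoci <- unique(unlist(lapply(sets, function(s) s$pos)))
  expect_identical(nrow(m), length(allLoci))
})

test_that("RIL-polymorphic filtering needs homozygous differing sisters", {
  tab <- mergePlatforms(list(x = data.table::rbindlist(list(
    mkRecords(10L),                                    # qualifies
    mkRecords(20L, gtE4 = "hom_alt", gtE5 = "hom_alt"),# sisters identical
    mkRecords(30L, gtE4 = "het"),                      # het sister
    mkRecords(40L, gtE4 = "missing")))))               # missing call
  q <- filterRilPolymorphic(tab, c("E4", "E5"))
  expect_identical(q$pos, 10L)
})

test_that("regions merge by gap and split on phase flips", {
  snps <- mkRecords(c(1000L, 2000L, 3000L))
  r1 <- suppressMessages(callRegions(snps, c("E4", "E5"),
                                     mergeDistance = 10000))
  expect_length(r1, 1L)
  expect_identical(S4Vectors::mcols(r1)$n_snps, 3L)
  expect_identical(GenomicRanges::start(r1), 1000L)
  expect_identical(GenomicRanges::end(r1), 3000L)
  far <- mkRecords(c(1000L, 1001000L))
  expect_length(suppressMessages(callRegions(far, c("E4", "E5"),
                                             mergeDistance = 10000)), 2L)
  # a phase flip starts a new region even within the merge distance
  flip <- data.table::rbindlist(list(
    mkRecords(c(1000L, 2000L)),
    mkRecords(3000L, gtE4 = "hom_alt", gtE5 = "hom_ref")))
  r3 <- suppressMessages(callRegions(flip, c("E4", "E5"),
                                     mergeDistance = 10000))
  expect_length(r3, 2L)
  # region count is monotone non-increasing in merge distance
  set.seed(17)
  rnd <- mkRecords(sort(sample.int(2000000L, 60L)))
  nReg <- vapply(c(1e4, 1e5, 1e6), function(md)
    length(suppressMessages(callRegions(rnd, c("E4", "E5"),
                                        mergeDistance = md))), numeric(1))
  expect_true(all(diff(nReg) <= 0))
})

test_that("region annotation equals a brute-force interval scan", {
  set.seed(18)
  regions <- GenomicRanges::GRanges("A01", IRanges::IRanges(
    sort(sample.int(90000L, 8L)), width = 5000L))
  genes <- GenomicRanges::GRanges("A01", IRanges::IRanges(
    sort(sample.int(95000L, 40L)), width = 1200L),
    gene_id = sprintf("g%02d", 1:40))
  degs <- sprintf("g%02d", sample.int(40L, 10L))
  nods <- sprintf("g%02d", sample.int(40L, 6L))
  ann <- annotateRegions(regions, genes, degs, nods)
  brute <- list()
  for (i in seq_along(regions)) for (j in seq_along(genes)) {
    if (GenomicRanges::start(genes)[j] <= GenomicRanges::end(regions)[i] &&
        GenomicRanges::end(genes)[j] >= GenomicRanges::start(regions)[i])
      brute[[length(brute) + 1L]] <- c(i, j)
  }
  expect_identical(nrow(ann), length(brute))
  expect_identical(paste(ann$region, ann$gene_id),
                   vapply(brute, function(x)
                     paste(x[1], sprintf("g%02d", x[2])), character(1)))
  both <- ann$gene_id %in% degs & ann$gene_id %in% nods
  expect_identical(ann$label[both], rep("both", sum(both)))
  # gene-desert region annotates nothing
  desert <- GenomicRanges::GRanges("B09", IRanges::IRanges(1L, 1000L))
  expect_identical(nrow(suppressWarnings(
    annotateRegions(desert, genes, degs, nods))), 0L)
})

test_that("region BED serialization round-trips losslessly", {
  snps <- mkRecords(c(1000L, 2000L, 900000L))
  regs <- suppressMessages(callRegions(snps, c("E4", "E5"),
                                       mergeDistance = 1e5))
  path <- tempfile(fileext = ".bed")
  exportBed(regs, path)
  back <- readBed(path)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(regs))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(regs))
  expect_identical(as.character(GenomicRanges::seqnames(back)),
                   as.character(GenomicRanges::seqnames(regs)))
})

test_that("graphical genotype matrix maps lines to parental origins", {
  tab <- mergePlatforms(list(x = data.table::rbindlist(list(
    mkRecords(10L), mkRecords(20L, gtE4 = "hom_alt", gtE5 = "hom_ref")))))
  g <- graphicalGenotypes(tab, c("E4", "E5"))
  expect_identical(g$E4, c("P1", "P2"))
  expect_identical(g$E5, c("P2", "P1"))
})
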