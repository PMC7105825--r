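# helper: a truth-like gene model GRanges over a supplied genome
mkGenes <- function(chrom, starts, ends, class, orthogroup = 0L,
                    simRank = 0L, seqlen = NULL) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, ends),
    gene_id = sprintf("g%03d", seq_along(starts)), class = class,
    orthogroup = orthogroup, simRank = simRank,
    expressed = TRUE, deg = FALSE, nod = FALSE)
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- seqlen
  gr
}

test_that("probe tiling counts follow template length arithmetic", {
  set.seed(1)
  genome <- Biostrings::DNAStringSet(c(A01 = rndSeq(20000)))
  # class 2: 360 bp CDS -> 3 probes, CDS only
  g2 <- mkGenes("A01", 5001L, 5360L, "class2", seqlen = c(A01 = 20000L))
  p2 <- tileProbes(g2, genome)
  expect_length(p2, 3L)
  expect_true(all(Biostrings::width(p2) == 120L))
  expect_identical(min(S4Vectors::mcols(p2)$designStart), 5001L)
  # class 1: 1000 bp gene + 2 kb up + 1 kb down -> floor(4000/120) = 33
  g1 <- mkGenes("A01", 8001L, 9000L, "class1", orthogroup = 1L,
                simRank = 1L, seqlen = c(A01 = 20000L))
  p1 <- tileProbes(g1, genome)
  expect_length(p1, 33L)
  expect_identical(min(S4Vectors::mcols(p1)$designStart), 8001L - 2000L)
  # tiles from one template never overlap
  st <- sort(S4Vectors::mcols(p1)$designStart)
  expect_true(all(diff(st) >= 120L))
})

test_that("an orthogroup contributes at most its top four genes", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(A01 = rndSeq(30000)))
  starts <- seq(1000L, by = 4000L, length.out = 6L)
  g <- mkGenes("A01", starts, starts + 239L, rep("class1", 6L),
               orthogroup = rep(7L, 6L), simRank = c(3L, 1L, 5L, 2L, 6L, 4L),
               seqlen = c(A01 = 30000L))
  p <- tileProbes(g, genome, flankUp = 0L, flankDown = 0L)
  contributing <- unique(S4Vectors::mcols(p)$source_gene)
  expect_length(contributing, 4L)
  # the four kept genes are those ranked 1..4
  expect_setequal(contributing,
                  S4Vectors::mcols(g)$gene_id[S4Vectors::mcols(g)$simRank <= 4L])
})

test_that("templates shorter than one probe yield no probes", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(c(A01 = rndSeq(5000)))
  g <- mkGenes("A01", 100L, 199L, "class2", seqlen = c(A01 = 5000L))
  expect_message(p <- tileProbes(g, genome), "0 probes")
  expect_length(p, 0L)
})

test_that("probe mapping finds exactly the loci sharing >=80% identity", {
  set.seed(4)
  chromA <- rndSeq(6000)
  probeSeq <- substring(chromA, 2001, 2120)
  # plant a homoeologous copy at 85% identity in chromosome B, keeping one
  # window clean so the seed-and-extend search has an exact seed
  mut <- strsplit(probeSeq, "")[[1]]
  flip <- sample(setdiff(seq_len(120L), 49:80), 18L)
  mut[flip] <- vapply(mut[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  chromB <- paste0(rndSeq(3000), paste(mut, collapse = ""), rndSeq(2880))
  genome <- Biostrings::DNAStringSet(c(A01 = chromA, B01 = chromB))
  probes <- Biostrings::DNAStringSet(c(p1 = probeSeq))
  hits <- mapProbes(probes, genome, hitCutoff = 96L)
  expect_length(hits, 2L)
  expect_setequal(as.character(GenomicRanges::seqnames(hits)), c("A01", "B01"))
  expect_identical(as.numeric(S4Vectors::mcols(hits)$identityScore[
    as.character(GenomicRanges::seqnames(hits)) == "A01"]), 120)
  # brute-force oracle: scan every ungapped placement on both strands
  oracle <- function(p, g, cutoff = 96L) {
    n <- 0L
    for (s in c(p, tetrasnp:::revCompChar(p))) {
      sv <- strsplit(s, "")[[1]]
      for (ch in as.character(g)) {
        cv <- strsplit(ch, "")[[1]]
        for (st in seq_len(nchar(ch) - 119L)) {
          if (sum(cv[st:(st + 119L)] == sv) >= cutoff) n <- n + 1L
        }
      }
    }
    n
  }
  expect_identical(length(hits), oracle(probeSeq, genome))
  # a random foreign probe has no hits
  expect_length(mapProbes(Biostrings::DNAStringSet(c(px = rndSeq(120))),
                          genome), 0L)
})

test_that("hit sets are nested as the cutoff is lowered", {
  w <- smallWorld()
  h96 <- mapProbes(w$probes, truthGenome(w$truth), hitCutoff = 96L)
  h84 <- mapProbes(w$probes, truthGenome(w$truth), hitCutoff = 84L)
  k96 <- paste(S4Vectors::mcols(h96)$probe_id,
               GenomicRanges::seqnames(h96), GenomicRanges::start(h96))
  k84 <- paste(S4Vectors::mcols(h84)$probe_id,
               GenomicRanges::seqnames(h84), GenomicRanges::start(h84))
  expect_true(all(k96 %in% k84))
})

test_that("redundancy removal collapses duplicates on both strands", {
  set.seed(5)
  a <- rndSeq(120)
  dup <- Biostrings::DNAStringSet(c(p1 = a, p2 = a))
  expect_length(deduplicateProbes(dup), 1L)
  rcDup <- Biostrings::DNAStringSet(c(p1 = a, p2 = tetrasnp:::revCompChar(a)))
  expect_length(deduplicateProbes(rcDup), 1L)
})

test_that("all-distinct random probes all survive deduplication", {
  set.seed(6)
  seqs <- vapply(1:25, function(i) rndSeq(120), character(1))
  # brute-force oracle: no pair reaches 80% ungapped identity at >=80%
  # mutual coverage on either strand
  pairIdentity <- function(x, y) {
    best <- 0
    xv <- strsplit(x, "")[[1]]
    for (s in c(y, tetrasnp:::revCompChar(y))) {
      yv <- strsplit(s, "")[[1]]
      for (off in -24:24) {
        xi <- max(1, 1 - off); yi <- max(1, 1 + off)
        ov <- min(120 - xi + 1, 120 - yi + 1)
        if (ov < 96) next
        m <- sum(xv[xi:(xi + ov - 1)] == yv[yi:(yi + ov - 1)]) / ov
        best <- max(best, m)
      }
    }
    best
  }
  maxId <- max(vapply(utils::combn(25, 2, simplify = FALSE), function(ij)
    pairIdentity(seqs[[ij[1]]], seqs[[ij[2]]]), numeric(1)))
  expect_lt(maxId, 0.8)
  probes <- Biostrings::DNAStringSet(seqs)
  names(probes) <- sprintf("p%02d", 1:25)
  expect_length(deduplicateProbes(probes), 25L)
})

test_that("panel selection fills uncovered fragments with one probe each", {
  set.seed(7)
  # toy genome of 10 fragments of 1 kb
  genome <- Biostrings::DNAStringSet(c(A01 = rndSeq(10000)))
  # 3 fragments pre-covered by a class1 single-hit probe each; the other 7
  # each contain class2 single-hit probes
  probeStarts <- c(200L, 1200L, 2200L,                 # class1, frags 1-3
                   3300L, 3500L, 4300L, 5300L, 6300L, 7300L, 8300L, 9300L)
  cls <- c(rep("class1", 3L), rep("class2", 8L))
  seqs <- substring(as.character(genome[[1]]), probeStarts, probeStarts + 119L)
  probes <- Biostrings::DNAStringSet(seqs)
  names(probes) <- sprintf("pr%02d", seq_along(seqs))
  S4Vectors::mcols(probes) <- S4Vectors::DataFrame(
    probe_id = names(probes), source_gene = sprintf("g%02d", seq_along(seqs)),
    class = cls, chrom = "A01", designStart = probeStarts)
  hits <- mapProbes(probes, genome)
  sel <- selectPanel(probes, hits, genome, fragmentSize = 1000L)
  counts <- sel@counts
  expect_identical(unname(counts["class1_single"]), 3L)
  expect_identical(unname(counts["spacing"]), 7L)
  # fragment 4 holds two candidates (3300, 3500): lowest coordinate wins
  chosen <- S4Vectors::mcols(sel@probes)
  expect_true("pr04" %in% chosen$probe_id[chosen$reason == "spacing"])
  expect_false("pr05" %in% chosen$probe_id)
  # spacing selection is injective over fragments: one probe per fragment
  spacingStarts <- sort(chosen$designStart[chosen$reason == "spacing"])
  expect_identical(length(unique(spacingStarts %/% 1000L)),
                   length(spacingStarts))
  # per-reason counts sum to the panel size
  expect_identical(sum(counts), length(sel@probes))
})

test_that("multi-hit rescue applies only to genes without single-hit probes", {
  w <- smallWorld()
  sel <- selectPanel(w$probes, w$hits, truthGenome(w$truth))
  md <- S4Vectors::mcols(sel@probes)
  rescued <- md[md$reason == "multi_hit_rescue", ]
  if (nrow(rescued)) {
    nH <- table(S4Vectors::mcols(w$hits)$probe_id)
    expect_true(all(nH[rescued$probe_id] >= 2 & nH[rescued$probe_id] <= 4))
    # rescued genes have no single-hit probe of their own
    singleGenes <- unique(md$source_gene[md$reason %in%
                                           c("class1_single", "resistance_single")])
    expect_length(intersect(rescued$source_gene, singleGenes), 0L)
  }
  # every class1/resistance gene owning a single-hit probe is in the panel
  pm <- S4Vectors::mcols(w$probes)
  nH <- table(S4Vectors::mcols(w$hits)$probe_id)
  single <- names(nH)[nH == 1]
  eligible <- pm$probe_id %in% single & pm$class %in% c("class1", "resistance")
  covered <- unique(pm$source_gene[eligible])
  expect_true(all(covered %in% md$source_gene))
})
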