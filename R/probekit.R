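#' Tile capture probes over gene templates
#'
#' Class 1 genes (nodulation-related / differentially expressed) are tiled
#' over the gene body plus 2 kb upstream and 1 kb downstream; class 2 and
#' resistance genes over the coding sequence only. Tiles are fixed-length,
#' non-overlapping, and a trailing remainder shorter than one probe is
#' dropped. Within a class 1 orthogroup only the top `maxPerOrthogroup` genes
#' by similarity rank contribute probes. Flanks are clipped at chromosome
#' ends; a template shorter than one probe yields no probes (message).
#'
#' @param geneModels GRanges with `gene_id`, `class`, `orthogroup`, `simRank`
#'   metadata columns (see [simulateTetraploid()]).
#' @param genome named DNAStringSet.
#' @param probeLength probe length in bp (120).
#' @param flankUp,flankDown class 1 flank sizes in bp.
#' @param maxPerOrthogroup cap on genes per class 1 orthogroup.
#' @return DNAStringSet of probes; mcols carry probe_id, source_gene, class,
#'   chrom and design start coordinate.
#' @export
tileProbes <- function(geneModels, genome, probeLength = 120L,
                       flankUp = 2000L, flankDown = 1000L,
                       maxPerOrthogroup = 4L) {
  gm <- geneModels
  keep <- rep(TRUE, length(gm))
  cls <- mcols(gm)$class
  og <- mcols(gm)$orthogroup
  rk <- mcols(gm)$simRank
  for (grp in unique(og[cls == "class1" & og > 0])) {
    idx <- which(og == grp & cls == "class1")
    if (length(idx) > maxPerOrthogroup)
      keep[idx[order(rk[idx])][-seq_len(maxPerOrthogroup)]] <- FALSE
  }
  gm <- gm[keep]
  cls <- mcols(gm)$class
  chromLens <- seqlengthsOf(genome)

  seqs <- character(0); meta <- list()
  chr <- as.character(GenomeInfoDb::seqnames(gm))
  tmplStart <- ifelse(cls == "class1", pmax(1L, start(gm) - flankUp), start(gm))
  tmplEnd <- ifelse(cls == "class1",
                    pmin(chromLens[chr], end(gm) + flankDown), end(gm))
  for (i in seq_along(gm)) {
    tlen <- tmplEnd[i] - tmplStart[i] + 1L
    ntile <- tlen %/% probeLength
    if (ntile == 0L) {
      message("template shorter than probe length for gene ",
              mcols(gm)$gene_id[i], "; 0 probes")
      next
    }
    starts <- tmplStart[i] + (seq_len(ntile) - 1L) * probeLength
    probe <- substring(as.character(genome[[chr[i]]]), starts,
                       starts + probeLength - 1L)
    meta[[length(meta) + 1L]] <- data.table(
      probe_id = sprintf("%s_p%03d", mcols(gm)$gene_id[i], seq_len(ntile)),
      source_gene = mcols(gm)$gene_id[i], class = cls[i], chrom = chr[i],
      designStart = starts)
    seqs <- c(seqs, probe)
  }
  md <- rbindlist(meta)
  if (!length(seqs)) {
    out <- Biostrings::DNAStringSet()
    mcols(out) <- DataFrame(probe_id = character(), source_gene = character(),
                            class = character(), chrom = character(),
                            designStart = integer())
    return(out)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- md$probe_id
  mcols(out) <- DataFrame(probe_id = md$probe_id, source_gene = md$source_gene,
                          class = md$class, chrom = md$chrom,
                          designStart = md$designStart)
  out
}

#' Map probes to the genome and score hits by alignment identity
#'
#' Seed-and-extend ungapped search on both strands. A hit is a full-length
#' ungapped placement whose identity score -- alignment length times
#' fractional identity, i.e. the number of matching bases -- reaches
#' `hitCutoff` (default 96, which is 80% of a 120 bp probe).
#'
#' @param probes DNAStringSet (e.g. from [tileProbes()]).
#' @param genome named DNAStringSet.
#' @param hitCutoff minimum identity score.
#' @param k exact seed length; @param seedStep spacing between seeds.
#' @return GRanges of hits with probe_id, percentIdentity, alignmentLength,
#'   identityScore, mismatches and nHits (hits of that probe) columns.
#' @export
mapProbes <- function(probes, genome, hitCutoff = 96L, k = 16L, seedStep = 8L) {
  if (!length(probes)) return(GRanges())
  plen <- Biostrings::width(probes)
  maxMm <- plen - as.integer(hitCutoff)
  if (any(maxMm < 0)) stop("hitCutoff exceeds probe length")
  hits <- cpp_align(as.character(genome), as.character(probes),
                    as.integer(maxMm), as.integer(k), as.integer(seedStep),
                    TRUE)
  if (!nrow(hits)) return(GRanges())
  pid <- names(probes)[hits$read]
  if (is.null(pid)) pid <- as.character(hits$read)
  w <- plen[hits$read]
  gr <- GRanges(names(genome)[hits$chrom],
                IRanges(hits$start, hits$start + w - 1L),
                strand = ifelse(hits$strand == 0L, "+", "-"),
                probe_id = pid, percentIdentity = (w - hits$mismatches) / w,
                alignmentLength = w, identityScore = w - hits$mismatches,
                mismatches = hits$mismatches)
  cnt <- table(gr$probe_id)
  mcols(gr)$nHits <- as.integer(cnt[gr$probe_id])
  GenomeInfoDb::seqlengths(gr) <- seqlengthsOf(genome)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Remove redundant probes by greedy clustering
#'
#' Greedy single-linkage-to-representative clustering in the style of
#' CD-HIT-EST: probes are sorted by length (ties broken lexicographically by
#' sequence) and each probe joins the first representative it matches at
#' `identity` or better over an ungapped overlap covering at least `coverage`
#' of both sequences, on either strand; otherwise it founds a new cluster.
#' Representatives are returned.
#'
#' @param probes DNAStringSet.
#' @param identity minimum fractional identity within the overlap (0.8).
#' @param coverage minimum fraction of both sequences covered (0.8).
#' @param word prefilter word size (candidate representatives must share one
#'   exact word).
#' @return the non-redundant subset of `probes`, in input order.
#' @export
deduplicateProbes <- function(probes, identity = 0.8, coverage = 0.8,
                              word = 10L) {
  if (length(probes) <= 1L) return(probes)
  ord <- order(-Biostrings::width(probes), as.character(probes))
  rep <- cpp_greedy_cluster(as.character(probes)[ord], identity, coverage,
                            as.integer(word))
  reps <- ord[rep == seq_along(ord)]
  probes[sort(reps)]
}

#' Select the final capture panel
#'
#' Three-stage selection mirroring gene-targeted capture panel design:
#' 1. every single-hit probe covering a class 1 or resistance gene;
#' 2. probes with two to four hits, rescued only for class 1/resistance genes
#'    that have no single-hit probe;
#' 3. spacing: the genome is partitioned into consecutive `fragmentSize`
#'    windows and, for each window not intersected by a hit of an
#'    already-selected probe, the single-hit class 2 probe with the lowest
#'    hit coordinate inside the window is selected (at most one per window).
#' An optional exact `targetSize` trims spacing probes deterministically from
#' the highest coordinates down.
#'
#' @param probes DNAStringSet with class metadata (from [tileProbes()],
#'   possibly deduplicated).
#' @param hits GRanges from [mapProbes()] computed at the panel's cutoff.
#' @param genome named DNAStringSet (defines the fragment grid).
#' @param fragmentSize genome fragment size in bp (default 44,300).
#' @param targetSize optional exact panel size.
#' @return a [PanelSelection-class].
#' @export
selectPanel <- function(probes, hits, genome, fragmentSize = 44300L,
                        targetSize = NULL) {
  pid <- mcols(probes)$probe_id
  cls <- stats::setNames(mcols(probes)$class, pid)
  hitCount <- table(hits$probe_id)
  nHits <- stats::setNames(as.integer(hitCount[pid]), pid)
  nHits[is.na(nHits)] <- 0L

  geneOf <- stats::setNames(mcols(probes)$source_gene, pid)
  single <- names(nHits)[nHits == 1L]
  stage1 <- single[cls[single] %in% c("class1", "resistance")]
  reason <- stats::setNames(
    ifelse(cls[stage1] == "class1", "class1_single", "resistance_single"),
    stage1)

  # genes of stage-1-eligible classes with no single-hit probe: rescue 2-4 hit
  targetGenes <- unique(geneOf[cls[pid] %in% c("class1", "resistance")])
  coveredGenes <- unique(geneOf[stage1])
  uncovered <- setdiff(targetGenes, coveredGenes)
  stage2 <- names(nHits)[nHits >= 2L & nHits <= 4L &
                           geneOf %in% uncovered &
                           cls %in% c("class1", "resistance")]
  reason[stage2] <- "multi_hit_rescue"

  selected <- c(stage1, stage2)

  # spacing stage over the fragment grid
  chromLens <- seqlengthsOf(genome)
  fragGr <- unlist(GenomicRanges::GRangesList(lapply(names(chromLens), function(ch) {
    starts <- seq(1L, chromLens[[ch]], by = fragmentSize)
    GRanges(ch, IRanges(starts, pmin(starts + fragmentSize - 1L,
                                     chromLens[[ch]])))
  })))
  coveredFrag <- rep(FALSE, length(fragGr))
  selHits <- hits[hits$probe_id %in% selected]
  if (length(selHits))
    coveredFrag <- IRanges::overlapsAny(fragGr, selHits)

  spacingCand <- hits[hits$probe_id %in% single & cls[hits$probe_id] == "class2"]
  spacing <- character(0)
  if (length(spacingCand)) {
    ov <- GenomicRanges::findOverlaps(fragGr, spacingCand)
    dt <- data.table(frag = S4Vectors::queryHits(ov),
                     probe = spacingCand$probe_id[S4Vectors::subjectHits(ov)],
                     start_ = start(spacingCand)[S4Vectors::subjectHits(ov)])
    dt <- dt[!coveredFrag[frag]]
    if (nrow(dt)) {
      setorder(dt, frag, start_, probe)
      pick <- dt[, .SD[1L], by = frag]
      # a probe straddling two windows can win both; keep its first
      pick <- pick[!duplicated(probe)]
      spacing <- pick$probe
    }
  }
  reason[spacing] <- "spacing"
  selected <- c(selected, spacing)

  if (!is.null(targetSize) && length(selected) > targetSize) {
    nDrop <- length(selected) - targetSize
    spHits <- hits[match(spacing, hits$probe_id)]
    dropOrder <- spacing[order(-start(spHits),
                               -as.integer(factor(as.character(
                                 GenomeInfoDb::seqnames(spHits)))))]
    drop <- utils::head(dropOrder, nDrop)
    selected <- setdiff(selected, drop)
    reason <- reason[selected]
  }

  sel <- probes[match(selected, pid)]
  mcols(sel)$reason <- unname(reason[selected])
  counts <- table(factor(reason[selected],
                         levels = c("class1_single", "resistance_single",
                                    "multi_hit_rescue", "spacing")))
  methods::new("PanelSelection", probes = sel,
               counts = stats::setNames(as.integer(counts), names(counts)),
               fragmentSize = as.integer(fragmentSize))
}
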