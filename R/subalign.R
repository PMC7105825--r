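#' Align reads to one or both subgenomes
#'
#' Deterministic exact-seed, ungapped-extension alignment supporting the two
#' reference strategies used for allotetraploid SNP calling:
#' \describe{
#' \item{`separate`}{reads are aligned to the A and B subgenomes
#'   independently and the best placement per subgenome is kept ("overall"
#'   retention) -- homoeologous reads co-align, which the anchor- and
#'   haplotype-based filters later exploit.}
#' \item{`concatenated`}{reads are aligned to the joint A+B reference and
#'   only reads with a single equally-best placement are retained ("unique"
#'   retention, the ungapped analogue of dropping MAPQ-0 / multi-hit reads).
#'   For paired reads both mates must be unique, on the same chromosome and
#'   within the insert window, or the pair is dropped.}
#' }
#' Best placement means fewest mismatches; ties make a read non-unique.
#' Reads shorter than the seed are skipped with a warning.
#'
#' @param readset a [ReadSet-class] or a DataFrame shaped like its reads.
#' @param genome named DNAStringSet; chromosome names must start with the
#'   subgenome letter (`A..`/`B..`).
#' @param mode `"concatenated"` or `"separate"`.
#' @param maxMismatchRate mismatch budget as a fraction of read length. The
#'   default 0.12 emulates a local aligner tolerant enough for reads from the
#'   ~7% divergent homoeologous subgenome to cross-align.
#' @param k exact seed length; @param seedStep seed spacing.
#' @param insertMin,insertMax pair concordance window (concatenated mode).
#' @return data.table with one row per retained alignment: id, sample, chrom,
#'   start, end, strand, mismatches, n_equal_best, mate, pairId, seqAligned
#'   (reference-oriented read sequence) plus the read's truth tags.
#' @export
alignReads <- function(readset, genome, mode = c("concatenated", "separate"),
                       maxMismatchRate = 0.12, k = 21L, seedStep = 10L,
                       insertMin = 100L, insertMax = 600L) {
  mode <- match.arg(mode)
  reads <- if (methods::is(readset, "ReadSet")) readset@reads else readset
  if (!nrow(reads)) return(emptyAlignments())
  lens <- nchar(reads$seq)
  if (any(lens < k)) {
    warning(sum(lens < k), " read(s) shorter than the seed length skipped")
    reads <- reads[lens >= k, ]
    if (!nrow(reads)) return(emptyAlignments())
    lens <- nchar(reads$seq)
  }
  maxMm <- as.integer(floor(maxMismatchRate * lens))

  alignTo <- function(chromSet) {
    res <- cpp_align(as.character(chromSet), reads$seq, maxMm,
                     as.integer(k), as.integer(seedStep), FALSE)
    if (!nrow(res)) return(data.table())
    dt <- as.data.table(res)
    dt[, `:=`(
      id = reads$id[read], sample = reads$sample[read],
      chrom = names(chromSet)[chrom],
      end = start + lens[read] - 1L,
      strand = ifelse(strand == 0L, "+", "-"),
      mate = reads$mate[read], pairId = reads$pairId[read],
      truthChrom = reads$truthChrom[read],
      truthStart = reads$truthStart[read],
      truthStrand = reads$truthStrand[read],
      seqAligned = ifelse(strand == 0L, reads$seq[read],
                          revCompChar(reads$seq[read])))]
    dt[, read := NULL]
    dt
  }

  if (mode == "separate") {
    sub <- subgenomeOf(names(genome))
    out <- rbindlist(list(alignTo(genome[sub == "A"]),
                          alignTo(genome[sub == "B"])),
                     use.names = TRUE, fill = TRUE)
  } else {
    out <- alignTo(genome)
    if (nrow(out)) {
      out <- out[n_equal_best == 1L]
      paired <- nrow(out) && any(out$mate > 0L)
      if (paired) {
        pairInfo <- out[mate > 0L,
          .(ok = .N == 2L && chrom[1] == chrom[2] &&
              {
                span <- max(end) - min(start) + 1L
                span >= insertMin && span <= insertMax
              }),
          by = pairId]
        good <- pairInfo[ok == TRUE, pairId]
        out <- out[mate == 0L | pairId %in% good]
      }
    }
  }
  if (!nrow(out)) return(emptyAlignments())
  setorder(out, chrom, start, id)
  out[]
}

emptyAlignments <- function() data.table(
  id = character(), sample = character(), chrom = character(),
  start = integer(), end = integer(), strand = character(),
  mismatches = integer(), n_equal_best = integer(), mate = integer(),
  pairId = character(), truthChrom = character(), truthStart = integer(),
  truthStrand = character(), seqAligned = character())

#' Alignment table as GRanges
#'
#' @param alignments a table from [alignReads()].
#' @param genome optional named DNAStringSet supplying seqlengths.
#' @return GRanges with the alignment metadata columns.
#' @export
alignmentsAsGRanges <- function(alignments, genome = NULL) {
  if (!nrow(alignments)) return(GRanges())
  gr <- GRanges(alignments$chrom, IRanges(alignments$start, alignments$end),
                strand = alignments$strand, id = alignments$id,
                sample = alignments$sample,
                mismatches = alignments$mismatches,
                n_equal_best = alignments$n_equal_best)
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <- seqlengthsOf(genome)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Per-site base counts per sample
#'
#' Accumulates A/C/G/T counts at every covered reference position, per
#' sample, from reference-oriented aligned read sequences (strand is ignored
#' for counting). Positions with no aligned base are absent from the result.
#'
#' @param alignments table from [alignReads()].
#' @param genome named DNAStringSet (the reference the alignments use).
#' @return data.table: sample, chrom, pos, ref, A, C, G, T, depth.
#' @export
pileupCounts <- function(alignments, genome) {
  if (!nrow(alignments))
    return(data.table(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      depth = integer()))
  refs <- as.character(genome)
  chromIdx <- match(alignments$chrom, names(genome))
  out <- list()
  for (smp in unique(alignments$sample)) {
    sel <- alignments$sample == smp
    p <- as.data.table(cpp_pileup(refs, chromIdx[sel],
                                  alignments$start[sel],
                                  alignments$seqAligned[sel]))
    if (!nrow(p)) next
    p[, `:=`(sample = smp, chrom = names(genome)[chrom])]
    out[[smp]] <- p
  }
  dt <- rbindlist(out)
  if (!nrow(dt)) return(pileupCounts(emptyAlignments(), genome))
  dt[, depth := A + C + G + T]
  # attach reference base
  refDt <- unique(dt[, .(chrom, pos)])
  refDt[, ref := {
    s <- refs[[chrom[1]]]
    substring(s, pos, pos)
  }, by = chrom]
  dt <- merge(dt, refDt, by = c("chrom", "pos"), sort = FALSE)
  setorder(dt, chrom, pos, sample)
  dt[, .(sample, chrom, pos, ref, A, C, G, T, depth)]
}
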