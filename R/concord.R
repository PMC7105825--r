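# genotype label ("hom_ref"/"hom_alt"/"het") -> unordered allele pair string
gtLabelToString <- function(label, ref, alt) {
  out <- rep(NA_character_, length(label))
  out[label == "hom_ref"] <- gtString(ref, ref)[label == "hom_ref"]
  out[label == "hom_alt"] <- gtString(alt, alt)[label == "hom_alt"]
  out[label == "het"] <- gtString(ref, alt)[label == "het"]
  out
}

#' Validate pipeline SNPs against array genotypes
#'
#' A SNP record is overlapped when an array marker sits at the same
#' chromosome and position. An overlapped record is concordant when the
#' array is also polymorphic between the two compared samples *and* both
#' samples' genotypes (unordered allele pairs) match the sequencing calls.
#' Non-concordant overlapped loci are partitioned into discordance classes:
#' heterozygous-by-sequence / homozygous-on-array, homozygous-by-sequence /
#' heterozygous-on-array, allele mismatch, or monomorphic on the array.
#'
#' @param snps SNP record table from [runPipeline()] (needs ref, alt and
#'   `gt_<sample>` columns).
#' @param arrayTable array genotype table (see [simulateArray()]).
#' @param samples character(2), compared samples.
#' @return list with `report` (one-row data.frame: pipeline, n_total,
#'   n_overlapped, n_concordant, concordance_pct, zygosity splits) and
#'   `loci` (per-overlapped-locus classification). With zero overlapped loci
#'   the concordance is `NA` with `concordance_defined = FALSE`.
#' @export
overlapAndScore <- function(snps, arrayTable, samples = c("P1", "P2")) {
  pipe <- if (nrow(snps) && "pipeline" %in% names(snps)) snps$pipeline[1]
          else NA_character_
  nTotal <- nrow(snps)
  nHet <- if (nTotal) sum(snps$zygosity == "heterozygous") else 0L
  nHom <- if (nTotal) sum(snps$zygosity == "homozygous") else 0L
  emptyRep <- function() data.frame(
    pipeline = pipe, n_total = nTotal, n_het_total = nHet, n_hom_total = nHom,
    n_overlapped = 0L, n_overlapped_het = 0L, n_overlapped_hom = 0L,
    n_concordant = 0L, n_concordant_het = 0L, n_concordant_hom = 0L,
    concordance_pct = NA_real_, concordance_defined = FALSE)
  if (!nTotal) return(list(report = emptyRep(), loci = NULL))

  s <- as.data.table(snps)
  a <- as.data.table(arrayTable)
  m <- merge(s, a[, c("chrom", "pos", samples), with = FALSE],
             by = c("chrom", "pos"), suffixes = c("", ".array"))
  if (!nrow(m)) return(list(report = emptyRep(), loci = NULL))

  seqA <- gtLabelToString(m[[paste0("gt_", samples[1])]], m$ref, m$alt)
  seqB <- gtLabelToString(m[[paste0("gt_", samples[2])]], m$ref, m$alt)
  arrA <- m[[samples[1]]]
  arrB <- m[[samples[2]]]
  arrayPoly <- !is.na(arrA) & !is.na(arrB) & arrA != arrB
  concordant <- arrayPoly & !is.na(seqA) & !is.na(seqB) &
    seqA == arrA & seqB == arrB

  isHetStr <- function(g) {
    p <- strsplit(g, "/", fixed = TRUE)
    vapply(p, function(x) length(x) == 2L && x[1] != x[2], logical(1))
  }
  seqHet <- m$zygosity == "heterozygous"
  arrHet <- isHetStr(arrA) | isHetStr(arrB)
  cls <- rep("allele_mismatch", nrow(m))
  cls[!arrayPoly] <- "monomorphic_on_array"
  cls[arrayPoly & seqHet & !arrHet] <- "het_seq_hom_array"
  cls[arrayPoly & !seqHet & arrHet] <- "hom_seq_het_array"
  cls[concordant] <- "concordant"

  nOv <- nrow(m)
  report <- data.frame(
    pipeline = pipe, n_total = nTotal, n_het_total = nHet, n_hom_total = nHom,
    n_overlapped = nOv,
    n_overlapped_het = sum(seqHet), n_overlapped_hom = sum(!seqHet),
    n_concordant = sum(concordant),
    n_concordant_het = sum(concordant & seqHet),
    n_concordant_hom = sum(concordant & !seqHet),
    concordance_pct = percentOf(sum(concordant), nOv),
    concordance_defined = TRUE)
  loci <- data.frame(chrom = m$chrom, pos = m$pos, class = cls,
                     seq_gt_a = seqA, seq_gt_b = seqB,
                     array_gt_a = arrA, array_gt_b = arrB,
                     stringsAsFactors = FALSE)
  list(report = report, loci = loci)
}

#' Counts and percentages of discordance classes
#'
#' @param loci the per-locus table from [overlapAndScore()].
#' @return data.frame: class, count, pct (of overlapped loci, half-up to two
#'   decimals). Classes partition the overlapped loci.
#' @export
discordanceClasses <- function(loci) {
  if (is.null(loci) || !nrow(loci))
    return(data.frame(class = character(), count = integer(),
                      pct = numeric()))
  tab <- table(loci$class)
  data.frame(class = names(tab), count = as.integer(tab),
             pct = percentOf(as.integer(tab), nrow(loci)),
             stringsAsFactors = FALSE)
}

#' Fraction of homozygous parental SNP loci monomorphic within a line pair
#'
#' Restricted to array loci with homozygous, polymorphic genotypes between
#' the two parents: the numerator counts loci where the pair's genotypes
#' agree, the denominator loci with non-missing genotypes in both pair
#' members. A zero denominator yields `NA`.
#'
#' @param arrayTable array genotype table.
#' @param pair character(2), the sister lines.
#' @param parents character(2), the parental columns (default P1, P2).
#' @return list: n_monomorphic, n_informative, pct.
#' @export
monomorphicFraction <- function(arrayTable, pair, parents = c("P1", "P2")) {
  a <- as.data.table(arrayTable)
  isHom <- function(g) {
    p <- strsplit(g, "/", fixed = TRUE)
    !is.na(g) & vapply(p, function(x) length(x) == 2L && x[1] == x[2],
                       logical(1))
  }
  pa <- a[[parents[1]]]; pb <- a[[parents[2]]]
  homPoly <- isHom(pa) & isHom(pb) & pa != pb
  g1 <- a[[pair[1]]][homPoly]; g2 <- a[[pair[2]]][homPoly]
  inf <- !is.na(g1) & !is.na(g2)
  n <- sum(inf)
  mono <- sum(inf & g1 == g2)
  list(n_monomorphic = mono, n_informative = n,
       pct = percentOf(mono, n))
}

#' Shared and unique loci between two pipelines' SNP sets
#'
#' @param setA,setB SNP record tables (chrom + pos define a locus).
#' @return data.frame: n_a, n_b, n_shared, n_a_only, n_b_only,
#'   pct_a_covered_by_b (half-up, two decimals).
#' @export
pipelineOverlap <- function(setA, setB) {
  ka <- if (nrow(setA)) unique(paste(setA$chrom, setA$pos)) else character()
  kb <- if (nrow(setB)) unique(paste(setB$chrom, setB$pos)) else character()
  shared <- length(intersect(ka, kb))
  data.frame(n_a = length(ka), n_b = length(kb), n_shared = shared,
             n_a_only = length(ka) - shared, n_b_only = length(kb) - shared,
             pct_a_covered_by_b = percentOf(shared, length(ka)))
}
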