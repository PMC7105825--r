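#' Merge SNP sets from multiple platforms into one combined table
#'
#' Union of loci (chrom + pos) across platforms, keeping per-platform
#' provenance flags. Only loci homozygous-polymorphic between the two
#' parents enter the table. Conflicting genotype calls for a sample across
#' platforms are resolved by majority; ties drop the locus (logged via
#' message). Loci whose alternate alleles disagree across platforms are
#' dropped likewise.
#'
#' @param snpSets named list of SNP record tables (names are platform tags);
#'   each needs chrom, pos, ref, alt and `gt_<sample>` columns.
#' @param parents character(2) parental sample names.
#' @return data.table: chrom, pos, ref, alt, platforms (comma-separated
#'   provenance), and one `gt_<sample>` column per sample seen.
#' @export
mergePlatforms <- function(snpSets, parents = c("P1", "P2")) {
  stopifnot(length(names(snpSets)) == length(snpSets))
  rows <- list()
  for (pf in names(snpSets)) {
    s <- as.data.table(snpSets[[pf]])
    if (!nrow(s)) next
    gtCols <- grep("^gt_", names(s), value = TRUE)
    s <- s[, c("chrom", "pos", "ref", "alt", gtCols), with = FALSE]
    s[, platform := pf]
    rows[[pf]] <- s
  }
  long <- rbindlist(rows, fill = TRUE)
  if (!nrow(long))
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), platforms = character()))

  # allele consistency across platforms
  alleleN <- long[, .(n = data.table::uniqueN(paste(ref, alt))),
                  by = .(chrom, pos)]
  bad <- alleleN[n > 1L]
  if (nrow(bad))
    message(nrow(bad), " locus/loci dropped: incompatible alleles across platforms")
  long <- long[!bad[, .(chrom, pos)], on = c("chrom", "pos")]

  gtCols <- grep("^gt_", names(long), value = TRUE)
  resolve <- function(v) {
    v <- v[!is.na(v) & v != "missing"]
    if (!length(v)) return("missing")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[[1L]] == tab[[2L]]) return("tie")
    names(tab)[1L]
  }
  wide <- long[, c(.(ref = ref[1L], alt = alt[1L],
                     platforms = paste(sort(unique(platform)), collapse = ",")),
                   lapply(.SD, resolve)),
               by = .(chrom, pos), .SDcols = gtCols]
  tied <- rowSums(as.matrix(wide[, gtCols, with = FALSE]) == "tie") > 0L
  if (any(tied))
    message(sum(tied), " locus/loci dropped: tied genotype calls across platforms")
  wide <- wide[!tied]

  # only homozygous-polymorphic parental loci enter
  pa <- wide[[paste0("gt_", parents[1])]]
  pb <- wide[[paste0("gt_", parents[2])]]
  keep <- pa %in% c("hom_ref", "hom_alt") & pb %in% c("hom_ref", "hom_alt") &
    pa != pb
  out <- wide[keep]
  setorder(out, chrom, pos)
  out[]
}

#' SNP loci polymorphic between a pair of sister RILs
#'
#' Keeps loci where both sisters are homozygous, differ from each other, and
#' the parents differ homozygously (guaranteed upstream by
#' [mergePlatforms()]). Loci heterozygous or missing in either sister are
#' excluded.
#'
#' @param table combined table from [mergePlatforms()].
#' @param pair character(2) sister line names.
#' @return the qualifying subset of `table`.
#' @export
filterRilPolymorphic <- function(table, pair) {
  ga <- table[[paste0("gt_", pair[1])]]
  gb <- table[[paste0("gt_", pair[2])]]
  if (is.null(ga) || is.null(gb)) stop("pair genotypes missing from table")
  hom <- c("hom_ref", "hom_alt")
  table[ga %in% hom & gb %in% hom & ga != gb]
}

#' Call polymorphic genomic regions between sister RILs
#'
#' Consecutive qualifying SNPs on one chromosome merge into a region while
#' their gaps stay within `mergeDistance` and their sister-origin phase is
#' consistent; a phase flip (which sister carries which parental allele)
#' starts a new region, so each region represents one origin contrast. The
#' region spans the first to the last member SNP.
#'
#' @param snps qualifying SNP table from [filterRilPolymorphic()].
#' @param pair character(2) sister line names.
#' @param mergeDistance maximum gap between consecutive SNPs in one region
#'   (bp). Required and logged deliberately: region counts depend on it.
#' @param pairId label stored on the regions.
#' @return GRanges of regions with n_snps, phase and pair_id columns.
#' @export
callRegions <- function(snps, pair, mergeDistance = 1e6, pairId = paste(pair, collapse = "")) {
  message("callRegions: merge distance ", format(mergeDistance, scientific = FALSE), " bp")
  if (!nrow(snps)) return(GRanges())
  s <- copy(as.data.table(snps))
  ga <- s[[paste0("gt_", pair[1])]]
  s[, phase := fifelse(ga == "hom_ref", "A", "B")]
  setorder(s, chrom, pos)
  s[, block := cumsum(c(TRUE, chrom[-1] != chrom[-.N] |
                          pos[-1] - pos[-.N] > mergeDistance |
                          phase[-1] != phase[-.N]))]
  reg <- s[, .(chrom = chrom[1], start_ = min(pos), end_ = max(pos),
               n_snps = .N, phase = phase[1]), by = block]
  GRanges(reg$chrom, IRanges(reg$start_, reg$end_), n_snps = reg$n_snps,
          phase = reg$phase, pair_id = pairId)
}

#' Annotate regions with candidate genes
#'
#' Genes overlapping a region are attached with labels: differentially
#' expressed (`DEG`), nodulation-related ortholog (`nod`), or both.
#'
#' @param regions GRanges from [callRegions()].
#' @param geneModels GRanges with gene_id metadata.
#' @param degList,nodList character vectors of gene ids.
#' @return data.frame: region index, chrom, start, end, gene_id, label.
#' @export
annotateRegions <- function(regions, geneModels, degList = character(),
                            nodList = character()) {
  if (!length(regions))
    return(data.frame(region = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), label = character()))
  ov <- GenomicRanges::findOverlaps(regions, geneModels)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  gid <- mcols(geneModels)$gene_id[si]
  lab <- ifelse(gid %in% degList & gid %in% nodList, "both",
                ifelse(gid %in% degList, "DEG",
                       ifelse(gid %in% nodList, "nod", "other")))
  data.frame(region = qi,
             chrom = as.character(GenomeInfoDb::seqnames(regions))[qi],
             start = start(regions)[qi], end = end(regions)[qi],
             gene_id = gid, label = lab, stringsAsFactors = FALSE)
}

#' Graphical-genotype matrix for plotting
#'
#' Per-locus parental origin of each line: rows are qualifying loci, columns
#' the lines, values `P1`/`P2` (which parental allele the line carries).
#'
#' @param table combined table from [mergePlatforms()].
#' @param lines character vector of line names (columns).
#' @param parents character(2) parents.
#' @return data.frame with chrom, pos and one column per line.
#' @export
graphicalGenotypes <- function(table, lines, parents = c("P1", "P2")) {
  pa <- table[[paste0("gt_", parents[1])]]
  out <- data.frame(chrom = table$chrom, pos = table$pos,
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    g <- table[[paste0("gt_", ln)]]
    out[[ln]] <- ifelse(g %in% c("hom_ref", "hom_alt"),
                        ifelse(g == pa, parents[1], parents[2]), NA)
  }
  out
}
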