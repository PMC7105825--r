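#' Identity-stratified capture target regions
#'
#' Each probe hit with identity score at or above `cutoff` becomes a target
#' region: the hit span extended 100 bp in both directions and clipped at
#' chromosome ends. Region sets are nested across cutoffs: lowering the
#' cutoff only adds regions.
#'
#' @param hits GRanges from [mapProbes()] (must carry `identityScore`).
#' @param cutoff identity-score threshold (the study panel used
#'   96, 90, 84, 78, 72, 66, 60, i.e. 80% down to 50% of a 120 bp probe).
#' @param pad extension in bp (100).
#' @param merge if `TRUE`, overlapping regions are merged; the default keeps
#'   one region per hit so region counts remain interpretable.
#' @return GRanges of target regions with a `cutoff` metadata column.
#' @export
buildTargetRegions <- function(hits, cutoff, pad = 100L, merge = FALSE) {
  sel <- hits[mcols(hits)$identityScore >= cutoff]
  if (!length(sel)) {
    out <- GRanges()
    metadata(out)$cutoff <- cutoff
    return(out)
  }
  sl <- GenomeInfoDb::seqlengths(sel)
  gr <- GRanges(GenomeInfoDb::seqnames(sel),
                IRanges(pmax(1L, start(sel) - pad),
                        if (all(!is.na(sl))) {
                          pmin(end(sel) + pad,
                               sl[as.character(GenomeInfoDb::seqnames(sel))])
                        } else end(sel) + pad))
  mcols(gr)$identityScore <- mcols(sel)$identityScore
  if (merge) gr <- GenomicRanges::reduce(gr)
  mcols(gr)$cutoff <- cutoff
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  metadata(gr)$cutoff <- cutoff
  gr
}

#' On-target rate and coverage over a target region set
#'
#' A mapped read is on-target iff its alignment interval overlaps any region
#' by at least one base; a region is covered iff at least one read overlaps
#' it. Mean depth is the mean over regions of the per-base depth averaged
#' within each region. Empty alignment sets give zero rates, not an error.
#'
#' @param alignments GRanges of read alignments (see [alignmentsAsGRanges()]),
#'   or an alignment table from [alignReads()].
#' @param regions GRanges from [buildTargetRegions()].
#' @return one-row data.frame: cutoff, n_regions, n_regions_covered,
#'   pct_regions_covered, on_target_rate, mean_depth.
#' @export
coverageSummary <- function(alignments, regions) {
  if (is.data.frame(alignments)) alignments <- alignmentsAsGRanges(alignments)
  cutoff <- metadata(regions)$cutoff
  if (is.null(cutoff)) cutoff <- NA_real_
  nReg <- length(regions)
  if (!length(alignments) || nReg == 0L) {
    return(data.frame(cutoff = cutoff, n_regions = nReg,
                      n_regions_covered = 0L,
                      pct_regions_covered = if (nReg) 0 else NA_real_,
                      on_target_rate = 0, mean_depth = 0))
  }
  onTarget <- IRanges::overlapsAny(alignments, regions)
  covered <- IRanges::overlapsAny(regions, alignments)
  cov <- GenomicRanges::coverage(alignments)
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  meanDepth <- numeric(nReg)
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    rle <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0L, max(end(regions[sel])))
    if (length(rle) < max(end(regions[sel])))
      rle <- c(rle, S4Vectors::Rle(0L, max(end(regions[sel])) - length(rle)))
    v <- IRanges::Views(rle, start(regions[sel]), end(regions[sel]))
    meanDepth[sel] <- IRanges::viewMeans(v)
  }
  data.frame(cutoff = cutoff, n_regions = nReg,
             n_regions_covered = sum(covered),
             pct_regions_covered = percentOf(sum(covered), nReg),
             on_target_rate = mean(onTarget), mean_depth = mean(meanDepth))
}

#' Capture metrics across a ladder of identity cutoffs
#'
#' @param hits GRanges from [mapProbes()].
#' @param alignments alignment GRanges or table.
#' @param cutoffs identity-score cutoffs, highest first.
#' @param pad region extension in bp.
#' @return data.frame with one [coverageSummary()] row per cutoff.
#' @export
captureMetrics <- function(hits, alignments,
                           cutoffs = c(96, 90, 84, 78, 72, 66, 60),
                           pad = 100L) {
  if (is.data.frame(alignments)) alignments <- alignmentsAsGRanges(alignments)
  do.call(rbind, lapply(cutoffs, function(co)
    coverageSummary(alignments, buildTargetRegions(hits, co, pad = pad))))
}
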