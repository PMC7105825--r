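#' Write genome or probe sequences as FASTA
#'
#' @param seqs named DNAStringSet.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a read set as FASTQ
#'
#' Paired platforms produce `_R1`/`_R2` files; single-end platforms one
#' file. Qualities are uniform (the simulator's error model is uniform).
#'
#' @param readset a [ReadSet-class].
#' @param prefix output path prefix (without extension).
#' @return character vector of files written, invisibly.
#' @export
exportFastq <- function(readset, prefix) {
  r <- readset@reads
  writeOne <- function(rows, path) {
    s <- Biostrings::DNAStringSet(rows$seq)
    names(s) <- rows$id
    q <- Biostrings::PhredQuality(vapply(nchar(rows$seq), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
    path
  }
  if (readset@paired) {
    files <- c(writeOne(r[r$mate == 1L, ], paste0(prefix, "_R1.fastq")),
               writeOne(r[r$mate == 2L, ], paste0(prefix, "_R2.fastq")))
  } else {
    files <- writeOne(r, paste0(prefix, ".fastq"))
  }
  invisible(files)
}

#' Write SNP records as a two-or-more-sample VCF 4.2
#'
#' INFO carries the pipeline id, zygosity class and anchor flag; genotypes
#' are emitted as GT fields per sample. Coordinates are 1-based as required
#' by VCF.
#'
#' @param records SNP record table from [runPipeline()].
#' @param path output file.
#' @param samples sample columns to emit (defaults to every `gt_` column).
#' @return `path`, invisibly.
#' @export
exportVcf <- function(records, path, samples = NULL) {
  if (is.null(samples))
    samples <- sub("^gt_", "", grep("^gt_", names(records), value = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tetrasnp",
               "##INFO=<ID=PIPELINE,Number=1,Type=String,Description=\"Calling pipeline\">",
               "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Inter-sample zygosity class\">",
               "##INFO=<ID=ANCHORED,Number=1,Type=String,Description=\"Homoeolog-anchor filter applied\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(records)) {
    gtCode <- function(lbl) c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
                              missing = "./.")[lbl]
    anch <- if ("anchored" %in% names(records))
      ifelse(records$anchored, "yes", "no") else "na"
    info <- sprintf("PIPELINE=%s;ZYG=%s;ANCHORED=%s",
                    if ("pipeline" %in% names(records)) records$pipeline else ".",
                    records$zygosity, anch)
    gts <- vapply(seq_len(nrow(records)), function(i)
      paste(vapply(samples, function(s) {
        v <- records[[paste0("gt_", s)]][i]
        unname(gtCode(if (is.na(v)) "missing" else v))
      }, character(1)), collapse = "\t"), character(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                       records$chrom, records$pos, records$ref, records$alt,
                       info, gts), con)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open; GRanges are 1-based closed, so starts shift by
#' one on the way out. Round-trips through [readBed()] losslessly.
#'
#' @param gr GRanges; a `score` or `identityScore` column lands in column 5.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportBed <- function(gr, path) {
  score <- if (!is.null(mcols(gr)$identityScore)) mcols(gr)$identityScore
           else if (!is.null(mcols(gr)$score)) mcols(gr)$score
           else rep(0, length(gr))
  name <- if (!is.null(mcols(gr)$probe_id)) mcols(gr)$probe_id
          else if (!is.null(mcols(gr)$pair_id)) mcols(gr)$pair_id
          else rep(".", length(gr))
  strand <- as.character(strand(gr))
  strand[strand == "*"] <- "."
  utils::write.table(
    data.frame(as.character(GenomeInfoDb::seqnames(gr)), start(gr) - 1L,
               end(gr), name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back as GRanges
#'
#' @param path BED3+ file.
#' @return GRanges (1-based closed).
#' @export
readBed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]))
  if (ncol(d) >= 4) mcols(gr)$name <- d[[4]]
  if (ncol(d) >= 5) mcols(gr)$score <- d[[5]]
  if (ncol(d) >= 6) strand(gr) <- ifelse(d[[6]] == ".", "*", d[[6]])
  gr
}

#' Write a data frame as TSV
#'
#' @param x data.frame; @param path output file.
#' @return `path`, invisibly.
#' @export
exportTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
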