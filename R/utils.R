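#' @importFrom data.table data.table as.data.table := setkey setorder rbindlist
#'   setnames fifelse copy set melt dcast tstrsplit uniqueN .N .SD .I
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "A", "C", "G", "T", "alt", "altCount", "aln", "base", "chrom", "pos",
  "depth", "gt", "i.gt", "id", "mate", "mismatches", "n_equal_best", "nAlt",
  "origin", "pairId", "probe_id", "read", "refCount", "sample_", "seq_",
  "site", "start_", "strand_", "zygosity", "end_", "hap", "allele", "grp",
  "locus", "platform", "gtA", "gtB", "V1", "N", "frac", "minor", "major",
  "a1", "a2", "keep", "phase", "block", "gene_id", "reason", "cnt", "ok",
  "truthChrom", "truthStart", "truthStrand", "identityScore", "nHits",
  "confounded", "dpos", "db", "cb", "n", "unit", "orthogroup", "simRank",
  "oa", "ob", "probe", "frag", "g", "anchored", "pipeline", "ref"))

BASES <- c("A", "C", "G", "T")

# deterministic child seeds below 2^31
childSeed <- function(seed, k) (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L

# logistic capture-efficiency curve on probe-target identity
logisticCapture <- function(identity, midpoint, steepness) {
  1 / (1 + exp(-steepness * (identity - midpoint)))
}

#' Capture probability of a probe-target pair
#'
#' Two-parameter logistic on fractional sequence identity between a capture
#' probe and its genomic target. Defaults are calibrated so that targets
#' with at least 75% identity are captured at 90% or more of the maximal
#' efficiency, matching the empirical behaviour of hybrid capture in
#' allotetraploids.
#'
#' @param identity numeric in \[0,1\].
#' @param config a [SimConfig-class] supplying midpoint and steepness.
#' @return capture probability in \[0,1\].
#' @export
captureProbability <- function(identity, config) {
  logisticCapture(identity, config@captureMidpoint, config@captureSteepness)
}

# percentage rounded half-up to 2 decimals, as printed in study reports
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage from integer counts, rounded half-up to two decimals
#'
#' @param numerator,denominator integer counts.
#' @return numeric percentage; `NA` when the denominator is zero.
#' @export
percentOf <- function(numerator, denominator) {
  out <- roundHalfUp(100 * numerator / denominator)
  out[!is.finite(out)] <- NA_real_
  out
}

# random DNA of length n as a character scalar
randomDna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute each base with a uniformly chosen different base
mutateBases <- function(bases) {
  idx <- match(bases, BASES)
  shift <- sample.int(3L, length(bases), replace = TRUE)
  BASES[((idx - 1L + shift) %% 4L) + 1L]
}

# apply uniform sequencing errors in place to a character vector of reads
addSequencingErrors <- function(seqs, errorRate) {
  if (errorRate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, errorRate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    p <- sample.int(lens[i], nerr[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    s[p] <- mutateBases(s[p])
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

subgenomeOf <- function(chrom) substr(chrom, 1L, 1L)

# genotype string helpers: unordered allele pair "A/G"
gtString <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

seqlengthsOf <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
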