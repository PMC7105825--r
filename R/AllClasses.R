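#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#' @useDynLib tetrasnp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration
#'
#' Holds every tunable of the synthetic allotetraploid world: genome geometry,
#' subgenome divergence, parental polymorphism rates, RIL breeding scheme,
#' sequencing platform read lengths and error rate, and the hybrid-capture
#' efficiency curve. Construct with [simConfig()].
#'
#' @slot nChromosomes integer, chromosomes per subgenome.
#' @slot chromosomeLength integer, length of each chromosome (bp).
#' @slot homoeologDivergence numeric, expected A-vs-B mismatch fraction.
#' @slot subgenomeSpecificFraction numeric, fraction of 10 kb windows whose B
#'   copy is unrelated sequence (presence/absence variation).
#' @slot allelicSnpDensity numeric, per-bp rate of parental differences.
#' @slot residualHetFraction numeric, fraction of parental SNP sites left
#'   heterozygous in one parent.
#' @slot selfingGenerations integer, generation of the shared RIL founder
#'   (6 = F6, i.e. F1 plus five selfings).
#' @slot crossoversPerChromosome numeric, expected crossovers per chromosome
#'   per meiosis (Poisson).
#' @slot nGenesPerChromosome integer; @slot geneLength integer (bp).
#' @slot readLengthTes,readLengthRnaseq,readLengthGbs integer read lengths.
#' @slot insertMin,insertMax integer, sequenced fragment size window (bp).
#' @slot sequencingErrorRate numeric, per-base substitution error rate.
#' @slot captureMidpoint,captureSteepness numeric, logistic capture-efficiency
#'   curve on probe-target identity.
#' @slot offTargetFraction numeric, fraction of capture fragments drawn
#'   uniformly from the genome instead of around probe targets.
#' @slot gbsSizeMin,gbsSizeMax integer, retained restriction fragment sizes.
#' @slot seed integer master seed.
#' @export
setClass("SimConfig", slots = c(
  nChromosomes = "integer", chromosomeLength = "integer",
  homoeologDivergence = "numeric", subgenomeSpecificFraction = "numeric",
  allelicSnpDensity = "numeric", residualHetFraction = "numeric",
  selfingGenerations = "integer", crossoversPerChromosome = "numeric",
  nGenesPerChromosome = "integer", geneLength = "integer",
  readLengthTes = "integer", readLengthRnaseq = "integer",
  readLengthGbs = "integer", insertMin = "integer", insertMax = "integer",
  sequencingErrorRate = "numeric", captureMidpoint = "numeric",
  captureSteepness = "numeric", offTargetFraction = "numeric",
  gbsSizeMin = "integer", gbsSizeMax = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(homoeologDivergence = object@homoeologDivergence,
             subgenomeSpecificFraction = object@subgenomeSpecificFraction,
             allelicSnpDensity = object@allelicSnpDensity,
             residualHetFraction = object@residualHetFraction,
             sequencingErrorRate = object@sequencingErrorRate,
             offTargetFraction = object@offTargetFraction)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    msg <- c(msg, paste0("rates must lie in [0,1]: ",
                         paste(names(rates)[bad], collapse = ", ")))
  lens <- c(object@nChromosomes, object@chromosomeLength, object@geneLength,
            object@readLengthTes, object@readLengthRnaseq, object@readLengthGbs,
            object@insertMin, object@insertMax)
  if (any(lens <= 0)) msg <- c(msg, "lengths and counts must be positive")
  if (object@insertMax < object@insertMin) msg <- c(msg, "insertMax < insertMin")
  if (object@selfingGenerations < 1L) msg <- c(msg, "selfingGenerations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated allotetraploid
#'
#' The two subgenome reference sequences plus full catalogs of what is known
#' by construction: homoeologous sites (fixed A-vs-B differences at alignable
#' positions), allelic sites (polymorphisms between the parental lines P1 and
#' P2, with per-haplotype alleles), gene models, and the subgenome-specific
#' (unalignable) windows.
#'
#' @slot genome DNAStringSet, chromosomes named `A01..`/`B01..`.
#' @slot homoeologSites data.frame: chromA, chromB, pos, alleleA, alleleB.
#' @slot allelicSites data.frame: chrom, pos, ref, alt, P1_1, P1_2, P2_1, P2_2.
#' @slot geneModels GRanges with gene_id, class, orthogroup, simRank,
#'   expressed, deg, nod metadata columns.
#' @slot specificRegions GRanges of subgenome-specific windows.
#' @slot config the SimConfig used.
#' @export
setClass("TetraploidTruth", slots = c(
  genome = "DNAStringSet", homoeologSites = "data.frame",
  allelicSites = "data.frame", geneModels = "GRanges",
  specificRegions = "GRanges", config = "SimConfig"))

setValidity("TetraploidTruth", function(object) {
  a <- object@allelicSites
  need <- c("chrom", "pos", "ref", "alt", "P1_1", "P1_2", "P2_1", "P2_2")
  if (!all(need %in% names(a)))
    return("allelicSites must carry per-haplotype parental alleles")
  if (nrow(a) && any(a$ref == a$alt))
    return("every allelic site must record exactly two distinct alleles")
  TRUE
})

#' A pair of near-isogenic sister RILs
#'
#' Two inbred sister lines descending from one shared selfed founder plant,
#' stored as per-chromosome mosaics of parental origin. `blocks` is the
#' genotype-level track (`P1`, `P2` or `HET`); `haplotypes` holds the two
#' origin tracks per line used to emit sequences; `founderBlocks` is the
#' shared founder's genotype track (its HET fraction is the residual
#' heterozygosity of the breeding scheme); `alleles` gives each line's two
#' haplotype alleles at every parental SNP site.
#'
#' @slot lines character(2), sample names (e.g. `c("E4","E5")`).
#' @slot blocks named list (per line) of GRanges with an `origin` column.
#' @slot haplotypes named list (per line) of 2-element lists of GRanges.
#' @slot founderBlocks GRanges with an `origin` column.
#' @slot alleles data.frame: chrom, pos plus `<line>_1`, `<line>_2` columns.
#' @export
setClass("RILPair", slots = c(
  lines = "character", blocks = "list", haplotypes = "list",
  founderBlocks = "GRanges", alleles = "data.frame"))

setValidity("RILPair", function(object) {
  if (length(object@lines) != 2L) return("a RILPair holds exactly two lines")
  if (!all(object@lines %in% names(object@blocks)))
    return("blocks must be named by line")
  for (ln in object@lines) {
    gr <- object@blocks[[ln]]
    for (ch in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
      g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == ch]
      g <- g[order(start(g))]
      if (length(g) && (start(g)[1] != 1L ||
          any(start(g)[-1] != end(g)[-length(g)] + 1L)))
        return("origin blocks must tile each chromosome without gaps/overlaps")
    }
  }
  TRUE
})

#' A simulated read set
#'
#' Reads from one platform for one or more samples, each tagged with its
#' emitting haplotype and true origin coordinate so that alignment and SNP
#' calls can be scored against truth.
#'
#' @slot platform one of `"tes"`, `"rnaseq"`, `"gbs"`.
#' @slot paired logical.
#' @slot reads DataFrame: id, sample, seq, mate, pairId, truthChrom,
#'   truthStart, truthStrand, hap.
#' @export
setClass("ReadSet", slots = c(platform = "character", paired = "logical",
                              reads = "DataFrame"))

setValidity("ReadSet", function(object) {
  if (!object@platform %in% c("tes", "rnaseq", "gbs"))
    return("platform must be tes, rnaseq or gbs")
  need <- c("id", "sample", "seq", "mate", "pairId",
            "truthChrom", "truthStart", "truthStrand", "hap")
  if (!all(need %in% colnames(object@reads)))
    return(paste("reads must carry columns:", paste(need, collapse = ", ")))
  TRUE
})

#' A selected capture probe panel
#'
#' @slot probes DNAStringSet of selected probes; mcols carry probe_id,
#'   source_gene, class and the selection reason (`class1_single`,
#'   `resistance_single`, `multi_hit_rescue`, `spacing`).
#' @slot counts named integer vector of per-reason totals.
#' @slot fragmentSize integer genome fragment size used by the spacing stage.
#' @export
setClass("PanelSelection", slots = c(probes = "DNAStringSet",
                                     counts = "integer",
                                     fragmentSize = "integer"))

#' A reproducibility manifest for a full workflow run
#'
#' @slot config list snapshot of the configuration.
#' @slot seed integer master seed.
#' @slot hashes named character, md5 of every file the run wrote.
#' @slot version package version string.
#' @export
setClass("RunManifest", slots = c(config = "list", seed = "integer",
                                  hashes = "character", version = "character"))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosome(s) x",
      object@chromosomeLength, "bp per subgenome\n")
  cat("  homoeolog divergence", object@homoeologDivergence,
      "| allelic SNP density", object@allelicSnpDensity,
      "| error rate", object@sequencingErrorRate, "\n")
  cat("  F", object@selfingGenerations, " founder, ",
      object@crossoversPerChromosome, " crossovers/chrom/meiosis, seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "TetraploidTruth", function(object) {
  cat("TetraploidTruth:", length(object@genome), "chromosomes (",
      sum(Biostrings::width(object@genome)), "bp )\n")
  cat(" ", nrow(object@homoeologSites), "homoeologous sites,",
      nrow(object@allelicSites), "allelic sites,",
      length(object@geneModels), "gene models\n")
})

setMethod("show", "RILPair", function(object) {
  cat("RILPair:", paste(object@lines, collapse = " & "), "\n")
  het <- residualHetFraction(object)
  cat("  founder residual heterozygosity:", signif(het, 4), "\n")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet:", nrow(object@reads), object@platform,
      if (object@paired) "paired-end" else "single-end", "reads,",
      length(unique(object@reads$sample)), "sample(s)\n")
})

setMethod("show", "PanelSelection", function(object) {
  cat("PanelSelection:", length(object@probes), "probes\n")
  print(object@counts)
})

setMethod("show", "RunManifest", function(object) {
  cat("RunManifest: seed", object@seed, "| tetrasnp", object@version, "|",
      length(object@hashes), "files hashed\n")
})

# ---- accessors ----

#' @describeIn TetraploidTruth-class subgenome A chromosomes.
#' @param object,x a TetraploidTruth (or RILPair for its accessors).
#' @export
genomeA <- function(x) x@genome[startsWith(names(x@genome), "A")]

#' @describeIn TetraploidTruth-class subgenome B chromosomes.
#' @export
genomeB <- function(x) x@genome[startsWith(names(x@genome), "B")]

#' @describeIn TetraploidTruth-class the full genome (both subgenomes).
#' @export
truthGenome <- function(x) x@genome

#' @describeIn TetraploidTruth-class catalog of fixed A-vs-B differences.
#' @export
homoeologSites <- function(x) x@homoeologSites

#' @describeIn TetraploidTruth-class catalog of parental polymorphisms.
#' @export
allelicSites <- function(x) x@allelicSites

#' @describeIn TetraploidTruth-class simulated gene models.
#' @export
geneModels <- function(x) x@geneModels

#' @describeIn RILPair-class genotype-level origin track of one line.
#' @param line line name; defaults to the first line of the pair.
#' @export
lineBlocks <- function(x, line = x@lines[1]) x@blocks[[line]]

#' Residual heterozygosity of the shared RIL founder
#'
#' Genome fraction of the founder plant's mosaic whose two haplotypes carry
#' different parental origins. For an F_g founder the Mendelian expectation
#' is `2^-(g-1)`.
#'
#' @param x a [RILPair-class].
#' @return numeric scalar in \[0, 1\].
#' @export
residualHetFraction <- function(x) {
  gr <- x@founderBlocks
  sum(width(gr)[gr$origin == "HET"]) / sum(width(gr))
}
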