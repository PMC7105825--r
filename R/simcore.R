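#' Build a simulation configuration
#'
#' Defaults describe the study system this package emulates: an allotetraploid
#' with two subgenomes whose overall identity is ~93% (divergence 0.07), two
#' homozygous-divergent parental lines, F6-derived near-isogenic sister RILs,
#' 100 bp paired target-enrichment reads, 150 bp paired RNA-seq reads, 64 bp
#' single-end GBS reads (ApeKI digest), and a logistic capture curve under
#' which targets at >= 75% identity are captured at >= 90% of maximal
#' efficiency.
#'
#' @param nChromosomes chromosomes per subgenome.
#' @param chromosomeLength chromosome length in bp.
#' @param homoeologDivergence expected A-vs-B mismatch fraction.
#' @param subgenomeSpecificFraction fraction of 10 kb windows whose B copy is
#'   unrelated sequence; capped at `homoeologDivergence/1.5` so the emitted
#'   divergence stays attainable (0 divergence implies identical subgenomes).
#' @param allelicSnpDensity per-bp rate of parental differences.
#' @param residualHetFraction fraction of parental SNP sites at which one
#'   parent is heterozygous.
#' @param selfingGenerations generation of the shared RIL founder (6 = F6).
#' @param crossoversPerChromosome expected crossovers per chromosome/meiosis.
#' @param nGenesPerChromosome,geneLength gene model placement.
#' @param readLengthTes,readLengthRnaseq,readLengthGbs platform read lengths.
#' @param insertMin,insertMax sequenced fragment size window (bp).
#' @param sequencingErrorRate per-base substitution error rate.
#' @param captureMidpoint,captureSteepness logistic capture curve parameters.
#' @param offTargetFraction fraction of capture fragments drawn genome-wide.
#' @param gbsSizeMin,gbsSizeMax retained restriction fragment size window.
#' @param seed master seed; a fixed seed makes every simulation output
#'   byte-identical across runs.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(chromosomeLength = 1e5, seed = 1)
#' @export
simConfig <- function(nChromosomes = 1L, chromosomeLength = 5e6L,
                      homoeologDivergence = 0.07,
                      subgenomeSpecificFraction = 0.05,
                      allelicSnpDensity = 0.002, residualHetFraction = 0.02,
                      selfingGenerations = 6L, crossoversPerChromosome = 2,
                      nGenesPerChromosome = 60L, geneLength = 1200L,
                      readLengthTes = 100L, readLengthRnaseq = 150L,
                      readLengthGbs = 64L, insertMin = 200L, insertMax = 500L,
                      sequencingErrorRate = 0.001, captureMidpoint = 0.62,
                      captureSteepness = 40, offTargetFraction = 0.3,
                      gbsSizeMin = 80L, gbsSizeMax = 400L, seed = 1L) {
  methods::new("SimConfig",
    nChromosomes = as.integer(nChromosomes),
    chromosomeLength = as.integer(chromosomeLength),
    homoeologDivergence = homoeologDivergence,
    subgenomeSpecificFraction = min(subgenomeSpecificFraction,
                                    homoeologDivergence / 1.5),
    allelicSnpDensity = allelicSnpDensity,
    residualHetFraction = residualHetFraction,
    selfingGenerations = as.integer(selfingGenerations),
    crossoversPerChromosome = crossoversPerChromosome,
    nGenesPerChromosome = as.integer(nGenesPerChromosome),
    geneLength = as.integer(geneLength),
    readLengthTes = as.integer(readLengthTes),
    readLengthRnaseq = as.integer(readLengthRnaseq),
    readLengthGbs = as.integer(readLengthGbs),
    insertMin = as.integer(insertMin), insertMax = as.integer(insertMax),
    sequencingErrorRate = sequencingErrorRate,
    captureMidpoint = captureMidpoint, captureSteepness = captureSteepness,
    offTargetFraction = offTargetFraction,
    gbsSizeMin = as.integer(gbsSizeMin), gbsSizeMax = as.integer(gbsSizeMax),
    seed = as.integer(seed))
}

WINDOW_SIZE <- 5000L

#' Simulate an allotetraploid genome with known ground truth
#'
#' Generates subgenome A de novo and derives subgenome B from it: a small
#' fraction of 10 kb windows is replaced by unrelated sequence
#' (subgenome-specific content), the remaining alignable positions are
#' substituted at a rate calibrated so the emitted A-vs-B mismatch fraction
#' equals `homoeologDivergence` in expectation. Substituted alignable
#' positions form the homoeologous-site catalog. Parental allelic SNPs are
#' then drawn per chromosome at `allelicSnpDensity`, each recording exactly
#' two alleles and the four parental haplotype alleles. Gene models are placed
#' non-overlapping on both subgenomes with class labels (`class1` =
#' nodulation-related/differentially expressed, `class2` = ordinary,
#' `resistance`), orthogroup membership with a similarity rank, and
#' expression flags.
#'
#' A position may be both homoeologous and allelic; both catalog entries are
#' kept.
#'
#' @param config a [SimConfig-class].
#' @return a [TetraploidTruth-class].
#' @export
simulateTetraploid <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  L <- config@chromosomeLength
  nchr <- config@nChromosomes
  if (config@nGenesPerChromosome * (config@geneLength + 200L) > L)
    stop("chromosome_length too small to place the requested gene models")

  f <- config@subgenomeSpecificFraction
  d <- config@homoeologDivergence
  # calibrate alignable substitution rate: f*0.75 + (1-f)*r = d
  r <- if (f < 1) (d - 0.75 * f) / (1 - f) else 0
  stopifnot(r >= 0, r <= 1)

  chromsA <- chromsB <- character(nchr)
  homo <- vector("list", nchr)
  specific <- vector("list", nchr)

  for (i in seq_len(nchr)) {
    a <- randomDna(L)
    b <- strsplit(a, "", fixed = TRUE)[[1]]
    nwin <- max(1L, L %/% WINDOW_SIZE)
    nspec <- round(f * nwin)
    alignable <- rep(TRUE, L)
    if (nspec > 0) {
      wspec <- sample.int(nwin, nspec)
      for (w in wspec) {
        from <- (w - 1L) * WINDOW_SIZE + 1L
        to <- min(w * WINDOW_SIZE, L)
        b[from:to] <- sample(BASES, to - from + 1L, replace = TRUE)
        alignable[from:to] <- FALSE
      }
      sp <- sort(wspec)
      specific[[i]] <- data.table(
        chrom = i, start = (sp - 1L) * WINDOW_SIZE + 1L,
        end = pmin(sp * WINDOW_SIZE, L))
    }
    idx <- which(alignable & stats::runif(L) < r)
    if (length(idx)) {
      old <- b[idx]
      b[idx] <- mutateBases(old)
      homo[[i]] <- data.table(chrom = i, pos = idx, alleleA = old,
                              alleleB = b[idx])
    }
    chromsA[i] <- a
    chromsB[i] <- paste(b, collapse = "")
  }

  chromNames <- c(sprintf("A%02d", seq_len(nchr)), sprintf("B%02d", seq_len(nchr)))
  genome <- Biostrings::DNAStringSet(c(chromsA, chromsB))
  names(genome) <- chromNames

  homoDt <- rbindlist(homo)
  if (nrow(homoDt)) {
    homoSites <- data.frame(chromA = sprintf("A%02d", homoDt$chrom),
                            chromB = sprintf("B%02d", homoDt$chrom),
                            pos = homoDt$pos, alleleA = homoDt$alleleA,
                            alleleB = homoDt$alleleB,
                            stringsAsFactors = FALSE)
  } else {
    homoSites <- data.frame(chromA = character(), chromB = character(),
                            pos = integer(), alleleA = character(),
                            alleleB = character(), stringsAsFactors = FALSE)
  }

  specDt <- rbindlist(specific)
  if (nrow(specDt)) {
    specGr <- GRanges(
      rep(c(sprintf("A%02d", specDt$chrom), sprintf("B%02d", specDt$chrom))),
      IRanges(rep(specDt$start, 2), rep(specDt$end, 2)))
  } else specGr <- GRanges()

  # parental allelic SNPs on every chromosome of both subgenomes
  allelic <- vector("list", length(chromNames))
  for (ci in seq_along(chromNames)) {
    s <- as.character(genome[[ci]])
    idx <- which(stats::runif(L) < config@allelicSnpDensity)
    if (!length(idx)) next
    ref <- strsplit(s, "", fixed = TRUE)[[1]][idx]
    altA <- mutateBases(ref)
    n <- length(idx)
    p1alt <- stats::runif(n) < 0.5        # which parent carries the alt allele
    isHet <- stats::runif(n) < config@residualHetFraction
    hetFirst <- stats::runif(n) < 0.5
    P1_1 <- ifelse(p1alt, altA, ref); P1_2 <- P1_1
    P2_1 <- ifelse(p1alt, ref, altA); P2_2 <- P2_1
    # at residual-het sites the alt-carrying parent is heterozygous
    P1h <- isHet & p1alt; P2h <- isHet & !p1alt
    P1_1[P1h] <- ifelse(hetFirst[P1h], altA[P1h], ref[P1h])
    P1_2[P1h] <- ifelse(hetFirst[P1h], ref[P1h], altA[P1h])
    P2_1[P2h] <- ifelse(hetFirst[P2h], altA[P2h], ref[P2h])
    P2_2[P2h] <- ifelse(hetFirst[P2h], ref[P2h], altA[P2h])
    allelic[[ci]] <- data.table(chrom = chromNames[ci], pos = idx, ref = ref,
                                alt = altA, P1_1 = P1_1, P1_2 = P1_2,
                                P2_1 = P2_1, P2_2 = P2_2)
  }
  allelicDt <- rbindlist(allelic)
  if (!nrow(allelicDt))
    allelicDt <- data.table(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            P1_1 = character(), P1_2 = character(),
                            P2_1 = character(), P2_2 = character())

  genes <- placeGeneModels(config, chromNames, L)

  methods::new("TetraploidTruth", genome = genome, homoeologSites = homoSites,
               allelicSites = as.data.frame(allelicDt), geneModels = genes,
               specificRegions = specGr, config = config)
}

# non-overlapping gene placement with class labels, orthogroups and
# expression/DEG/nodulation flags
placeGeneModels <- function(config, chromNames, L) {
  ng <- config@nGenesPerChromosome
  gl <- config@geneLength
  bin <- L %/% ng
  if (bin <= gl) stop("chromosome_length too small to place the requested gene models")
  rows <- list()
  for (ci in seq_along(chromNames)) {
    offs <- (seq_len(ng) - 1L) * bin
    starts <- offs + sample.int(bin - gl, ng, replace = TRUE)
    cls <- sample(c("class1", "class2", "resistance"), ng, replace = TRUE,
                  prob = c(0.25, 0.65, 0.10))
    rows[[ci]] <- data.table(chrom = chromNames[ci], start = starts,
                             end = starts + gl - 1L, class = cls)
  }
  dt <- rbindlist(rows)
  dt[, gene_id := sprintf("gene%05d", seq_len(nrow(dt)))]
  # orthogroups among class1 genes, sizes 1..6, ranks by simulated similarity
  i1 <- which(dt$class == "class1")
  og <- integer(nrow(dt)); rk <- integer(nrow(dt))
  gid <- 0L; i <- 1L
  while (i <= length(i1)) {
    gid <- gid + 1L
    size <- sample.int(6L, 1L)
    take <- i1[i:min(i + size - 1L, length(i1))]
    og[take] <- gid
    rk[take] <- sample(seq_along(take))
    i <- i + size
  }
  dt[, `:=`(orthogroup = og, simRank = rk)]
  isC1 <- dt$class == "class1"
  deg <- ifelse(isC1, stats::runif(nrow(dt)) < 0.5, stats::runif(nrow(dt)) < 0.05)
  nod <- isC1 & stats::runif(nrow(dt)) < 0.5
  # class1 genes are nodulation-related orthologs and/or DEGs by construction
  deg[isC1 & !nod & !deg] <- TRUE
  expressed <- deg | stats::runif(nrow(dt)) < 0.4
  gr <- GRanges(dt$chrom, IRanges(dt$start, dt$end),
                gene_id = dt$gene_id, class = dt$class,
                orthogroup = dt$orthogroup, simRank = dt$simRank,
                expressed = expressed, deg = deg, nod = nod)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(rep(L, length(chromNames)),
                                                  chromNames)
  gr
}

# ---- RIL breeding -----------------------------------------------------------

mergeAdjacentTrack <- function(dt) {
  if (nrow(dt) <= 1L) return(dt)
  keepRow <- c(TRUE, dt$origin[-1] != dt$origin[-nrow(dt)])
  grpId <- cumsum(keepRow)
  dt[, .(start = min(start_), end = max(end_), origin = origin[1]),
     by = .(g = grpId)][, .(start_ = start, end_ = end, origin)]
}

# one gamete from a plant's two haplotype tracks on one chromosome
gameteChrom <- function(h1, h2, L, lambda) {
  nco <- stats::rpois(1L, lambda)
  cuts <- if (nco > 0L) sort(sample.int(L - 1L, min(nco, L - 1L))) else integer()
  bounds <- c(0L, cuts, L)
  first <- sample.int(2L, 1L)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    from <- bounds[i] + 1L; to <- bounds[i + 1L]
    h <- if ((first + i) %% 2L == 0L) h1 else h2
    sel <- h[h$end_ >= from & h$start_ <= to, ]
    pieces[[i]] <- data.table(start_ = pmax(sel$start_, from),
                              end_ = pmin(sel$end_, to), origin = sel$origin)
  }
  mergeAdjacentTrack(rbindlist(pieces))
}

selfPlant <- function(plant, L, lambda) {
  lapply(plant, function(chr)
    list(h1 = gameteChrom(chr$h1, chr$h2, L, lambda),
         h2 = gameteChrom(chr$h1, chr$h2, L, lambda)))
}

# genotype-level overlay of the two haplotype origin tracks
genotypeTrackChrom <- function(h1, h2) {
  bp <- sort(unique(c(h1$start_, h1$end_ + 1L, h2$start_, h2$end_ + 1L)))
  starts <- bp[-length(bp)]; ends <- bp[-1] - 1L
  o1 <- h1$origin[findInterval(starts, h1$start_)]
  o2 <- h2$origin[findInterval(starts, h2$start_)]
  dt <- data.table(start_ = starts, end_ = ends,
                   origin = fifelse(o1 == o2, o1, "HET"))
  mergeAdjacentTrack(dt)
}

trackToGRanges <- function(plantTracks, chromNames) {
  rows <- rbindlist(lapply(seq_along(plantTracks), function(i)
    cbind(chrom = chromNames[i], plantTracks[[i]])))
  GRanges(rows$chrom, IRanges(rows$start_, rows$end_), origin = rows$origin)
}

#' Simulate a pair of near-isogenic sister RILs
#'
#' Models the breeding scheme behind near-isogenic sister lines: an F1 between
#' the two homozygous-divergent parents is selfed for
#' `selfingGenerations - 1` rounds (Poisson crossovers per chromosome per
#' meiosis) to yield a shared founder plant; each sister is then one further
#' independent selfing of that founder. The founder's expected heterozygous
#' genome fraction is `2^-(generations-1)`. Parental haplotype alleles are
#' propagated through the pedigree so that each sister's two haplotypes carry
#' concrete alleles at every parental SNP site.
#'
#' @param truth a [TetraploidTruth-class] (allelic sites must exist).
#' @param config the [SimConfig-class] used for the truth.
#' @param lines character(2) sample names for the sisters.
#' @param seed seed for this pedigree (keep distinct per pair).
#' @return a [RILPair-class].
#' @export
simulateRilPair <- function(truth, config, lines = c("E4", "E5"),
                            seed = config@seed + 1L) {
  if (!nrow(truth@allelicSites)) stop("truth contains no allelic sites")
  set.seed(seed)
  chromNames <- names(truth@genome)
  L <- config@chromosomeLength
  lambda <- config@crossoversPerChromosome

  f1 <- lapply(chromNames, function(ch) list(
    h1 = data.table(start_ = 1L, end_ = L, origin = "P1"),
    h2 = data.table(start_ = 1L, end_ = L, origin = "P2")))
  plant <- f1
  g <- config@selfingGenerations
  if (g >= 2L) for (k in seq_len(g - 1L)) plant <- selfPlant(plant, L, lambda)

  founderTrack <- lapply(plant, function(chr) genotypeTrackChrom(chr$h1, chr$h2))
  sisters <- list(selfPlant(plant, L, lambda), selfPlant(plant, L, lambda))
  names(sisters) <- lines

  blocks <- list(); haplos <- list()
  for (ln in lines) {
    pl <- sisters[[ln]]
    blocks[[ln]] <- trackToGRanges(
      lapply(pl, function(chr) genotypeTrackChrom(chr$h1, chr$h2)), chromNames)
    haplos[[ln]] <- list(
      trackToGRanges(lapply(pl, function(chr) chr$h1), chromNames),
      trackToGRanges(lapply(pl, function(chr) chr$h2), chromNames))
  }

  # transmitted parental gamete alleles (resolves residual parental hets)
  sites <- as.data.table(truth@allelicSites)
  p1t <- fifelse(sites$P1_1 == sites$P1_2, sites$P1_1,
                 fifelse(stats::runif(nrow(sites)) < 0.5, sites$P1_1, sites$P1_2))
  p2t <- fifelse(sites$P2_1 == sites$P2_2, sites$P2_1,
                 fifelse(stats::runif(nrow(sites)) < 0.5, sites$P2_1, sites$P2_2))
  alleles <- data.table(chrom = sites$chrom, pos = sites$pos)
  for (ln in lines) {
    for (hi in 1:2) {
      hgr <- haplos[[ln]][[hi]]
      org <- originAt(hgr, sites$chrom, sites$pos)
      alleles[[paste0(ln, "_", hi)]] <- fifelse(org == "P1", p1t, p2t)
    }
  }

  methods::new("RILPair", lines = lines, blocks = blocks, haplotypes = haplos,
               founderBlocks = trackToGRanges(founderTrack, chromNames),
               alleles = as.data.frame(alleles))
}

# origin label of a (chrom, pos) vector in an origin track
originAt <- function(trackGr, chrom, pos) {
  out <- character(length(chrom))
  tchr <- as.character(GenomeInfoDb::seqnames(trackGr))
  for (ch in unique(chrom)) {
    g <- trackGr[tchr == ch]
    g <- g[order(start(g))]
    sel <- chrom == ch
    out[sel] <- g$origin[findInterval(pos[sel], start(g))]
  }
  out
}

#' Intervals where the two sister RILs differ in parental origin
#'
#' @param pair a [RILPair-class].
#' @param homOnly if `TRUE` (default) report only intervals where both sisters
#'   are homozygous for opposite parental origins; otherwise any label
#'   difference (including HET mismatches) qualifies.
#' @return GRanges with `originA`/`originB` columns (one per sister).
#' @export
truthPolymorphicBlocks <- function(pair, homOnly = TRUE) {
  a <- pair@blocks[[pair@lines[1]]]
  b <- pair@blocks[[pair@lines[2]]]
  rows <- list()
  achr <- as.character(GenomeInfoDb::seqnames(a))
  bchr <- as.character(GenomeInfoDb::seqnames(b))
  for (ch in unique(achr)) {
    ga <- a[achr == ch]; gb <- b[bchr == ch]
    ga <- ga[order(start(ga))]; gb <- gb[order(start(gb))]
    bp <- sort(unique(c(start(ga), end(ga) + 1L, start(gb), end(gb) + 1L)))
    s <- bp[-length(bp)]; e <- bp[-1] - 1L
    oa <- ga$origin[findInterval(s, start(ga))]
    ob <- gb$origin[findInterval(s, start(gb))]
    diff <- if (homOnly) (oa != ob & oa != "HET" & ob != "HET") else oa != ob
    if (any(diff))
      rows[[ch]] <- data.table(chrom = ch, start_ = s[diff], end_ = e[diff],
                               oa = oa[diff], ob = ob[diff])
  }
  dt <- rbindlist(rows)
  if (!nrow(dt)) return(GRanges())
  # merge adjacent intervals with identical label pairs
  dt[, block := cumsum(c(TRUE, !(chrom[-1] == chrom[-.N] &
                                 start_[-1] == end_[-.N] + 1L &
                                 oa[-1] == oa[-.N] & ob[-1] == ob[-.N])))]
  m <- dt[, .(chrom = chrom[1], start_ = min(start_), end_ = max(end_),
              oa = oa[1], ob = ob[1]), by = block]
  GRanges(m$chrom, IRanges(m$start_, m$end_), originA = m$oa, originB = m$ob)
}

# ---- sample haplotype sequences --------------------------------------------

# two full haplotype DNAStringSets for a sample; parents come from the truth
# catalog, RIL lines from their pair's mosaic alleles
haplotypeSequences <- function(truth, sample, pairs = list()) {
  sites <- as.data.table(truth@allelicSites)
  makeHap <- function(alleleCol) {
    g <- truth@genome
    for (ch in unique(sites$chrom)) {
      sel <- sites[chrom == ch & get(alleleCol) != ref]
      if (!nrow(sel)) next
      g[[ch]] <- Biostrings::replaceLetterAt(
        g[[ch]], sel$pos, paste(sel[[alleleCol]], collapse = ""))
    }
    g
  }
  if (sample %in% c("P1", "P2")) {
    cols <- paste0(sample, "_", 1:2)
    return(list(makeHap(cols[1]), makeHap(cols[2])))
  }
  for (pr in pairs) {
    if (sample %in% pr@lines) {
      al <- as.data.table(pr@alleles)
      stopifnot(nrow(al) == nrow(sites))
      sites2 <- copy(sites)
      sites2[[paste0(sample, "_1")]] <- al[[paste0(sample, "_1")]]
      sites2[[paste0(sample, "_2")]] <- al[[paste0(sample, "_2")]]
      sites <- sites2
      cols <- paste0(sample, "_", 1:2)
      return(list(makeHap(cols[1]), makeHap(cols[2])))
    }
  }
  stop("unknown sample: ", sample)
}

#' Genotype strings of a sample at the parental SNP sites
#'
#' @param truth a [TetraploidTruth-class].
#' @param sample `"P1"`, `"P2"` or a RIL line name present in `pairs`.
#' @param pairs list of [RILPair-class] objects for RIL samples.
#' @return character vector of unordered allele pairs (e.g. `"A/G"`) aligned
#'   with `allelicSites(truth)` rows.
#' @export
lineGenotypes <- function(truth, sample, pairs = list()) {
  sites <- truth@allelicSites
  if (sample %in% c("P1", "P2"))
    return(gtString(sites[[paste0(sample, "_1")]], sites[[paste0(sample, "_2")]]))
  for (pr in pairs) {
    if (sample %in% pr@lines) {
      al <- pr@alleles
      return(gtString(al[[paste0(sample, "_1")]], al[[paste0(sample, "_2")]]))
    }
  }
  stop("unknown sample: ", sample)
}

# ---- read simulation --------------------------------------------------------

emptyReads <- function() DataFrame(
  id = character(), sample = character(), seq = character(), mate = integer(),
  pairId = character(), truthChrom = character(), truthStart = integer(),
  truthStrand = character(), hap = integer())

#' Simulate platform reads with truth tags
#'
#' Emits reads for one or more samples on one platform. Target-enrichment
#' (`tes`): paired fragments drawn around probe target loci with capture
#' probability given by the configured logistic on probe-target identity,
#' plus a genome-wide off-target fraction. RNA-seq: paired fragments from
#' expressed gene models only (genes are unspliced). GBS: in-silico ApeKI
#' digest (recognition `GCWGC`, cut after the first base), fragments kept in
#' a size window, a single 64 bp read from a random fragment end. All
#' platforms substitute uniform sequencing errors at the configured rate;
#' with an error rate of zero every read is an exact substring of its
#' emitting haplotype, and its truth tag relocates it there.
#'
#' @param truth a [TetraploidTruth-class].
#' @param samples character vector of sample names.
#' @param platform `"tes"`, `"rnaseq"` or `"gbs"`.
#' @param config the [SimConfig-class].
#' @param depth target mean read depth over the platform's accessible space
#'   (per-fragment read count for GBS).
#' @param seed seed for read generation.
#' @param pairs list of [RILPair-class] objects resolving RIL sample names.
#' @param targets for `tes`: GRanges of probe hits carrying a
#'   `percentIdentity` metadata column (from [mapProbes()]).
#' @return a [ReadSet-class].
#' @export
simulateReads <- function(truth, samples, platform = c("tes", "rnaseq", "gbs"),
                          config, depth = 30, seed = config@seed + 100L,
                          pairs = list(), targets = NULL) {
  platform <- match.arg(platform)
  if (platform == "tes" && is.null(targets))
    stop("platform 'tes' requires a probe target set")
  set.seed(seed)
  paired <- platform %in% c("tes", "rnaseq")
  all <- list()
  for (smp in samples) {
    haps <- haplotypeSequences(truth, smp, pairs)
    hapChars <- lapply(haps, function(h)
      stats::setNames(as.character(h), names(h)))
    rows <- switch(platform,
      tes = simulateCaptureReads(hapChars, smp, config, depth, targets,
                                 config@readLengthTes, "tes"),
      rnaseq = simulateCaptureReads(hapChars, smp, config, depth,
                                    expressedTargets(truth),
                                    config@readLengthRnaseq, "rnaseq"),
      gbs = simulateGbsReads(hapChars, smp, config, depth))
    all[[smp]] <- rows
  }
  reads <- rbindlist(all)
  if (!nrow(reads)) {
    warning("no reads generated (empty digest or no accessible targets)")
    return(methods::new("ReadSet", platform = platform, paired = paired,
                        reads = emptyReads()))
  }
  reads[, seq_ := addSequencingErrors(seq_, config@sequencingErrorRate)]
  df <- DataFrame(id = reads$id, sample = reads$sample, seq = reads$seq_,
                  mate = reads$mate, pairId = reads$pairId,
                  truthChrom = reads$truthChrom, truthStart = reads$truthStart,
                  truthStrand = reads$truthStrand, hap = reads$hap)
  methods::new("ReadSet", platform = platform, paired = paired, reads = df)
}

expressedTargets <- function(truth) {
  gm <- truth@geneModels
  gr <- gm[mcols(gm)$expressed]
  mcols(gr)$percentIdentity <- 1
  gr
}

# paired fragments around weighted target loci (capture and RNA-seq share it)
simulateCaptureReads <- function(hapChars, smp, config, depth, targets, rl,
                                 tag) {
  if (!length(targets)) {
    warning("no accessible targets for sample ", smp)
    return(data.table())
  }
  ident <- mcols(targets)$percentIdentity
  if (is.null(ident)) ident <- rep(1, length(targets))
  w <- captureProbability(ident, config)
  ext <- 100L
  tchr <- as.character(GenomeInfoDb::seqnames(targets))
  tstart <- pmax(1L, start(targets) - ext)
  chromLens <- vapply(hapChars[[1]], nchar, integer(1))
  tend <- pmin(end(targets) + ext, chromLens[tchr])
  accessible <- sum(GenomicRanges::width(GenomicRanges::reduce(
    GRanges(tchr, IRanges(tstart, tend)))))
  nOn <- max(1L, round(depth * accessible / (2 * rl)))
  offFrac <- if (tag == "tes") config@offTargetFraction else 0
  nOff <- round(nOn * offFrac / (1 - offFrac))

  pickT <- sample.int(length(targets), nOn, replace = TRUE, prob = w)
  fl <- pmax(rl, sample(config@insertMin:config@insertMax, nOn + nOff,
                        replace = TRUE))
  centers <- tstart[pickT] +
    floor(stats::runif(nOn) * (tend[pickT] - tstart[pickT] + 1L))
  chrom <- tchr[pickT]
  if (nOff > 0) {
    offChrom <- sample(names(chromLens), nOff, replace = TRUE)
    offCenter <- floor(stats::runif(nOff) * chromLens[offChrom]) + 1L
    chrom <- c(chrom, offChrom)
    centers <- c(centers, offCenter)
  }
  n <- nOn + nOff
  startF <- centers - fl %/% 2L
  startF <- pmax(1L, pmin(startF, chromLens[chrom] - fl + 1L))
  endF <- startF + fl - 1L
  hap <- sample.int(2L, n, replace = TRUE)
  fragStrand <- sample(c("+", "-"), n, replace = TRUE)

  frag <- character(n)
  for (h in 1:2) {
    sel <- hap == h
    if (!any(sel)) next
    for (ch in unique(chrom[sel])) {
      s2 <- sel & chrom == ch
      frag[s2] <- substring(hapChars[[h]][[ch]], startF[s2], endF[s2])
    }
  }
  leftSeq <- substr(frag, 1L, rl)
  rightSeq <- revCompChar(substring(frag, fl - rl + 1L, fl))
  r1seq <- fifelse(fragStrand == "+", leftSeq, rightSeq)
  r2seq <- fifelse(fragStrand == "+", rightSeq, leftSeq)
  r1start <- fifelse(fragStrand == "+", startF, endF - rl + 1L)
  r2start <- fifelse(fragStrand == "+", endF - rl + 1L, startF)
  r1strand <- fifelse(fragStrand == "+", "+", "-")
  r2strand <- fifelse(fragStrand == "+", "-", "+")
  pid <- sprintf("%s_%s_f%07d", smp, tag, seq_len(n))
  rbindlist(list(
    data.table(id = paste0(pid, "/1"), sample = smp, seq_ = r1seq, mate = 1L,
               pairId = pid, truthChrom = chrom, truthStart = as.integer(r1start),
               truthStrand = r1strand, hap = hap),
    data.table(id = paste0(pid, "/2"), sample = smp, seq_ = r2seq, mate = 2L,
               pairId = pid, truthChrom = chrom, truthStart = as.integer(r2start),
               truthStrand = r2strand, hap = hap)))
}

simulateGbsReads <- function(hapChars, smp, config, depth) {
  rl <- config@readLengthGbs
  frags <- list()
  for (h in 1:2) {
    for (ch in names(hapChars[[h]])) {
      s <- hapChars[[h]][[ch]]
      cutG <- cpp_motif_positions(s, "GCWGC")   # cut after the leading G
      if (!length(cutG)) next
      bounds <- c(cutG, nchar(s))               # fragment starts at cut+1
      fs <- c(cutG + 1L)
      fe <- c(cutG[-1L], nchar(s))
      keepF <- (fe - fs + 1L) >= max(rl, config@gbsSizeMin) &
               (fe - fs + 1L) <= config@gbsSizeMax
      if (!any(keepF)) next
      frags[[paste(h, ch)]] <- data.table(hap = h, chrom = ch,
                                          start_ = fs[keepF], end_ = fe[keepF])
    }
  }
  fdt <- rbindlist(frags)
  if (!nrow(fdt)) return(data.table())
  nReads <- max(1L, round(depth * nrow(fdt) / 2))  # two haplotypes
  pick <- sample.int(nrow(fdt), nReads, replace = TRUE)
  strand <- sample(c("+", "-"), nReads, replace = TRUE)
  f <- fdt[pick]
  seqs <- character(nReads)
  starts <- integer(nReads)
  for (h in 1:2) {
    for (ch in unique(f$chrom[f$hap == h])) {
      sel <- f$hap == h & f$chrom == ch
      full <- substring(hapChars[[h]][[ch]], f$start_[sel], f$end_[sel])
      fw <- substr(full, 1L, rl)
      rv <- substr(revCompChar(full), 1L, rl)
      seqs[sel] <- ifelse(strand[sel] == "+", fw, rv)
      starts[sel] <- ifelse(strand[sel] == "+", f$start_[sel],
                            f$end_[sel] - rl + 1L)
    }
  }
  data.table(id = sprintf("%s_gbs_r%07d", smp, seq_len(nReads)), sample = smp,
             seq_ = seqs, mate = 0L,
             pairId = sprintf("%s_gbs_r%07d", smp, seq_len(nReads)),
             truthChrom = f$chrom, truthStart = starts, truthStrand = strand,
             hap = f$hap)
}

# ---- array simulation -------------------------------------------------------

#' Simulate an SNP-array genotype table
#'
#' Samples markers from the known allelic sites and, mirroring the
#' homoeolog-confounded probes of real allotetraploid arrays, makes a
#' fraction of markers behave as heterozygous in every sample (their two
#' "alleles" are the subgenome alleles). Genotypes are miscalled at
#' `errorRate` by swapping to a random different genotype.
#'
#' @param truth a [TetraploidTruth-class].
#' @param pairs list of [RILPair-class]; their lines are genotyped alongside
#'   P1 and P2.
#' @param nMarkers number of markers; must not exceed the number of available
#'   allelic plus homoeologous sites.
#' @param errorRate per-genotype miscall rate.
#' @param seed seed.
#' @param confoundedFraction fraction of markers drawn from homoeologous sites.
#' @return data.frame: marker_id, chrom, pos, alleles, confounded flag and one
#'   genotype column per sample (`"A/G"` style, unordered).
#' @export
simulateArray <- function(truth, pairs = list(), nMarkers, errorRate = 0.01,
                          seed = truth@config@seed + 200L,
                          confoundedFraction = 0.1) {
  set.seed(seed)
  samples <- c("P1", "P2", unlist(lapply(pairs, function(p) p@lines)))
  sites <- truth@allelicSites
  homo <- truth@homoeologSites
  if (nMarkers > nrow(sites) + nrow(homo))
    stop("n_markers exceeds the number of available sites")
  if (nMarkers == 0L) {
    out <- data.frame(marker_id = character(), chrom = character(),
                      pos = integer(), alleles = character(),
                      confounded = logical())
    for (s in samples) out[[s]] <- character()
    return(out)
  }
  nConf <- min(round(confoundedFraction * nMarkers), nrow(homo))
  nAll <- nMarkers - nConf
  if (nAll > nrow(sites)) stop("n_markers exceeds the number of allelic sites")

  ai <- sort(sample.int(nrow(sites), nAll))
  rows <- data.frame(marker_id = sprintf("AX%06d", seq_len(nAll)),
                     chrom = sites$chrom[ai], pos = sites$pos[ai],
                     alleles = paste(sites$ref[ai], sites$alt[ai], sep = "/"),
                     confounded = FALSE, stringsAsFactors = FALSE)
  gts <- lapply(samples, function(s) lineGenotypes(truth, s, pairs)[ai])
  names(gts) <- samples
  for (s in samples) rows[[s]] <- gts[[s]]

  if (nConf > 0L) {
    hi <- sort(sample.int(nrow(homo), nConf))
    conf <- data.frame(marker_id = sprintf("AXH%05d", seq_len(nConf)),
                       chrom = homo$chromA[hi], pos = homo$pos[hi],
                       alleles = paste(homo$alleleA[hi], homo$alleleB[hi],
                                       sep = "/"),
                       confounded = TRUE, stringsAsFactors = FALSE)
    for (s in samples)
      conf[[s]] <- gtString(homo$alleleA[hi], homo$alleleB[hi])
    rows <- rbind(rows, conf)
  }

  # uniform miscalls: replace with a random different genotype on the marker's
  # two alleles
  if (errorRate > 0) {
    al <- strsplit(rows$alleles, "/", fixed = TRUE)
    for (s in samples) {
      hit <- which(stats::runif(nrow(rows)) < errorRate)
      for (i in hit) {
        opts <- c(gtString(al[[i]][1], al[[i]][1]),
                  gtString(al[[i]][1], al[[i]][2]),
                  gtString(al[[i]][2], al[[i]][2]))
        opts <- setdiff(opts, rows[[s]][i])
        rows[[s]][i] <- sample(opts, 1L)
      }
    }
  }
  rows[order(rows$chrom, rows$pos), , drop = FALSE]
}
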