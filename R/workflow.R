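#' Run the complete synthetic-cohort workflow
#'
#' End-to-end reproduction on a simulated cohort of six samples -- the two
#' parents (P1, P2) and two pairs of near-isogenic sister RILs (E4 & E5,
#' E6 & E7): simulate the allotetraploid truth, design and select a capture
#' probe panel, emit platform read sets, run the five SNP pipelines, compute
#' identity-stratified capture metrics, validate against a simulated array,
#' and build graphical-genotype maps of the RIL-polymorphic regions. Every
#' stage derives its seed from the master seed, so a fixed seed reproduces
#' byte-identical outputs and an identical manifest.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param platforms platforms to sequence and call SNPs on.
#' @param pipelines pipeline ids to run on each platform.
#' @param depth sequencing depth per platform.
#' @param nMarkers array marker count (capped at the available sites).
#' @param mergeDistance region merge distance in bp for graphical maps.
#' @param writeReads also write FASTQ files (off by default: bulky).
#' @return a [RunManifest-class]; outputs land in `outDir`.
#' @export
runAll <- function(config, outDir, platforms = c("tes", "rnaseq", "gbs"),
                   pipelines = c("M1", "M2", "M3", "M4", "M5"),
                   depth = 30, nMarkers = 2000L, mergeDistance = 1e6,
                   writeReads = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@seed
  files <- character()
  keep <- function(f) files <<- c(files, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- stage("simulate", simulateTetraploid(config))
  pairs <- stage("ril", list(
    simulateRilPair(truth, config, c("E4", "E5"), seed = childSeed(seed, 1L)),
    simulateRilPair(truth, config, c("E6", "E7"), seed = childSeed(seed, 2L))))
  samples <- c("P1", "P2", "E4", "E5", "E6", "E7")

  keep(exportFasta(truth@genome, file.path(outDir, "genome.fasta")))
  keep(exportTsv(as.data.frame(truth@geneModels),
                 file.path(outDir, "gene_models.tsv")))

  panel <- stage("probes", {
    set.seed(childSeed(seed, 3L))
    probes <- tileProbes(truth@geneModels, truth@genome)
    probes <- deduplicateProbes(probes)
    hits <- mapProbes(probes, truth@genome)
    selectPanel(probes, hits, truth@genome)
  })
  panelHits <- stage("panel-hits", mapProbes(panel@probes, truth@genome))
  keep(exportFasta(panel@probes, file.path(outDir, "panel.fasta")))
  keep(exportTsv(as.data.frame(mcols(panel@probes)),
                 file.path(outDir, "panel.tsv")))
  keep(exportBed(panelHits, file.path(outDir, "panel_hits.bed")))

  reads <- list()
  for (pf in platforms) {
    reads[[pf]] <- stage(paste0("reads-", pf), simulateReads(
      truth, samples, platform = pf, config = config, depth = depth,
      seed = childSeed(seed, 10L + match(pf, c("tes", "rnaseq", "gbs"))),
      pairs = pairs, targets = if (pf == "tes") panelHits else NULL))
    if (writeReads)
      keep(exportFastq(reads[[pf]], file.path(outDir, paste0("reads_", pf))))
  }

  # capture metrics on TES alignments, overall (separate) and unique
  # (concatenated) retention
  capFiles <- NULL
  if ("tes" %in% platforms) {
    capTab <- stage("capmetrics", {
      alnSep <- alignReads(reads$tes, truth@genome, mode = "separate")
      alnCat <- alignReads(reads$tes, truth@genome, mode = "concatenated")
      rbind(cbind(retention = "overall",
                  captureMetrics(panelHits, alnSep)),
            cbind(retention = "unique",
                  captureMetrics(panelHits, alnCat)))
    })
    capFiles <- exportTsv(capTab, file.path(outDir, "capture_metrics.tsv"))
    keep(capFiles)
  }

  arrayTab <- stage("array", simulateArray(
    truth, pairs,
    nMarkers = min(nMarkers, nrow(truth@allelicSites) +
                     nrow(truth@homoeologSites)),
    seed = childSeed(seed, 20L)))
  keep(exportTsv(arrayTab, file.path(outDir, "array_genotypes.tsv")))

  records <- list(); reports <- list()
  for (pf in platforms) {
    # one alignment per mode per platform, shared across its pipelines
    alnCache <- list()
    for (pid in pipelines) {
      cfg <- pipelineConfig(pid)
      if (is.null(alnCache[[cfg$mode]]))
        alnCache[[cfg$mode]] <- alignReads(reads[[pf]], truth@genome,
                                           mode = cfg$mode)
      tag <- paste(pf, pid, sep = "_")
      rec <- stage(paste0("pipeline-", tag), runPipeline(
        cfg, reads[[pf]], truth@genome, alignments = alnCache[[cfg$mode]]))
      records[[tag]] <- rec
      keep(exportVcf(rec, file.path(outDir, paste0("snps_", tag, ".vcf"))))
      reports[[tag]] <- cbind(platform = pf,
                              overlapAndScore(rec, arrayTab)$report)
    }
  }
  keep(exportTsv(rbindlist(reports, fill = TRUE),
                 file.path(outDir, "concordance.tsv")))

  graph <- stage("graphmap", {
    bestByPlatform <- lapply(platforms, function(pf) {
      tag <- paste(pf, if ("M4" %in% pipelines) "M4" else pipelines[1],
                   sep = "_")
      r <- records[[tag]]
      r[r$zygosity == "homozygous", ]
    })
    names(bestByPlatform) <- platforms
    bestByPlatform$array <- arrayRecords(arrayTab, truth)
    combined <- mergePlatforms(bestByPlatform)
    gm <- truth@geneModels
    degs <- mcols(gm)$gene_id[mcols(gm)$deg]
    nods <- mcols(gm)$gene_id[mcols(gm)$nod]
    out <- list(combined = combined)
    for (pr in pairs) {
      id <- paste(pr@lines, collapse = "")
      qual <- filterRilPolymorphic(combined, pr@lines)
      regs <- callRegions(qual, pr@lines, mergeDistance = mergeDistance,
                          pairId = id)
      ann <- annotateRegions(regs, gm, degs, nods)
      keep(exportBed(regs, file.path(outDir, paste0("regions_", id, ".bed"))))
      keep(exportTsv(ann, file.path(outDir, paste0("candidates_", id, ".tsv"))))
      out[[id]] <- list(regions = regs, annotations = ann)
    }
    keep(exportTsv(graphicalGenotypes(combined, samples[-(1:2)]),
                   file.path(outDir, "graphical_genotypes.tsv")))
    out
  })

  manifest <- methods::new("RunManifest",
    config = configAsList(config), seed = seed,
    hashes = tools::md5sum(sort(unique(files))),
    version = as.character(utils::packageVersion("tetrasnp")))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(list(config = manifest@config, seed = manifest@seed,
                            version = manifest@version,
                            hashes = as.list(manifest@hashes)),
                       manifestPath, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# array genotype table -> SNP-record-shaped table for merging (allelic
# markers only; genotypes re-expressed relative to the reference allele)
arrayRecords <- function(arrayTab, truth) {
  a <- as.data.table(arrayTab)
  a <- a[confounded == FALSE]
  if (!nrow(a)) return(emptyRecords())
  al <- data.table::tstrsplit(a$alleles, "/", fixed = TRUE)
  a[, `:=`(ref = al[[1]], alt = al[[2]])]
  sampleCols <- setdiff(names(arrayTab),
                        c("marker_id", "chrom", "pos", "alleles", "confounded"))
  for (s in sampleCols) {
    g <- a[[s]]
    a[[paste0("gt_", s)]] <- fifelse(
      g == gtString(a$ref, a$ref), "hom_ref",
      fifelse(g == gtString(a$alt, a$alt), "hom_alt",
              fifelse(g == gtString(a$ref, a$alt), "het", "missing")))
  }
  gtCols <- paste0("gt_", sampleCols)
  out <- a[, c("chrom", "pos", "ref", "alt", gtCols), with = FALSE]
  out[, zygosity := "homozygous"]
  out[]
}

configAsList <- function(config) {
  sl <- methods::slotNames(config)
  stats::setNames(lapply(sl, function(s) methods::slot(config, s)), sl)
}

#' @rdname runAll
#' @param manifest a [RunManifest-class].
#' @export
manifestHashes <- function(manifest) manifest@hashes
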