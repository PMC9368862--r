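# End-to-end orchestration: simulate -> QC -> ED scan -> annotate -> segregation
# test -> fine mapping -> report, with per-stage file handoff and deterministic
# child seeds derived from one global seed.

#' Run the full pooled-mapping pipeline on synthetic data
#'
#' Executes the whole workflow under one configuration and seed: simulate the
#' reference, gene models, EMS variants, selfed MutMap+ cohort and pooled read
#' counts; apply the read-support filter and the ED scan; call candidate
#' intervals and annotate their genes; filter to nonsynonymous motif-hit
#' candidate genes; simulate the biparental fine-mapping cross, test its
#' phenotype segregation against 1:2:1 (or 3:1 for two classes), narrow the
#' interval by recombinant breakpoints, and intersect it with the BSA
#' candidate intervals.
#'
#' Stage outputs are plain files so each stage can be re-run from persisted
#' intermediates: \code{reference.fasta}, \code{genes.gff3},
#' \code{pooled.vcf}, \code{truth.tsv}, \code{sites_ed.tsv},
#' \code{intervals.bed}, \code{scan_summary.tsv}, \code{annotation.tsv},
#' \code{candidates.tsv}, \code{segregation.tsv}, \code{marker_map.tsv},
#' \code{marker_genotypes.tsv}, \code{finemap.tsv} and \code{summary.json}.
#'
#' @param config A [SimulationConfig].
#' @param outDir Output directory (created if missing); required unless
#'   \code{artifacts = "none"}.
#' @param seed Global seed; expanded into per-stage child seeds by a
#'   deterministic derivation. Defaults to the config seed.
#' @param artifacts \code{"all"} writes every stage file, \code{"tables"}
#'   skips the large FASTA/GFF3/VCF, \code{"none"} writes nothing and only
#'   returns the report.
#' @param minReads,windowBp,power,thresholdMethod,thresholdValue,thresholdQ
#'   Scan parameters (see [edScan()] and [computeEdThreshold()]). The pipeline
#'   thresholds at the 0.95 fitted-ED quantile: a candidate region should
#'   cover the window-wide correlated plateau around a peak, not only its
#'   extreme order statistics.
#' @param mergeGapBp Gap bridged when merging super-threshold runs; defaults
#'   to \code{windowBp}, the correlation length imposed by the smoother.
#' @param verbose Print stage progress.
#' @return Invisibly, the report: a list with \code{truth}, \code{filterLog},
#'   \code{threshold}, \code{intervals}, \code{peak} (chrom/pos/ed and
#'   distance to the causal SNP), \code{candidates},
#'   \code{uniqueCandidate} (the single nonsynonymous motif-hit gene, or NA),
#'   \code{segregation}, \code{finemap}, \code{intersected} and
#'   \code{parameters}.
#' @examples
#' cfg <- simulationConfig(chromLengths = c(chr1 = 2e6), nSnps = 300,
#'                         nGenes = 40, seed = 7L)
#' rep <- runPipeline(cfg, artifacts = "none")
#' rep$peak$distance
#' @export
runPipeline <- function(config, outDir = NULL, seed = config@seed,
                        artifacts = c("all", "tables", "none"),
                        minReads = 4L, windowBp = 1e6, power = 1,
                        thresholdMethod = "quantile_permutation",
                        thresholdValue = 0.05, thresholdQ = 0.95,
                        mergeGapBp = windowBp, verbose = FALSE) {
  artifacts <- match.arg(artifacts)
  methods::validObject(config)
  if (artifacts != "none") {
    if (is.null(outDir)) stop("validation error: 'outDir' required unless artifacts = \"none\"")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("validation error: cannot create ", outDir)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  params <- list(seed = seed, minReads = minReads, windowBp = windowBp,
                 power = power, thresholdMethod = thresholdMethod,
                 thresholdValue = thresholdValue, thresholdQ = thresholdQ,
                 mergeGapBp = mergeGapBp)
  tsv <- function(df, name) utils::write.table(
    df, file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage simulate: genome, genes, EMS variants, cohort, pools")
  sim <- simulateMutmapExperiment(config, seed = seed)
  # the stage contract is the pooled VCF, which carries AD (ref/alt) counts;
  # reduce the in-memory panel to the same information so that re-running the
  # scan from the persisted file reproduces the pipeline exactly
  sim$panel <- .reduceToRefAlt(sim$panel)
  if (artifacts == "all") {
    writeGenomeFasta(sim$genome, file.path(outDir, "reference.fasta"))
    writeGeneModels(sim$genes, file.path(outDir, "genes.gff3"))
    writePooledVcf(sim$panel, file.path(outDir, "pooled.vcf"),
                   chromLengths = config@chromLengths)
  }
  if (artifacts != "none")
    tsv(data.frame(chrom = sim$truth$chrom, pos = sim$truth$pos,
                   gene = sim$truth$gene), "truth.tsv")

  say("stage edscan: QC, ED statistic, tricube fit, threshold, intervals")
  profile <- edScan(sim$panel, minReads = minReads, power = power,
                    windowBp = windowBp, thresholdMethod = thresholdMethod,
                    thresholdValue = thresholdValue, q = thresholdQ,
                    seed = .childSeed(seed, 30L))
  intervals <- candidateIntervals(profile, mergeGapBp = mergeGapBp)
  # the fitted profile localizes interval edges only to the smoother's
  # resolution; collect genes over the interval padded by half a window
  padded <- intervals
  GenomicRanges::start(padded) <-
    pmax(1L, GenomicRanges::start(padded) - as.integer(windowBp / 2))
  GenomicRanges::end(padded) <-
    GenomicRanges::end(padded) + as.integer(windowBp / 2)
  padded <- genesInIntervals(padded, sim$genes)
  S4Vectors::mcols(intervals)$geneIds <- S4Vectors::mcols(padded)$geneIds
  sProf <- edValues(profile)
  peakIdx <- which.max(sProf$edFitted)
  peak <- list(chrom = sProf$chrom[peakIdx], pos = sProf$pos[peakIdx],
               ed = sProf$edFitted[peakIdx],
               distance = if (sProf$chrom[peakIdx] == sim$truth$chrom)
                 abs(sProf$pos[peakIdx] - sim$truth$pos) else Inf)
  if (artifacts != "none") {
    tsv(sProf, "sites_ed.tsv")
    writeIntervalsBed(intervals, file.path(outDir, "intervals.bed"))
    tsv(data.frame(n_sites_in = nSites(sim$panel),
                   n_removed = profile@filterLog$n[
                     profile@filterLog$reason == "removed"],
                   threshold = edThreshold(profile),
                   n_intervals = length(intervals)), "scan_summary.tsv")
  }

  say("stage annotate: codon-level effects and motif hits")
  annotations <- classifyVariants(siteInfo(sim$panel), sim$genes, sim$genome,
                                  motif = config@motif)
  candidates <- nonsynFilter(intervals, annotations)
  motifCand <- candidates$gene[candidates$motifHit %in% TRUE]
  uniqueCandidate <- if (length(motifCand) == 1L) motifCand else NA_character_
  if (artifacts != "none") {
    tsv(annotations, "annotation.tsv")
    tsv(candidates, "candidates.tsv")
  }

  say("stage finemap cross: biparental F2, segregation, recombinants")
  cross <- simulateFinemapCross(config, causalPos = sim$truth$pos,
                                chrom = sim$truth$chrom,
                                seed = .childSeed(seed, 40L))
  phen <- phenotypes(cross$cohort)
  counts <- table(factor(phen, levels = .PHENO_CLASSES))
  counts <- counts[counts > 0]
  ratio <- if (length(counts) == 3L) c(1, 2, 1) else c(3, 1)
  seg <- chiSquareGof(as.numeric(counts), ratio)
  mIdx <- setdiff(seq_len(nrow(lociInfo(cross$cohort))),
                  causalLocus(cross$cohort))
  genoM <- genotypes(cross$cohort)[, mIdx, drop = FALSE]
  colnames(genoM) <- cross$markerMap$marker
  fm <- narrowInterval(cross$markerMap, genoM, phen, config@mode,
                       chromStart = 0,
                       chromEnd = config@chromLengths[[sim$truth$chrom]] + 1)
  inter <- suppressWarnings(intersectWithBsa(fm, intervals))
  if (artifacts != "none") {
    tsv(data.frame(class = names(counts), observed = as.numeric(counts),
                   expected = seg@expected, chisq = seg@statistic,
                   df = seg@df, p_value = seg@pValue,
                   decision = seg@decision), "segregation.tsv")
    writeMarkerMap(cross$markerMap, file.path(outDir, "marker_map.tsv"))
    writeMarkerGenotypes(seq_len(nrow(genoM)), phen, genoM,
                         file.path(outDir, "marker_genotypes.tsv"))
    tsv(data.frame(chrom = fm@chrom, lower = fm@interval[1],
                   upper = fm@interval[2],
                   left_marker = fm@leftMarker, right_marker = fm@rightMarker,
                   n_recombinants = nrow(fm@recombinants)), "finemap.tsv")
  }

  report <- list(
    truth = sim$truth, filterLog = profile@filterLog,
    threshold = edThreshold(profile), intervals = intervals, peak = peak,
    candidates = candidates, uniqueCandidate = uniqueCandidate,
    segregation = seg,
    finemap = fm, intersected = inter, parameters = params)
  if (artifacts != "none") {
    summary <- list(
      seed = seed,
      causal = sim$truth,
      peak = peak[c("chrom", "pos", "ed", "distance")],
      threshold = edThreshold(profile),
      n_intervals = length(intervals),
      candidates = candidates$gene,
      unique_candidate = uniqueCandidate,
      segregation = list(observed = as.numeric(counts),
                         ratio = paste(ratio, collapse = ":"),
                         chisq = seg@statistic, p = seg@pValue,
                         decision = seg@decision),
      finemap = list(chrom = fm@chrom, lower = fm@interval[1],
                     upper = fm@interval[2],
                     n_recombinants = nrow(fm@recombinants)),
      parameters = params)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  say("done: peak %s:%d (%.0f bp from causal), candidate %s",
      peak$chrom, peak$pos, peak$distance, uniqueCandidate)
  invisible(report)
}
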