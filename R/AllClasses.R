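# S4 containers for the pooled-mapping pipeline. Coordinates are 1-based
# inclusive throughout (VCF/GFF3 convention); conversion to 0-based half-open
# happens only at the BED boundary.

.ACGT <- c("A", "C", "G", "T")
.GENO_CODES <- c("A", "H", "B")
.PHENO_CLASSES <- c("WT", "INT", "MUT")
.MODES <- c("semi-dominant", "dominant", "recessive")
.NONSYN_EFFECTS <- c("missense", "nonsense", "start_loss", "stop_loss")

#' Gene models with ordered CDS segments
#'
#' A set of protein-coding gene models, each a stranded, ordered collection of
#' CDS segments on one chromosome. Models whose total CDS length is not a
#' multiple of 3 are retained but flagged non-translatable.
#'
#' @slot cds A \link[GenomicRanges]{GRangesList}, one element per model,
#'   named by model id; each element holds that model's CDS segments
#'   (sorted by start, non-overlapping, single chromosome and strand).
#' @slot gene Character vector of parent gene ids, parallel to \code{cds}.
#' @slot translatable Logical vector, parallel to \code{cds}: total CDS
#'   length divisible by 3.
#'
#' @seealso [readGeneModels()], [geneSpans()], [translateGeneModel()]
#' @export
setClass("GeneModels",
  representation(cds = "CompressedGRangesList",
                 gene = "character",
                 translatable = "logical"))

setValidity("GeneModels", function(object) {
  n <- length(object@cds)
  msg <- character(0)
  ids <- names(object@cds)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "model ids must be unique non-empty names on 'cds'")
  if (length(object@gene) != n || length(object@translatable) != n)
    msg <- c(msg, "'gene' and 'translatable' must parallel 'cds'")
  len <- lengths(object@cds)
  if (any(len == 0L)) msg <- c(msg, "empty CDS set")
  ul <- unlist(object@cds, use.names = FALSE)
  grp <- rep.int(seq_len(n), len)
  first <- cumsum(len) - len + 1L
  ch <- as.character(GenomicRanges::seqnames(ul))
  st <- as.character(GenomicRanges::strand(ul))
  if (any(ch != ch[first][grp]))
    msg <- c(msg, "CDS segments of one model must share a chromosome")
  if (any(st != st[first][grp]) || any(!st[first] %in% c("+", "-")))
    msg <- c(msg, "CDS segments of one model must share a +/- strand")
  s <- GenomicRanges::start(ul); e <- GenomicRanges::end(ul)
  if (length(ul) > 1L) {
    sameGrp <- grp[-1L] == grp[-length(grp)]
    if (any(sameGrp & s[-1L] <= e[-length(e)]))
      msg <- c(msg, "CDS segments must be sorted by start and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Biallelic SNP sites with per-pool base counts
#'
#' The unit of the Euclidean-distance scan: biallelic SNPs with, for each of
#' the two phenotype-selected pools (\code{mut} and \code{wt}), read counts
#' over the four bases A/C/G/T.
#'
#' @slot sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @slot mutCounts,wtCounts Integer matrices (sites x 4, columns A,C,G,T) of
#'   read counts in the mutant-phenotype and wild-type-phenotype pool.
#'
#' @seealso [readPooledVcf()], [edStatistic()], [filterSites()]
#' @export
setClass("VariantPanel",
  representation(sites = "data.frame",
                 mutCounts = "matrix",
                 wtCounts = "matrix"))

setValidity("VariantPanel", function(object) {
  s <- object@sites
  msg <- character(0)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(s)))
    return(sprintf("'sites' must have columns %s", paste(need, collapse = ", ")))
  n <- nrow(s)
  for (nm in c("mutCounts", "wtCounts")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 4L ||
        !identical(colnames(m), .ACGT))
      msg <- c(msg, sprintf("'%s' must be a sites x 4 matrix with columns A,C,G,T", nm))
    else if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, sprintf("'%s' must hold non-negative integer counts", nm))
  }
  if (n > 0) {
    if (!all(s$ref %in% .ACGT) || !all(s$alt %in% .ACGT))
      msg <- c(msg, "ref and alt must be single bases in A,C,G,T")
    else if (any(s$ref == s$alt))
      msg <- c(msg, "ref must differ from alt at every site")
    if (any(s$pos < 1)) msg <- c(msg, "positions are 1-based and must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-chromosome Euclidean-distance profile
#'
#' Raw and locally fitted ED values for the retained sites of a scan, with the
#' threshold used for interval calling.
#'
#' @slot sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{edRaw}, \code{edFitted}; positions strictly increasing within each
#'   chromosome.
#' @slot threshold Numeric threshold on the fitted values.
#' @slot power Exponent applied to the ED statistic (default 1).
#' @slot windowBp Physical window used by the tricube smoother.
#' @slot thresholdMethod Character; how the threshold was obtained.
#' @slot filterLog data.frame of read-support QC counts by reason.
#'
#' @seealso [edScan()], [candidateIntervals()]
#' @export
setClass("EDProfile",
  representation(sites = "data.frame",
                 threshold = "numeric",
                 power = "numeric",
                 windowBp = "numeric",
                 thresholdMethod = "character",
                 filterLog = "data.frame"))

setValidity("EDProfile", function(object) {
  s <- object@sites
  msg <- character(0)
  need <- c("chrom", "pos", "edRaw", "edFitted")
  if (!all(need %in% names(s)))
    return(sprintf("'sites' must have columns %s", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0)
    msg <- c(msg, "'threshold' must be a single non-negative value")
  if (nrow(s) > 0) {
    if (any(!is.finite(s$edFitted)))
      msg <- c(msg, "fitted values must be defined for every retained site")
    bad <- vapply(split(s$pos, s$chrom),
                  function(p) is.unsorted(p, strictly = TRUE), logical(1))
    if (any(bad))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated F2 cohort
#'
#' Individuals from a selfed heterozygote (MutMap+ design) or a biparental F1
#' selfing, with per-locus genotype codes and phenotype classes.
#'
#' Genotype codes: \code{A} homozygous wild allele, \code{H} heterozygous,
#' \code{B} homozygous mutant allele. Phenotype classes: \code{WT},
#' \code{INT}, \code{MUT}.
#'
#' @slot loci data.frame of locus coordinates: \code{chrom}, \code{pos}.
#' @slot geno Character matrix (individuals x loci) of codes A/H/B (NA allowed
#'   for missing genotypes).
#' @slot phenotype Character vector of classes, one per individual.
#' @slot causal Integer index of the causal locus in \code{loci}.
#' @slot mode Inheritance mode: one of \code{"semi-dominant"},
#'   \code{"dominant"}, \code{"recessive"}.
#'
#' @seealso [simulateF2Cohort()], [buildPoolsAndReads()]
#' @export
setClass("F2Cohort",
  representation(loci = "data.frame",
                 geno = "matrix",
                 phenotype = "character",
                 causal = "integer",
                 mode = "character"))

setValidity("F2Cohort", function(object) {
  msg <- character(0)
  L <- nrow(object@loci)
  if (!all(c("chrom", "pos") %in% names(object@loci)))
    return("'loci' must have columns chrom, pos")
  if (ncol(object@geno) != L)
    msg <- c(msg, "genotype matrix must have one column per locus")
  if (length(object@phenotype) != nrow(object@geno))
    msg <- c(msg, "one phenotype class per individual required")
  g <- object@geno
  if (!all(g[!is.na(g)] %in% .GENO_CODES))
    msg <- c(msg, "genotype codes must be A, H or B")
  if (!all(object@phenotype %in% .PHENO_CLASSES))
    msg <- c(msg, "phenotype classes must be WT, INT or MUT")
  if (length(object@causal) != 1L || is.na(object@causal) ||
      object@causal < 1L || object@causal > L)
    msg <- c(msg, "'causal' must index a locus")
  if (!object@mode %in% .MODES)
    msg <- c(msg, sprintf("'mode' must be one of %s", paste(.MODES, collapse = ", ")))
  else {
    gc <- object@geno[, object@causal]
    ok <- is.na(gc) |
      object@phenotype == phenotypeFromGenotype(gc, object@mode)
    if (!all(ok))
      msg <- c(msg, "phenotype must be determined by the causal genotype and mode")
  }
  if (length(msg)) msg else TRUE
})

#' Mendelian segregation-ratio test result
#'
#' Chi-square goodness-of-fit of observed phenotype class counts against an
#' expected Mendelian ratio.
#'
#' @slot observed,expected Numeric vectors of observed and expected counts.
#' @slot ratio The expected ratio (positive weights, same length).
#' @slot statistic Chi-square statistic.
#' @slot df Degrees of freedom (classes - 1).
#' @slot pValue Upper-tail p-value.
#' @slot alpha Significance level used for the decision.
#' @slot critical Critical value of the chi-square distribution at alpha.
#' @slot decision \code{"fits"} iff statistic <= critical, else
#'   \code{"rejected"}.
#'
#' @seealso [chiSquareGof()], [classifyInheritance()]
#' @export
setClass("SegregationResult",
  representation(observed = "numeric", ratio = "numeric", expected = "numeric",
                 statistic = "numeric", df = "numeric", pValue = "numeric",
                 alpha = "numeric", critical = "numeric", decision = "character"))

setValidity("SegregationResult", function(object) {
  msg <- character(0)
  if (abs(sum(object@expected) - sum(object@observed)) > 1e-8)
    msg <- c(msg, "expected counts must sum to the observed total")
  if (object@df != length(object@observed) - 1L)
    msg <- c(msg, "df must equal the number of classes minus 1")
  fits <- object@statistic <= object@critical
  if (!identical(object@decision, if (fits) "fits" else "rejected"))
    msg <- c(msg, "decision must be 'fits' iff statistic <= critical")
  if (length(msg)) msg else TRUE
})

#' Recombinant-breakpoint fine-mapping result
#'
#' The interval bracketing the causal locus after excluding every marker at
#' which some individual's genotype contradicts its phenotype-implied causal
#' genotype. The interval is open at the bounding (excluded) markers.
#'
#' @slot chrom Chromosome of the marker map.
#' @slot leftMarker,rightMarker Ids of the bounding excluded markers
#'   (\code{NA} when the bound is the chromosome end).
#' @slot coreMarkers Ids of the consistent (non-excluded) markers.
#' @slot interval Numeric length-2 open interval (left bound, right bound) in
#'   bp; the causal locus is asserted to lie strictly between the bounds.
#' @slot recombinants data.frame of recombinant individuals: \code{id} and the
#'   comma-separated \code{markers} at which each is discordant.
#' @slot excludedMarkers Ids of all excluded markers.
#'
#' @seealso [narrowInterval()], [intersectWithBsa()]
#' @export
setClass("FineMapResult",
  representation(chrom = "character",
                 leftMarker = "character", rightMarker = "character",
                 coreMarkers = "character", interval = "numeric",
                 recombinants = "data.frame", excludedMarkers = "character"))

setValidity("FineMapResult", function(object) {
  msg <- character(0)
  if (length(object@interval) != 2L || !(object@interval[1] < object@interval[2]))
    msg <- c(msg, "interval must be (left, right) with left < right")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic study design
#'
#' Bundles every knob of the synthetic-data generator: the genome, the EMS
#' mutation load, the selfed-heterozygote MutMap+ cohort and its
#' phenotype-selected pools, pooled sequencing, and the biparental fine-mapping
#' cross. Defaults emulate the study design the pipeline targets: 20+20
#' extreme-phenotype pools at ~38x pooled depth from the selfed progeny of
#' plants heterozygous for a semi-dominant EMS allele, and a separate 185-plant
#' biparental F2 for fine mapping.
#'
#' @slot chromLengths Named numeric vector of chromosome lengths (bp).
#' @slot nSnps Total number of EMS SNPs (background + 1 causal).
#' @slot nGenes Number of gene models to place.
#' @slot poolSize Individuals per phenotype pool.
#' @slot depth Mean pooled read depth per site per pool (Poisson mean).
#' @slot errorRate Per-base sequencing error rate (symmetric substitution).
#' @slot cmPerMb Recombination rate, centimorgan per megabase.
#' @slot mode Inheritance mode of the causal allele.
#' @slot cohortSize Size of the selfed MutMap+ F2 cohort.
#' @slot f2Size Size of the biparental fine-mapping F2.
#' @slot nMarkers Number of ordered fine-mapping markers.
#' @slot markerSpacingBp Physical spacing of the fine-mapping marker grid.
#' @slot emsBias Probability that a background SNP is an EMS-type transition
#'   (C>T or G>A).
#' @slot motif Protein motif planted into (and required in) one gene.
#' @slot maxRetries Resimulation attempts when a cohort lacks enough
#'   individuals of a pooled phenotype class.
#' @slot seed Integer seed (NA for none).
#'
#' @seealso [simulationConfig()], [runPipeline()]
#' @export
setClass("SimulationConfig",
  representation(chromLengths = "numeric", nSnps = "integer",
                 nGenes = "integer", poolSize = "integer", depth = "numeric",
                 errorRate = "numeric", cmPerMb = "numeric", mode = "character",
                 cohortSize = "integer", f2Size = "integer",
                 nMarkers = "integer", markerSpacingBp = "numeric",
                 emsBias = "numeric", motif = "character",
                 maxRetries = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  cl <- object@chromLengths
  if (length(cl) == 0 || is.null(names(cl)) || any(!nzchar(names(cl))) ||
      any(cl < 1000))
    msg <- c(msg, "'chromLengths' must be named lengths of at least 1 kb")
  if (object@depth <= 0) msg <- c(msg, "'depth' must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 0.5)
    msg <- c(msg, "'errorRate' must satisfy 0 <= e < 0.5")
  if (!object@mode %in% .MODES)
    msg <- c(msg, sprintf("'mode' must be one of %s", paste(.MODES, collapse = ", ")))
  if (object@emsBias < 0 || object@emsBias > 1)
    msg <- c(msg, "'emsBias' must be in [0, 1]")
  if (object@poolSize < 1) msg <- c(msg, "'poolSize' must be >= 1")
  if (object@nSnps < 1) msg <- c(msg, "'nSnps' must be >= 1")
  if (!nzchar(object@motif)) msg <- c(msg, "'motif' must be non-empty")
  if (object@nMarkers < 3) msg <- c(msg, "'nMarkers' must be >= 3")
  if (length(msg)) msg else TRUE
})
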