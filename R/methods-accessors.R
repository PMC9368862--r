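# Accessors and show() methods.

.newGeneModels <- function(cds, gene, translatable = NULL) {
  if (is.null(translatable)) {
    w <- GenomicRanges::width(unlist(cds, use.names = FALSE))
    grp <- rep.int(seq_along(cds), lengths(cds))
    translatable <- as.vector(rowsum(w, grp)) %% 3L == 0L
  }
  methods::new("GeneModels", cds = cds, gene = unname(gene),
               translatable = unname(translatable))
}

#' @rdname GeneModels-class
#' @export
setMethod("geneSpans", "GeneModels", function(x) {
  # segments are sorted within each model, so the first/last segment carry
  # the span bounds
  len <- lengths(x@cds)
  first <- cumsum(len) - len + 1L
  last <- cumsum(len)
  ul <- unlist(x@cds, use.names = FALSE)
  spans <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(ul))[first],
    IRanges::IRanges(GenomicRanges::start(ul)[first],
                     GenomicRanges::end(ul)[last]),
    strand = as.character(GenomicRanges::strand(ul))[first])
  names(spans) <- names(x@cds)
  S4Vectors::mcols(spans)$gene <- x@gene
  spans
})

#' @rdname GeneModels-class
#' @export
setMethod("cdsRanges", "GeneModels", function(x) x@cds)

#' @rdname GeneModels-class
#' @export
setMethod("geneIds", "GeneModels", function(x) names(x@cds))

#' @rdname GeneModels-class
#' @export
setMethod("isTranslatable", "GeneModels", function(x)
  stats::setNames(x@translatable, names(x@cds)))

#' @rdname GeneModels-class
#' @export
setMethod("length", "GeneModels", function(x) length(x@cds))

#' @rdname GeneModels-class
#' @param i Index or model ids.
#' @export
setMethod("[", "GeneModels", function(x, i) {
  idx <- if (is.character(i)) match(i, names(x@cds)) else i
  .newGeneModels(x@cds[idx], x@gene[idx], x@translatable[idx])
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d model(s) on %s\n", length(object),
              paste(unique(as.character(unlist(
                GenomicRanges::seqnames(object@cds)))), collapse = ", ")))
  k <- min(length(object), 5L)
  for (i in seq_len(k)) {
    gr <- object@cds[[i]]
    cat(sprintf("  %s (gene %s, %s): %d CDS segment(s), %d bp%s\n",
                names(object@cds)[i], object@gene[i],
                as.character(GenomicRanges::strand(gr))[1], length(gr),
                sum(GenomicRanges::width(gr)),
                if (object@translatable[i]) "" else " [non-translatable]"))
  }
  if (length(object) > k) cat(sprintf("  ... and %d more\n", length(object) - k))
})

#' @rdname VariantPanel-class
#' @export
setMethod("siteInfo", "VariantPanel", function(x) x@sites)

#' @rdname VariantPanel-class
#' @export
setMethod("poolCounts", "VariantPanel", function(x, pool = c("mut", "wt")) {
  pool <- match.arg(pool)
  if (pool == "mut") x@mutCounts else x@wtCounts
})

#' @rdname VariantPanel-class
#' @export
setMethod("nSites", "VariantPanel", function(x) nrow(x@sites))

#' @rdname VariantPanel-class
#' @export
setMethod("[", "VariantPanel", function(x, i) {
  methods::new("VariantPanel", sites = x@sites[i, , drop = FALSE],
               mutCounts = x@mutCounts[i, , drop = FALSE],
               wtCounts = x@wtCounts[i, , drop = FALSE])
})

setMethod("show", "VariantPanel", function(object) {
  cat(sprintf("VariantPanel with %d biallelic site(s) on %s\n",
              nSites(object),
              paste(unique(object@sites$chrom), collapse = ", ")))
  if (nSites(object) > 0) {
    md <- rowSums(object@mutCounts); wd <- rowSums(object@wtCounts)
    cat(sprintf("  median depth: mut %.0f, wt %.0f\n",
                stats::median(md), stats::median(wd)))
  }
})

#' @rdname EDProfile-class
#' @export
setMethod("edValues", "EDProfile", function(x) x@sites)

#' @rdname EDProfile-class
#' @export
setMethod("edThreshold", "EDProfile", function(x) x@threshold)

setMethod("show", "EDProfile", function(object) {
  s <- object@sites
  cat(sprintf("EDProfile: %d site(s) on %d chromosome(s)\n",
              nrow(s), length(unique(s$chrom))))
  cat(sprintf("  power %g, window %g bp, threshold %.4g (%s)\n",
              object@power, object@windowBp, object@threshold,
              object@thresholdMethod))
  if (nrow(s) > 0)
    cat(sprintf("  fitted ED range: [%.4g, %.4g]\n",
                min(s$edFitted), max(s$edFitted)))
})

#' @rdname F2Cohort-class
#' @export
setMethod("genotypes", "F2Cohort", function(x) x@geno)

#' @rdname F2Cohort-class
#' @export
setMethod("phenotypes", "F2Cohort", function(x) x@phenotype)

#' @rdname F2Cohort-class
#' @export
setMethod("lociInfo", "F2Cohort", function(x) x@loci)

#' @rdname F2Cohort-class
#' @export
setMethod("causalLocus", "F2Cohort", function(x) x@causal)

#' @rdname F2Cohort-class
#' @export
setMethod("length", "F2Cohort", function(x) nrow(x@geno))

setMethod("show", "F2Cohort", function(object) {
  tab <- table(factor(object@phenotype, levels = .PHENO_CLASSES))
  cat(sprintf("F2Cohort: %d individuals, %d loci, %s causal locus %s:%d\n",
              nrow(object@geno), nrow(object@loci), object@mode,
              object@loci$chrom[object@causal],
              object@loci$pos[object@causal]))
  cat(sprintf("  phenotype classes: WT %d, INT %d, MUT %d\n",
              tab["WT"], tab["INT"], tab["MUT"]))
})

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf("Segregation test against %s\n",
              paste(object@ratio, collapse = ":")))
  cat(sprintf("  observed: %s  expected: %s\n",
              paste(object@observed, collapse = ", "),
              paste(round(object@expected, 2), collapse = ", ")))
  cat(sprintf("  chi-square = %.4g (df = %d), p = %.4g\n",
              object@statistic, object@df, object@pValue))
  cat(sprintf("  %s at alpha = %g (critical %.4g)\n",
              object@decision, object@alpha, object@critical))
})

setMethod("show", "FineMapResult", function(object) {
  cat(sprintf("FineMapResult on %s: causal in open interval (%s, %s)\n",
              object@chrom,
              format(object@interval[1], big.mark = ","),
              format(object@interval[2], big.mark = ",")))
  cat(sprintf("  bounding markers: %s | %s; %d core marker(s); %d recombinant(s)\n",
              ifelse(is.na(object@leftMarker), "<chrom start>", object@leftMarker),
              ifelse(is.na(object@rightMarker), "<chrom end>", object@rightMarker),
              length(object@coreMarkers), nrow(object@recombinants)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  genome: %s (%s bp); %d genes; %d EMS SNPs (bias %.2f), motif %s\n",
              paste(names(object@chromLengths), collapse = ","),
              paste(format(object@chromLengths, big.mark = ",", trim = TRUE),
                    collapse = ","),
              object@nGenes, object@nSnps, object@emsBias, object@motif))
  cat(sprintf("  inheritance: %s; cohort %d; pools %d+%d; depth %gx; error %g\n",
              object@mode, object@cohortSize, object@poolSize, object@poolSize,
              object@depth, object@errorRate))
  cat(sprintf("  map: %g cM/Mb; fine-map F2 %d, %d markers every %g kb; seed %s\n",
              object@cmPerMb, object@f2Size, object@nMarkers,
              object@markerSpacingBp / 1000,
              ifelse(is.na(object@seed), "none", object@seed)))
})
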