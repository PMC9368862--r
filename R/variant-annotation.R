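# Codon-level effect prediction against gene models, nonsynonymous candidate
# filtering, and protein-motif checks (the Pro-to-Leu degron logic).

# concatenated coding-strand CDS sequence of one model
.cdsSequence <- function(genes, id, chromStr) {
  gr <- genes@cds[[id]]
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  segs <- substring(chromStr[[chrom]], starts, ends)
  s <- paste(segs, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.chromStrings <- function(genome) {
  if (is.list(genome)) return(genome)
  if (is.character(genome)) return(as.list(genome))
  stats::setNames(as.list(as.character(genome)), names(genome))
}

#' Translate a gene model
#'
#' Concatenates the CDS segments in coding order (strand-aware) and translates
#' with the standard nuclear codon table. Internal stops appear as \code{*}.
#'
#' @param genes A [GeneModels].
#' @param id Model id.
#' @param genome \link[Biostrings]{DNAStringSet} (or named character vector).
#' @return Single-letter protein string.
#' @export
translateGeneModel <- function(genes, id, genome) {
  if (!id %in% geneIds(genes)) stop("unknown gene model: ", id)
  if (!isTranslatable(genes)[[id]])
    stop("non-translatable model (CDS length not divisible by 3): ", id)
  s <- .cdsSequence(genes, id, .chromStrings(genome))
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

#' Codon-level consequence of a SNP inside a CDS
#'
#' Computes the coding coordinate by summing CDS segment lengths in coding
#' order (minus-strand models use reverse-complemented bases and reversed
#' segment order), mutates the affected codon, and classifies the change with
#' the standard nuclear codon table: synonymous when the residue is unchanged,
#' nonsense when the new residue is \code{*}, stop_loss when the old residue
#' was \code{*}, start_loss when codon 1 loses ATG, otherwise missense.
#'
#' @param genes A [GeneModels].
#' @param id Model id whose CDS contains \code{pos}.
#' @param pos Genomic position (1-based) inside a CDS segment of the model.
#' @param ref,alt Reference and alternate base on the genomic plus strand.
#' @param genome \link[Biostrings]{DNAStringSet} (or named character vector).
#' @return A list: \code{codonBefore}, \code{codonAfter}, \code{proteinPos},
#'   \code{residueBefore}, \code{residueAfter}, \code{effect}.
#' @export
codingChange <- function(genes, id, pos, ref, alt, genome) {
  if (!isTranslatable(genes)[[id]])
    stop("non-translatable model (CDS length not divisible by 3): ", id)
  gr <- genes@cds[[id]]
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  chromStr <- .chromStrings(genome)
  gbase <- substring(chromStr[[chrom]], pos, pos)
  if (gbase != ref)
    stop(sprintf("consistency error at %s:%d: genome has %s, variant ref is %s",
                 chrom, pos, gbase, ref))
  cp <- .genomicToCoding(starts, ends, strand, pos)
  if (is.na(cp)) stop(sprintf("position %d is not inside a CDS segment of %s",
                              pos, id))
  refCoding <- if (strand == "+") ref else unname(.COMPLEMENT[ref])
  altCoding <- if (strand == "+") alt else unname(.COMPLEMENT[alt])
  codonIdx <- (cp - 1L) %/% 3L + 1L
  offset <- (cp - 1L) %% 3L + 1L
  cdsSeq <- .cdsSequence(genes, id, chromStr)
  codonBefore <- substring(cdsSeq, 3L * codonIdx - 2L, 3L * codonIdx)
  if (substring(codonBefore, offset, offset) != refCoding)
    stop("internal inconsistency mapping coding coordinates for ", id)
  codonAfter <- codonBefore
  substring(codonAfter, offset, offset) <- altCoding
  tab <- .codonTable()
  before <- unname(tab[codonBefore]); after <- unname(tab[codonAfter])
  effect <-
    if (before == after) "synonymous"
    else if (after == "*") "nonsense"
    else if (before == "*") "stop_loss"
    else if (codonIdx == 1L && codonBefore == "ATG") "start_loss"
    else "missense"
  list(codonBefore = codonBefore, codonAfter = codonAfter,
       proteinPos = codonIdx, residueBefore = before, residueAfter = after,
       effect = effect)
}

#' Classify variants against gene models
#'
#' Each variant inside a CDS segment gets a coding classification via
#' [codingChange()]; inside a gene span but outside every CDS segment it is
#' intronic; otherwise intergenic. A variant overlapping several models yields
#' one row per model. Variants whose reference base mismatches the genome are
#' a consistency error; variants over an N reference base are skipped with a
#' warning.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (e.g. \code{siteInfo(panel)}).
#' @param genes A [GeneModels].
#' @param genome \link[Biostrings]{DNAStringSet} (or named character vector).
#' @param motif Optional protein motif; when given, coding variants get
#'   \code{motifHit}/\code{motifOffset} columns via [motifHit()].
#' @return data.frame with columns chrom, pos, ref, alt, effect, gene (model
#'   id), codonBefore, codonAfter, proteinPos, residueBefore, residueAfter,
#'   proteinChange (e.g. \code{"P160L"}), and optionally motifHit/motifOffset.
#' @export
classifyVariants <- function(sites, genes, genome, motif = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  chromStr <- .chromStrings(genome)
  refBase <- vapply(seq_len(nrow(sites)), function(i)
    substring(chromStr[[sites$chrom[i]]], sites$pos[i], sites$pos[i]),
    character(1))
  isN <- refBase == "N"
  if (any(isN)) {
    warning(sum(isN), " variant(s) over an N reference base skipped")
    sites <- sites[!isN, , drop = FALSE]
    refBase <- refBase[!isN]
  }
  bad <- refBase != sites$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("consistency error at %s:%d: genome has %s, variant ref is %s",
                 sites$chrom[i], sites$pos[i], refBase[i], sites$ref[i]))
  }
  vgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  spans <- geneSpans(genes)
  cdsAll <- unlist(genes@cds)
  cdsModel <- rep(names(genes@cds), lengths(genes@cds))
  spanHits <- GenomicRanges::findOverlaps(vgr, spans, ignore.strand = TRUE)
  cdsHits <- GenomicRanges::findOverlaps(vgr, cdsAll, ignore.strand = TRUE)
  cdsKey <- paste(S4Vectors::queryHits(cdsHits),
                  cdsModel[S4Vectors::subjectHits(cdsHits)])
  spanQ <- S4Vectors::queryHits(spanHits)
  spanS <- S4Vectors::subjectHits(spanHits)
  translatable <- isTranslatable(genes)
  # one output row per (variant, overlapping model); intergenic variants get
  # one row with gene = NA
  outIdx <- c(setdiff(seq_len(nrow(sites)), spanQ), spanQ)
  outGene <- c(rep(NA_character_, nrow(sites) - length(unique(spanQ))),
               names(spans)[spanS])
  n <- length(outIdx)
  effect <- rep("intergenic", n)
  codonBefore <- codonAfter <- residueBefore <- residueAfter <-
    rep(NA_character_, n)
  proteinPos <- rep(NA_integer_, n)
  genic <- which(!is.na(outGene))
  for (k in genic) {
    i <- outIdx[k]; id <- outGene[k]
    if (paste(i, id) %in% cdsKey && translatable[[id]]) {
      cc <- codingChange(genes, id, sites$pos[i], sites$ref[i],
                         sites$alt[i], chromStr)
      effect[k] <- cc$effect
      codonBefore[k] <- cc$codonBefore; codonAfter[k] <- cc$codonAfter
      proteinPos[k] <- cc$proteinPos
      residueBefore[k] <- cc$residueBefore; residueAfter[k] <- cc$residueAfter
    } else {
      effect[k] <- "intronic"
    }
  }
  out <- data.frame(sites[outIdx, c("chrom", "pos", "ref", "alt")],
                    effect = effect, gene = outGene,
                    codonBefore = codonBefore, codonAfter = codonAfter,
                    proteinPos = proteinPos, residueBefore = residueBefore,
                    residueAfter = residueAfter, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  coding <- !is.na(out$proteinPos)
  out$proteinChange <- NA_character_
  out$proteinChange[coding] <- sprintf("%s%d%s", out$residueBefore[coding],
                                       out$proteinPos[coding],
                                       out$residueAfter[coding])
  if (!is.null(motif)) {
    out$motifHit <- FALSE
    out$motifOffset <- NA_integer_
    protCache <- new.env(parent = emptyenv())
    for (i in which(coding)) {
      id <- out$gene[i]
      if (is.null(protCache[[id]]))
        protCache[[id]] <- translateGeneModel(genes, id, chromStr)
      mh <- .motifHitInProtein(protCache[[id]], out$proteinPos[i], motif)
      out$motifHit[i] <- mh$hit
      out$motifOffset[i] <- mh$offset
    }
  }
  out
}

.motifHitInProtein <- function(prot, proteinPos, motif) {
  occ <- gregexpr(motif, prot, fixed = TRUE)[[1]]
  if (occ[1] == -1L) return(list(hit = FALSE, offset = NA_integer_))
  w <- nchar(motif)
  inOcc <- proteinPos >= occ & proteinPos <= occ + w - 1L
  if (!any(inOcc)) return(list(hit = FALSE, offset = NA_integer_))
  list(hit = TRUE, offset = as.integer(proteinPos - occ[which(inOcc)[1]] + 1L))
}

#' Genes carrying nonsynonymous variants within candidate intervals
#'
#' Restricts an annotation table to the genes contained in the candidate
#' intervals and keeps those with at least one missense, nonsense, start-loss
#' or stop-loss variant.
#'
#' @param intervals A \link[GenomicRanges]{GRanges} with a \code{geneIds}
#'   metadata column ([genesInIntervals()]).
#' @param annotations Annotation table from [classifyVariants()].
#' @return data.frame with one row per qualifying gene (ordered by chromosome
#'   and first variant position): \code{gene}, \code{chrom}, \code{nVariants},
#'   \code{effects}, \code{proteinChanges}, and \code{motifHit} when the
#'   annotation carries motif columns.
#' @export
nonsynFilter <- function(intervals, annotations) {
  ids <- unique(unlist(S4Vectors::mcols(intervals)$geneIds))
  keep <- annotations$effect %in% .NONSYN_EFFECTS &
    !is.na(annotations$gene) & annotations$gene %in% ids
  hits <- annotations[keep, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(gene = character(0), chrom = character(0),
                      nVariants = integer(0), effects = character(0),
                      proteinChanges = character(0),
                      motifHit = logical(0))[, if ("motifHit" %in% names(annotations))
                        1:6 else 1:5, drop = FALSE])
  byGene <- split(hits, hits$gene)
  out <- do.call(rbind, lapply(byGene, function(h) data.frame(
    gene = h$gene[1], chrom = h$chrom[1],
    nVariants = nrow(h),
    effects = paste(h$effect, collapse = ","),
    proteinChanges = paste(h$proteinChange, collapse = ","),
    firstPos = min(h$pos),
    motifHit = if ("motifHit" %in% names(h)) any(h$motifHit) else NA,
    stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$firstPos), , drop = FALSE]
  out$firstPos <- NULL
  if (!"motifHit" %in% names(annotations)) out$motifHit <- NULL
  rownames(out) <- NULL
  out
}

#' Does a coding variant fall inside a protein motif?
#'
#' Translates the model's full protein and reports whether the affected
#' residue lies within any exact occurrence of \code{motif}.
#'
#' @param genes A [GeneModels].
#' @param id Model id.
#' @param proteinPos 1-based residue position of the variant.
#' @param genome \link[Biostrings]{DNAStringSet} (or named character vector).
#' @param motif Non-empty protein motif (exact match).
#' @return A list: \code{hit} (logical) and \code{offset} (1-based position of
#'   the residue within the matched occurrence; NA when no hit).
#' @export
motifHit <- function(genes, id, proteinPos, genome, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (is.na(proteinPos) || proteinPos < 1)
    stop("motifHit requires a coding variant with a protein position")
  prot <- translateGeneModel(genes, id, genome)
  .motifHitInProtein(prot, proteinPos, motif)
}
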