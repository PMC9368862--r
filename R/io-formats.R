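# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 1-based inclusive (VCF/GFF3 convention); BED output
# alone is 0-based half-open.

#' Read a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a \link[Biostrings]{DNAStringSet}. Sequences
#' are uppercased and restricted to the alphabet A/C/G/T/N; record order is
#' preserved. Malformed input is reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one entry per record.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), f)
#' readGenomeFasta(f)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, ">")
  if (length(lines) == 0 || body[1])
    stop("FASTA format error at line 1: expected a '>' header")
  bad <- which(body & grepl("[^ACGTNacgtn]", lines))
  if (length(bad))
    stop(sprintf("FASTA format error at line %d: illegal character in sequence",
                 bad[1]))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (any(Biostrings::width(seqs) == 0))
    stop("FASTA format error: empty sequence for record ",
         names(seqs)[Biostrings::width(seqs) == 0][1])
  seqs
}

#' Write a reference genome to FASTA
#'
#' Writes with a 60-column wrap, so that writing what [readGenomeFasta()]
#' returned reproduces a normalized input byte for byte.
#'
#' @param genome A \link[Biostrings]{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file with gene/mRNA/CDS features linked by ID/Parent
#' attributes into a [GeneModels] object, one model per mRNA. CDS segments are
#' sorted by start; a model whose total CDS length is not divisible by 3 is
#' flagged non-translatable with a warning. A CDS feature without a Parent is a
#' format error.
#'
#' @param path Path to a GFF3 file.
#' @return A [GeneModels] object.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  cds <- gr[typ == "CDS"]
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) == 0 || length(cds) == 0)
    stop("GFF3 format error: need mRNA and CDS features")
  pl <- cds$Parent
  if (is.null(pl) || any(lengths(pl) == 0))
    stop("GFF3 format error: CDS feature without a Parent attribute")
  par <- vapply(seq_along(pl), function(i) as.character(pl[[i]][1]),
                character(1))
  ids <- mrna$ID
  if (is.null(ids) || anyNA(ids))
    stop("GFF3 format error: mRNA feature without an ID attribute")
  genePar <- vapply(seq_along(mrna), function(i) {
    p <- mrna$Parent[[i]]
    if (length(p)) as.character(p[1]) else ids[i]
  }, character(1))
  keep <- par %in% ids
  if (!all(keep))
    stop("GFF3 format error: CDS Parent not matching any mRNA ID: ",
         paste(unique(par[!keep]), collapse = ", "))
  segl <- split(cds, factor(par, levels = ids))
  segl <- methods::as(lapply(segl, function(g) {
    g <- g[order(GenomicRanges::start(g))]
    S4Vectors::mcols(g) <- NULL
    names(g) <- NULL
    g
  }), "CompressedGRangesList")
  models <- .newGeneModels(segl, genePar)
  nt <- !models@translatable
  if (any(nt))
    warning(sprintf("%d model(s) with CDS length not divisible by 3 flagged non-translatable: %s",
                    sum(nt), paste(names(segl)[nt], collapse = ", ")))
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features with ID/Parent attributes, the subset of
#' GFF3 that [readGeneModels()] consumes.
#'
#' @param models A [GeneModels] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(methods::is(models, "GeneModels"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  spans <- geneSpans(models)
  for (i in seq_along(models@cds)) {
    id <- names(models@cds)[i]
    gene <- models@gene[i]
    gr <- models@cds[[i]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[1]
    strand <- as.character(GenomicRanges::strand(gr))[1]
    s <- GenomicRanges::start(spans)[i]; e <- GenomicRanges::end(spans)[i]
    writeLines(c(
      sprintf("%s\tedmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, s, e, strand, gene),
      sprintf("%s\tedmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom, s, e, strand, id, gene),
      sprintf("%s\tedmap\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              chrom, GenomicRanges::start(gr), GenomicRanges::end(gr), strand,
              id, seq_along(gr), id)), con)
  }
  invisible(path)
}

#' Read pooled variant calls from VCF
#'
#' Reads a VCF with per-sample allele depths (FORMAT field \code{AD}) for the
#' two phenotype pools into a [VariantPanel]. Only biallelic SNP records are
#' kept; multiallelic and indel records, and records without AD, are skipped
#' and counted in the \code{skipped} attribute of the result.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param mutSample,wtSample Sample names of the mutant- and wild-type-pool
#'   columns.
#' @return A [VariantPanel]; \code{attr(, "skipped")} holds skip counts by
#'   reason.
#' @export
readPooledVcf <- function(path, mutSample = "mut", wtSample = "wt") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  smp <- colnames(vcf)
  for (s in c(mutSample, wtSample))
    if (!s %in% smp)
      stop(sprintf("sample '%s' not present in VCF (found: %s)",
                   s, paste(smp, collapse = ", ")))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- rr$ALT
  nAlt <- lengths(altL)
  alt1 <- rep(NA_character_, length(rr))
  one <- nAlt == 1L
  alt1[one] <- as.character(unlist(altL[one]))
  multi <- nAlt > 1L
  snp <- one & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% .ACGT & alt1 %in% .ACGT
  indel <- one & !snp
  if (!"AD" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no AD FORMAT field")
  ad <- VariantAnnotation::geno(vcf)$AD
  # readVcf returns AD either as a list-matrix or, when all records have the
  # same allele count, as a 3D array
  adAt <- function(i, smp) {
    if (length(dim(ad)) == 3L) ad[i, smp, ] else ad[[i, smp]]
  }
  hasAD <- vapply(seq_len(nrow(ad)), function(i) {
    a <- adAt(i, mutSample); b <- adAt(i, wtSample)
    length(a) >= 2L && length(b) >= 2L && !anyNA(a[1:2]) && !anyNA(b[1:2])
  }, logical(1))
  keep <- snp & hasAD
  skipped <- c(multiallelic = sum(multi), indel = sum(indel),
               no_ad = sum(snp & !hasAD))
  if (sum(skipped) > 0)
    message(sprintf("readPooledVcf: skipped %d record(s) (%s)", sum(skipped),
                    paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  idx <- which(keep)
  n <- length(idx)
  mut <- wt <- matrix(0L, n, 4L, dimnames = list(NULL, .ACGT))
  for (k in seq_len(n)) {
    i <- idx[k]
    a <- adAt(i, mutSample); b <- adAt(i, wtSample)
    mut[k, ref[i]] <- as.integer(a[1]); mut[k, alt1[i]] <- as.integer(a[2])
    wt[k, ref[i]] <- as.integer(b[1]); wt[k, alt1[i]] <- as.integer(b[2])
  }
  panel <- methods::new("VariantPanel",
    sites = data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[idx],
                       pos = GenomicRanges::start(rr)[idx],
                       ref = ref[idx], alt = alt1[idx],
                       stringsAsFactors = FALSE),
    mutCounts = mut, wtCounts = wt)
  attr(panel, "skipped") <- skipped
  panel
}

#' Write pooled variant calls to VCF
#'
#' Emits a VCF v4.2 with samples \code{mut} and \code{wt} and FORMAT fields
#' \code{AD} (ref,alt read counts) and \code{DP} (total base counts). Reads
#' observed at bases other than ref/alt (sequencing error) are included in DP
#' but not AD.
#'
#' @param panel A [VariantPanel].
#' @param path Output path.
#' @param chromLengths Optional named vector for \code{##contig} header lines.
#' @return The path, invisibly.
#' @export
writePooledVcf <- function(panel, path, chromLengths = NULL) {
  stopifnot(methods::is(panel, "VariantPanel"))
  s <- panel@sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=edmap")
  if (!is.null(chromLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                          as.integer(chromLengths)))
  hdr <- c(hdr,
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read counts for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth over all bases\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmut\twt")
  ridx <- match(s$ref, .ACGT); aidx <- match(s$alt, .ACGT)
  n <- nrow(s)
  take <- function(m, j) m[cbind(seq_len(n), j)]
  recs <- if (n == 0) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
    s$chrom, s$pos, s$ref, s$alt,
    take(panel@mutCounts, ridx), take(panel@mutCounts, aidx),
    rowSums(panel@mutCounts),
    take(panel@wtCounts, ridx), take(panel@wtCounts, aidx),
    rowSums(panel@wtCounts))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write candidate intervals to BED6
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention (\code{start_bed = start - 1}, \code{end_bed = end}).
#' The score column is the interval's peak fitted ED scaled to [0, 1000]
#' (1000 corresponds to the biallelic maximum sqrt(2)).
#'
#' @param intervals A \link[GenomicRanges]{GRanges} of candidate intervals as
#'   returned by [candidateIntervals()] (metadata columns \code{peakPos},
#'   \code{peakEd}, \code{nSites}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeIntervalsBed <- function(intervals, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (length(intervals) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  o <- order(as.character(GenomicRanges::seqnames(intervals)),
             GenomicRanges::start(intervals))
  intervals <- intervals[o]
  peakEd <- S4Vectors::mcols(intervals)$peakEd
  if (is.null(peakEd)) peakEd <- rep(0, length(intervals))
  score <- pmin(1000L, pmax(0L, as.integer(round(1000 * peakEd / sqrt(2)))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   as.character(GenomicRanges::seqnames(intervals)),
                   GenomicRanges::start(intervals) - 1L,
                   GenomicRanges::end(intervals),
                   sprintf("interval_%d", seq_along(intervals)), score)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read and write fine-mapping marker tables
#'
#' The marker map TSV has columns \code{marker}, \code{chrom}, \code{pos}
#' (bp, strictly increasing within a chromosome). The genotype TSV has columns
#' \code{id}, \code{phenotype} (WT/INT/MUT), then one column per marker with
#' values A/H/B/NA.
#'
#' @param path File path.
#' @return \code{readMarkerMap}: a data.frame \code{marker}, \code{chrom},
#'   \code{pos}. \code{readMarkerGenotypes}: a list with \code{ids},
#'   \code{phenotype} and the genotype \code{matrix}.
#' @name marker-io
NULL

#' @rdname marker-io
#' @export
readMarkerMap <- function(path) {
  mm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(mm)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mm$marker)) stop("marker ids must be unique")
  bad <- vapply(split(mm$pos, mm$chrom),
                function(p) is.unsorted(p, strictly = TRUE), logical(1))
  if (any(bad)) stop("marker positions must be strictly increasing within chromosome")
  mm
}

#' @rdname marker-io
#' @param map A marker map data.frame.
#' @export
writeMarkerMap <- function(map, path) {
  utils::write.table(map[, c("marker", "chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname marker-io
#' @export
readMarkerGenotypes <- function(path) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("id", "phenotype") %in% names(gt)))
    stop("genotype table must have columns id, phenotype, then one per marker")
  markers <- setdiff(names(gt), c("id", "phenotype"))
  g <- as.matrix(gt[, markers, drop = FALSE])
  g[g %in% c("NA", "")] <- NA_character_
  bad <- !is.na(g) & !g %in% .GENO_CODES
  if (any(bad)) stop("genotype codes must be A, H, B or NA")
  list(ids = gt$id, phenotype = gt$phenotype, matrix = g)
}

#' @rdname marker-io
#' @param ids,phenotype,geno Individual ids, phenotype classes, and the
#'   individuals x markers genotype matrix (colnames = marker ids).
#' @export
writeMarkerGenotypes <- function(ids, phenotype, geno, path) {
  df <- data.frame(id = ids, phenotype = phenotype, geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
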