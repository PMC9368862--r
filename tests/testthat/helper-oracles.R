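# Shared fixtures and independent oracles used across the suite.

ACGT <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# independent translation: split into triplets and look codons up one by one
oracleTranslate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# brute-force coding-change oracle: mutate the full CDS string, translate both,
# and diff the proteins
oracleCodingChange <- function(cdsSeq, codingPos, altCoding) {
  mutated <- cdsSeq
  substring(mutated, codingPos, codingPos) <- altCoding
  pBefore <- oracleTranslate(cdsSeq)
  pAfter <- oracleTranslate(mutated)
  codonIdx <- (codingPos - 1) %/% 3 + 1
  before <- substring(pBefore, codonIdx, codonIdx)
  after <- substring(pAfter, codonIdx, codonIdx)
  codonBefore <- substring(cdsSeq, 3 * codonIdx - 2, 3 * codonIdx)
  effect <-
    if (before == after) "synonymous"
    else if (after == "*") "nonsense"
    else if (before == "*") "stop_loss"
    else if (codonIdx == 1 && codonBefore == "ATG") "start_loss"
    else "missense"
  list(proteinPos = as.integer(codonIdx), residueBefore = before,
       residueAfter = after, effect = effect)
}

# independent chi-square by explicit summation
oracleChisq <- function(observed, ratio) {
  expected <- sum(observed) * ratio / sum(ratio)
  total <- 0
  for (i in seq_along(observed))
    total <- total + (observed[i] - expected[i])^2 / expected[i]
  total
}

# small variant panel from explicit per-pool count matrices
makePanel <- function(pos, ref, alt, mut, wt, chrom = "chr1") {
  colnames(mut) <- colnames(wt) <- ACGT
  new("VariantPanel",
      sites = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt, stringsAsFactors = FALSE),
      mutCounts = mut, wtCounts = wt)
}

# panel with a single biallelic site built from ref/alt counts
makeBiallelicPanel <- function(refCounts, altCounts, ref = "C", alt = "T") {
  n <- length(refCounts$mut)
  mut <- wt <- matrix(0L, n, 4, dimnames = list(NULL, ACGT))
  mut[, ref] <- refCounts$mut; mut[, alt] <- altCounts$mut
  wt[, ref] <- refCounts$wt; wt[, alt] <- altCounts$wt
  makePanel(seq_len(n) * 100L, rep(ref, n), rep(alt, n), mut, wt)
}

# one-model GeneModels object
makeGene <- function(starts, ends, strand = "+", chrom = "chr1",
                     id = "m1", gene = "g1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  cds <- methods::as(stats::setNames(list(gr), id), "CompressedGRangesList")
  edmap:::.newGeneModels(cds, gene)
}

# genome string for a single-CDS gene whose coding sequence is 'coding',
# embedded at 'at' (plus strand) within random padding
embedCoding <- function(coding, at = 11L, totalLen = 200L, strand = "+",
                        seed = 1L) {
  withr::with_seed(seed, {
    g <- sample(ACGT, totalLen, replace = TRUE)
    insert <- if (strand == "+") coding else revcomp(coding)
    g[at:(at + nchar(coding) - 1L)] <- strsplit(insert, "")[[1]]
    paste(g, collapse = "")
  })
}

smallConfig <- function(seed = 1L, ...) {
  simulationConfig(chromLengths = c(chr1 = 2e6), nSnps = 400L, nGenes = 40L,
                   markerSpacingBp = 1e5, seed = as.integer(seed), ...)
}
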