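# Synthetic-data generator: genomes, gene models, EMS variant spectra, F2
# cohorts (selfed heterozygote for the pooled scan; biparental cross for fine
# mapping), phenotype-selected pools and pooled read counts. All stochastic
# steps honour an explicit seed and are pure functions of (config, seed).

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# standard nuclear codon table, keyed by codon
.codonTable <- function() Biostrings::GENETIC_CODE

# preferred codon per amino acid used when planting protein motifs
.AA_CODON <- c(G = "GGA", W = "TGG", P = "CCA", V = "GTT", A = "GCT",
               R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
               E = "GAA", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
               M = "ATG", F = "TTT", S = "TCT", T = "ACT", Y = "TAT")

.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# deterministic per-stage child seeds from one global seed (documented LCG step)
.childSeed <- function(seed, stage) {
  if (is.null(seed) || is.na(seed)) return(NA_integer_)
  as.integer((1103515245 * (as.double(seed) %% 65536) + 12345 + stage) %%
               2147483647)
}

#' Build a synthetic study configuration
#'
#' Defaults reproduce the pooled-mapping study design the package targets: a
#' single EMS-mutagenized semi-dominant locus segregating in the selfed progeny
#' of heterozygous plants; 20 mutant-phenotype and 20 wild-type plants pooled;
#' mean pooled depth 38x; a causal C-to-T missense change planted in a
#' "GWPPV"-motif gene; and a separate 185-plant biparental F2 with 13 ordered
#' markers for fine mapping.
#'
#' @param chromLengths Named chromosome lengths in bp.
#' @param nSnps Number of EMS SNPs, including the single causal SNP.
#' @param nGenes Number of non-overlapping gene models to place.
#' @param poolSize Individuals per phenotype pool.
#' @param depth Mean pooled depth per site per pool (Poisson mean).
#' @param errorRate Per-base sequencing error rate; a misread base is replaced
#'   by each of the 3 other bases with probability errorRate/3.
#' @param cmPerMb Uniform recombination rate in cM/Mb.
#' @param mode Inheritance mode of the causal allele.
#' @param cohortSize Selfed MutMap+ cohort size (must comfortably exceed what
#'   the two pools need; 1:2:1 segregation leaves ~cohortSize/4 per homozygous
#'   class).
#' @param f2Size Biparental fine-mapping F2 size.
#' @param nMarkers Number of fine-mapping markers.
#' @param markerSpacingBp Spacing of the fine-mapping marker grid.
#' @param emsBias Probability that a background SNP is an EMS-type transition
#'   (C>T or G>A on the plus strand).
#' @param motif Protein motif planted into one gene; the causal SNP hits a
#'   proline inside it.
#' @param maxRetries Resimulation attempts when a cohort lacks pool-size
#'   individuals of a needed phenotype class.
#' @param seed Integer seed; NA leaves the RNG stream untouched.
#' @return A [SimulationConfig].
#' @examples
#' simulationConfig(chromLengths = c(chr1 = 1e6), nSnps = 200, nGenes = 20)
#' @export
simulationConfig <- function(chromLengths = c(chr1 = 1e7),
                             nSnps = 2000L, nGenes = 200L, poolSize = 20L,
                             depth = 38, errorRate = 0.005, cmPerMb = 4,
                             mode = "semi-dominant", cohortSize = 120L,
                             f2Size = 185L, nMarkers = 13L,
                             markerSpacingBp = 250000, emsBias = 0.9,
                             motif = "GWPPV", maxRetries = 10L,
                             seed = NA_integer_) {
  methods::new("SimulationConfig", chromLengths = chromLengths,
               nSnps = as.integer(nSnps), nGenes = as.integer(nGenes),
               poolSize = as.integer(poolSize), depth = depth,
               errorRate = errorRate, cmPerMb = cmPerMb, mode = mode,
               cohortSize = as.integer(cohortSize), f2Size = as.integer(f2Size),
               nMarkers = as.integer(nMarkers),
               markerSpacingBp = markerSpacingBp, emsBias = emsBias,
               motif = motif, maxRetries = as.integer(maxRetries),
               seed = as.integer(seed))
}

# Map a coding-strand position to its genomic position, given sorted CDS
# segments (starts/ends) and strand.
.codingToGenomic <- function(starts, ends, strand, codingPos) {
  w <- ends - starts + 1L
  if (strand == "+") {
    cum <- cumsum(w)
    seg <- findInterval(codingPos - 1L, c(0L, cum), rightmost.closed = FALSE)
    starts[seg] + (codingPos - c(0L, cum)[seg] - 1L)
  } else {
    wr <- rev(w); cum <- cumsum(wr)
    seg <- findInterval(codingPos - 1L, c(0L, cum), rightmost.closed = FALSE)
    ir <- length(w) - seg + 1L
    ends[ir] - (codingPos - c(0L, cum)[seg] - 1L)
  }
}

# Inverse: genomic position -> coding-strand position (pos must be in a CDS).
.genomicToCoding <- function(starts, ends, strand, pos) {
  seg <- which(pos >= starts & pos <= ends)
  if (length(seg) != 1L) return(NA_integer_)
  w <- ends - starts + 1L
  if (strand == "+") {
    sum(w[seq_len(seg - 1L)]) + (pos - starts[seg] + 1L)
  } else {
    k <- length(w)
    before <- if (seg < k) sum(w[(seg + 1L):k]) else 0L
    before + (ends[seg] - pos + 1L)
  }
}

#' Simulate a reference genome and gene models
#'
#' Generates uniform-composition random chromosomes and places
#' \code{nGenes} non-overlapping gene models (2-6 CDS segments each, random
#' strand, total CDS length divisible by 3). Exactly one gene has the
#' configured protein motif planted into its translation, so that downstream
#' motif checks have a guaranteed target.
#'
#' @param config A [SimulationConfig].
#' @param seed Integer seed (defaults to the config seed).
#' @return A list with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{genes} ([GeneModels]).
#' @export
simulateReferenceAndGenes <- function(config, seed = config@seed) {
  .withSeed(seed, {
    rawBases <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
    chroms <- lapply(config@chromLengths, function(len)
      rawBases[sample.int(4L, len, replace = TRUE)])
    # distribute genes over chromosomes proportional to length
    nPer <- .apportion(config@nGenes, config@chromLengths)
    ids <- sprintf("mRNA%04d", seq_len(config@nGenes))
    genes <- sprintf("gene%04d", seq_len(config@nGenes))
    allGr <- vector("list", config@nGenes)
    gi <- 0L
    for (ci in seq_along(chroms)) {
      n <- nPer[ci]
      if (n == 0L) next
      len <- config@chromLengths[ci]
      plans <- lapply(seq_len(n), .planGene)
      foot <- vapply(plans, function(p) p$footprint, numeric(1))
      slack <- len - sum(foot)
      if (slack < n + 1L)
        stop("generation error: chromosome ", names(chroms)[ci],
             " too short for ", n, " gene models")
      gaps <- .randomPartition(slack, n + 1L)
      at <- 1L + cumsum(gaps[seq_len(n)]) +
        c(0L, cumsum(foot[-n]))  # footprints of the genes already placed
      for (k in seq_len(n)) {
        gi <- gi + 1L
        p <- plans[[k]]
        starts <- at[k] + p$relStarts
        ends <- starts + p$segLens - 1L
        allGr[[gi]] <- GenomicRanges::GRanges(
          names(chroms)[ci], IRanges::IRanges(starts, ends),
          strand = sample(c("+", "-"), 1L))
      }
    }
    cds <- methods::as(stats::setNames(allGr, ids), "CompressedGRangesList")
    models <- .newGeneModels(cds, genes)
    # plant the motif into one randomly chosen translatable gene
    target <- sample(length(models), 1L)
    chroms <- .plantMotif(chroms, models, target, config@motif)
    genome <- Biostrings::DNAStringSet(vapply(chroms, rawToChar, character(1)))
    prot <- translateGeneModel(models, names(cds)[target], genome)
    if (!grepl(config@motif, prot, fixed = TRUE))
      stop("generation error: motif could not be planted in any gene")
    list(genome = genome, genes = models)
  })
}

# split n into parts proportional to weights, summing exactly to n
.apportion <- function(n, weights) {
  p <- weights / sum(weights)
  out <- floor(n * p)
  rem <- n - sum(out)
  if (rem > 0) {
    o <- order(n * p - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
  }
  as.integer(out)
}

# random composition of 'total' into 'k' non-negative parts
.randomPartition <- function(total, k) {
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total + 1L, k - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, total))
}

# plan one gene: 2-6 CDS segments, 100-400 codons, introns 80-500 bp
.planGene <- function(ignored) {
  nSeg <- sample(2:6, 1L)
  aa <- sample(100:400, 1L)
  cdsLen <- 3L * aa
  segLens <- .randomPartition(cdsLen - 3L * nSeg, nSeg) + 3L
  introns <- sample(80:500, nSeg - 1L, replace = TRUE)
  relStarts <- cumsum(c(0L, segLens[-nSeg] + introns))
  list(segLens = as.integer(segLens), relStarts = as.integer(relStarts),
       footprint = sum(segLens) + sum(introns))
}

# overwrite genome bases so that the target model's translation contains the
# motif (codons written strand-aware)
.plantMotif <- function(chroms, models, target, motif) {
  gr <- models@cds[[target]]
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  aaLen <- sum(ends - starts + 1L) %/% 3L
  aaChars <- strsplit(motif, "")[[1]]
  if (any(!aaChars %in% names(.AA_CODON)))
    stop("generation error: motif has unsupported residues")
  if (aaLen < length(aaChars) + 4L)
    stop("generation error: motif longer than the target protein")
  aaStart <- sample(seq(3L, aaLen - length(aaChars) - 1L), 1L)
  codingPos <- (3L * (aaStart - 1L) + 1L):(3L * (aaStart + length(aaChars) - 1L))
  codingBase <- strsplit(paste(.AA_CODON[aaChars], collapse = ""), "")[[1]]
  gpos <- vapply(codingPos, function(cp)
    .codingToGenomic(starts, ends, strand, cp), numeric(1))
  if (strand == "-") codingBase <- unname(.COMPLEMENT[codingBase])
  chroms[[chrom]][gpos] <- charToRaw(paste(codingBase, collapse = ""))
  chroms
}

#' Simulate EMS-induced variant sites
#'
#' Draws \code{nSnps - 1} background SNPs with the EMS mutational bias (with
#' probability \code{emsBias} a C>T or G>A transition on the plus strand,
#' otherwise a random substitution) plus exactly one causal SNP: a C>T change
#' at the second base of a proline codon (CCx>CTx) inside the motif occurrence
#' of the motif-bearing gene, the canonical Pro-to-Leu degron lesion.
#'
#' @param config A [SimulationConfig].
#' @param genome \link[Biostrings]{DNAStringSet} from
#'   [simulateReferenceAndGenes()].
#' @param genes The matching [GeneModels].
#' @param seed Integer seed.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{causal}; sorted by chromosome and position.
#' @export
simulateEmsVariants <- function(config, genome, genes, seed = config@seed) {
  .withSeed(seed, {
    chromStr <- stats::setNames(as.character(genome), names(genome))
    causal <- .placeCausalSnp(config, genome, genes, chromStr)
    nBg <- config@nSnps - 1L
    lens <- Biostrings::width(genome)
    names(lens) <- names(genome)
    nPer <- .apportion(nBg, lens)
    rows <- vector("list", length(lens) + 1L)
    for (ci in seq_along(lens)) {
      n <- nPer[ci]
      if (n == 0L) next
      chrom <- names(lens)[ci]
      forbidden <- if (chrom == causal$chrom) causal$pos else integer(0)
      # fix the biased/unbiased split first, then sample positions for each
      # class, so that the realized transition fraction is Binomial(n, bias)
      nBiased <- sum(stats::runif(n) < config@emsBias)
      drawPositions <- function(need, wantCG) {
        out <- integer(0); ref <- character(0)
        while (length(out) < need) {
          cand <- sample.int(lens[ci], 4L * (need - length(out)) + 8L,
                             replace = TRUE)
          cand <- setdiff(unique(cand), c(forbidden, out))
          refc <- substring(chromStr[chrom], cand, cand)
          if (wantCG) {
            keep <- refc %in% c("C", "G")
            cand <- cand[keep]; refc <- refc[keep]
          }
          take <- seq_len(min(need - length(out), length(cand)))
          out <- c(out, cand[take]); ref <- c(ref, refc[take])
        }
        list(pos = out, ref = ref)
      }
      bi <- drawPositions(nBiased, wantCG = TRUE)
      un <- drawPositions(n - nBiased, wantCG = FALSE)
      # unbiased positions must not collide with biased ones
      dup <- un$pos %in% bi$pos
      while (any(dup)) {
        redo <- drawPositions(sum(dup), wantCG = FALSE)
        un$pos[dup] <- redo$pos; un$ref[dup] <- redo$ref
        dup <- un$pos %in% bi$pos | duplicated(un$pos)
      }
      altBi <- ifelse(bi$ref == "C", "T", "A")
      altUn <- vapply(un$ref, function(b) sample(setdiff(.ACGT, b), 1L),
                      character(1))
      rows[[ci]] <- data.frame(chrom = chrom,
                               pos = c(bi$pos, un$pos),
                               ref = c(bi$ref, un$ref),
                               alt = c(altBi, unname(altUn)), causal = FALSE,
                               stringsAsFactors = FALSE)
    }
    rows[[length(lens) + 1L]] <- data.frame(
      chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
      alt = causal$alt, causal = TRUE, stringsAsFactors = FALSE)
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# locate the motif gene and the genomic coordinates of a C>T lesion at the
# second base of a proline codon inside the motif occurrence
.placeCausalSnp <- function(config, genome, genes, chromStr) {
  motif <- config@motif
  hit <- NULL
  translatable <- isTranslatable(genes)
  for (id in geneIds(genes)) {
    if (!translatable[[id]]) next
    prot <- translateGeneModel(genes, id, chromStr)
    occ <- regexpr(motif, prot, fixed = TRUE)
    if (occ > 0) { hit <- list(id = id, occ = as.integer(occ), prot = prot); break }
  }
  if (is.null(hit))
    stop("generation error: no gene translation contains motif ", motif)
  aaChars <- strsplit(motif, "")[[1]]
  pIdx <- which(aaChars == "P")
  if (!length(pIdx))
    stop("generation error: no proline codon available in the motif gene")
  aaPos <- hit$occ + pIdx[1] - 1L  # first proline of the occurrence
  gr <- genes@cds[[hit$id]]
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  codingPos <- 3L * (aaPos - 1L) + 2L  # second base of the proline codon
  gpos <- .codingToGenomic(starts, ends, strand, codingPos)
  ref <- substring(chromStr[chrom], gpos, gpos)
  expected <- if (strand == "+") "C" else "G"
  if (ref != expected)
    stop("generation error: proline codon does not expose a C at base 2")
  alt <- if (strand == "+") "T" else "A"
  list(chrom = chrom, pos = as.integer(gpos), ref = ref, alt = alt,
       gene = hit$id, proteinPos = aaPos)
}

# one gamete per row: 0 = wild homolog, 1 = mutant homolog, at each locus.
# Crossover count ~ Poisson(chromosome length in Morgans), positions uniform;
# the implied recombination fraction between loci follows Haldane's map
# function r = (1 - exp(-2d))/2.
.simGametes <- function(nGametes, lociM, chromLenM) {
  out <- matrix(0L, nGametes, length(lociM))
  for (g in seq_len(nGametes)) {
    nco <- stats::rpois(1L, chromLenM)
    startHom <- sample(0:1, 1L)
    if (nco == 0L) { out[g, ] <- startHom; next }
    cuts <- sort(stats::runif(nco, 0, chromLenM))
    out[g, ] <- (startHom + findInterval(lociM, cuts)) %% 2L
  }
  out
}

#' Map phenotype class from causal genotype
#'
#' Semi-dominant: A>WT, H>INT, B>MUT. Dominant: A>WT, H or B>MUT. Recessive:
#' A or H>WT, B>MUT.
#'
#' @param geno Character vector of genotype codes A/H/B (NA passed through).
#' @param mode Inheritance mode.
#' @return Character vector of phenotype classes WT/INT/MUT.
#' @examples
#' phenotypeFromGenotype(c("A", "H", "B"), "semi-dominant")
#' @export
phenotypeFromGenotype <- function(geno, mode) {
  if (!mode %in% .MODES)
    stop("configuration error: unknown inheritance mode '", mode, "'")
  bad <- !is.na(geno) & !geno %in% .GENO_CODES
  if (any(bad)) stop("genotype codes must be A, H or B")
  map <- switch(mode,
    "semi-dominant" = c(A = "WT", H = "INT", B = "MUT"),
    "dominant"      = c(A = "WT", H = "MUT", B = "MUT"),
    "recessive"     = c(A = "WT", H = "WT", B = "MUT"))
  out <- unname(map[geno])
  out[is.na(geno)] <- NA_character_
  out
}

#' Simulate a selfed-heterozygote F2 cohort
#'
#' Each individual is the union of two gametes of a parent heterozygous at
#' every supplied locus, with the EMS alleles in coupling on one homolog.
#' Gametes carry Poisson-distributed crossovers with uniform positions, so the
#' recombination fraction between loci follows Haldane's map function.
#' Phenotypes are assigned from the causal genotype under the configured
#' inheritance mode.
#'
#' @param config A [SimulationConfig].
#' @param loci data.frame with columns \code{chrom}, \code{pos}, sorted by
#'   position within chromosome.
#' @param causal Index of the causal locus in \code{loci}.
#' @param n Number of individuals (defaults to \code{config@cohortSize}).
#' @param seed Integer seed.
#' @return An [F2Cohort].
#' @export
simulateF2Cohort <- function(config, loci, causal, n = config@cohortSize,
                             seed = config@seed) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)),
            causal >= 1L, causal <= nrow(loci))
  bad <- vapply(split(loci$pos, loci$chrom),
                function(p) is.unsorted(p, strictly = TRUE), logical(1))
  if (any(bad)) stop("loci must be sorted and unique within chromosome")
  .withSeed(seed, {
    dose <- matrix(0L, n, nrow(loci))
    for (chrom in unique(loci$chrom)) {
      idx <- which(loci$chrom == chrom)
      lenBp <- config@chromLengths[[chrom]]
      if (is.null(lenBp) || is.na(lenBp))
        stop("locus chromosome not in config: ", chrom)
      chromLenM <- lenBp * config@cmPerMb / 1e8
      lociM <- loci$pos[idx] * config@cmPerMb / 1e8
      g1 <- .simGametes(n, lociM, chromLenM)
      g2 <- .simGametes(n, lociM, chromLenM)
      dose[, idx] <- g1 + g2
    }
    geno <- matrix(c("A", "H", "B")[dose + 1L], nrow = n)
    methods::new("F2Cohort",
                 loci = loci[, c("chrom", "pos")], geno = geno,
                 phenotype = phenotypeFromGenotype(geno[, causal], config@mode),
                 causal = as.integer(causal), mode = config@mode)
  })
}

#' Pool extreme phenotypes and simulate pooled read counts
#'
#' Selects \code{poolSize} individuals of class MUT and \code{poolSize} of
#' class WT, computes each pool's alt-allele frequency at every variant site
#' (alt alleles among \code{2 * poolSize} chromosomes), then draws per-site
#' per-pool depth ~ Poisson(depth) and read bases from a symmetric
#' substitution-error model: a read reports the alt allele with probability
#' \code{f (1 - e) + (1 - f) e/3}, the ref allele with the mirrored
#' probability, and each other base with probability e/3.
#'
#' @param cohort An [F2Cohort] whose loci are the variant positions.
#' @param variants data.frame from [simulateEmsVariants()] (row order must
#'   match the cohort loci).
#' @param config A [SimulationConfig].
#' @param seed Integer seed.
#' @return A [VariantPanel]; sites where a pool drew depth 0 carry zero counts
#'   and are expected to be removed by [filterSites()].
#' @export
buildPoolsAndReads <- function(cohort, variants, config, seed = config@seed) {
  stopifnot(nrow(variants) == nrow(cohort@loci),
            all(variants$pos == cohort@loci$pos),
            all(variants$chrom == cohort@loci$chrom))
  phen <- phenotypes(cohort)
  nMut <- sum(phen == "MUT"); nWt <- sum(phen == "WT")
  if (nMut < config@poolSize || nWt < config@poolSize)
    stop(sprintf(
      "generation error: cohort has %d MUT and %d WT individuals; need %d of each",
      nMut, nWt, config@poolSize))
  .withSeed(seed, {
    mutIdx <- sample(which(phen == "MUT"), config@poolSize)
    wtIdx <- sample(which(phen == "WT"), config@poolSize)
    dose <- (cohort@geno == "H") + 2L * (cohort@geno == "B")
    fMut <- colSums(dose[mutIdx, , drop = FALSE]) / (2 * config@poolSize)
    fWt <- colSums(dose[wtIdx, , drop = FALSE]) / (2 * config@poolSize)
    n <- nrow(variants)
    e <- config@errorRate
    drawPool <- function(f) {
      depth <- stats::rpois(n, config@depth)
      counts <- matrix(0L, n, 4L, dimnames = list(NULL, .ACGT))
      ridx <- match(variants$ref, .ACGT); aidx <- match(variants$alt, .ACGT)
      for (i in seq_len(n)) {
        if (depth[i] == 0L) next
        p <- rep(e / 3, 4L)
        p[aidx[i]] <- f[i] * (1 - e) + (1 - f[i]) * e / 3
        p[ridx[i]] <- (1 - f[i]) * (1 - e) + f[i] * e / 3
        counts[i, ] <- stats::rmultinom(1L, depth[i], p)
      }
      counts
    }
    methods::new("VariantPanel",
                 sites = variants[, c("chrom", "pos", "ref", "alt")],
                 mutCounts = drawPool(fMut), wtCounts = drawPool(fWt))
  })
}

#' Simulate the full MutMap+ pooled-sequencing experiment
#'
#' Convenience wrapper running the generator end to end with per-stage child
#' seeds: reference + genes, EMS variants, the selfed F2 cohort (resimulated
#' up to \code{maxRetries} times when a pooled phenotype class is short), and
#' pooled read counts.
#'
#' @param config A [SimulationConfig].
#' @param seed Integer seed (defaults to the config seed).
#' @return A list: \code{genome}, \code{genes}, \code{variants},
#'   \code{cohort}, \code{panel}, and \code{truth} (causal chrom/pos/gene).
#' @export
simulateMutmapExperiment <- function(config, seed = config@seed) {
  ref <- simulateReferenceAndGenes(config, seed = .childSeed(seed, 1L))
  variants <- simulateEmsVariants(config, ref$genome, ref$genes,
                                  seed = .childSeed(seed, 2L))
  causal <- which(variants$causal)
  cohort <- NULL
  for (attempt in seq_len(config@maxRetries)) {
    cand <- simulateF2Cohort(config, variants[, c("chrom", "pos")], causal,
                             seed = .childSeed(seed, 2L + attempt))
    tab <- table(factor(phenotypes(cand), levels = .PHENO_CLASSES))
    if (tab["MUT"] >= config@poolSize && tab["WT"] >= config@poolSize) {
      cohort <- cand
      break
    }
  }
  if (is.null(cohort))
    stop(sprintf("generation error after %d attempts: last cohort had %s",
                 config@maxRetries,
                 paste(names(tab), tab, sep = "=", collapse = ", ")))
  panel <- buildPoolsAndReads(cohort, variants, config,
                              seed = .childSeed(seed, 20L))
  causalGene <- .geneAt(ref$genes, variants$chrom[causal], variants$pos[causal])
  list(genome = ref$genome, genes = ref$genes, variants = variants,
       cohort = cohort, panel = panel,
       truth = list(chrom = variants$chrom[causal], pos = variants$pos[causal],
                    gene = causalGene))
}

.geneAt <- function(genes, chrom, pos) {
  spans <- geneSpans(genes)
  hit <- which(as.character(GenomicRanges::seqnames(spans)) == chrom &
                 GenomicRanges::start(spans) <= pos &
                 GenomicRanges::end(spans) >= pos)
  if (length(hit)) names(spans)[hit[1]] else NA_character_
}

#' Simulate a biparental fine-mapping F2 cross
#'
#' Both parents are homozygous for opposite alleles at every marker and at the
#' causal locus; the F1 is selfed, gametes are generated by the same Haldane
#' crossover process as [simulateF2Cohort()], and phenotypes follow the causal
#' genotype. By default markers sit on a regular grid of
#' \code{markerSpacingBp} spanning \code{nMarkers} positions around the causal
#' locus (shifted to fit the chromosome); the causal locus always lies
#' strictly between two markers.
#'
#' @param config A [SimulationConfig].
#' @param causalPos Causal position in bp.
#' @param chrom Chromosome of the causal locus.
#' @param markerPositions Optional explicit marker positions (bp).
#' @param seed Integer seed.
#' @return A list: \code{markerMap} (data.frame marker/chrom/pos) and
#'   \code{cohort} (an [F2Cohort] whose loci are the markers plus the causal
#'   locus, \code{causalLocus()} giving its index).
#' @export
simulateFinemapCross <- function(config, causalPos,
                                 chrom = names(config@chromLengths)[1],
                                 markerPositions = NULL, seed = config@seed) {
  lenBp <- config@chromLengths[[chrom]]
  if (is.null(markerPositions)) {
    k <- config@nMarkers
    sp <- config@markerSpacingBp
    span <- (k - 1) * sp
    if (span >= lenBp)
      stop("configuration error: marker grid (", span,
           " bp) does not fit on chromosome ", chrom)
    left <- causalPos - (span / 2 + sp / 2)
    left <- max(1, min(left, lenBp - span))
    markerPositions <- round(left + (seq_len(k) - 1) * sp)
    coincide <- markerPositions == causalPos
    if (any(coincide))
      markerPositions[coincide] <- markerPositions[coincide] + 1
  }
  markerPositions <- sort(as.integer(markerPositions))
  if (any(markerPositions < 1) || any(markerPositions > lenBp))
    stop("configuration error: marker positions outside chromosome ", chrom)
  if (causalPos <= min(markerPositions) || causalPos >= max(markerPositions))
    stop("configuration error: causal locus must lie strictly between markers")
  if (any(markerPositions == causalPos))
    stop("configuration error: a marker coincides with the causal locus")
  loci <- data.frame(chrom = chrom, pos = sort(c(markerPositions, causalPos)))
  causal <- which(loci$pos == causalPos)
  cohort <- simulateF2Cohort(config, loci, causal, n = config@f2Size,
                             seed = seed)
  mIdx <- setdiff(seq_len(nrow(loci)), causal)
  markerMap <- data.frame(
    marker = sprintf("M%02d", seq_along(mIdx)),
    chrom = chrom, pos = loci$pos[mIdx], stringsAsFactors = FALSE)
  list(markerMap = markerMap, cohort = cohort)
}
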