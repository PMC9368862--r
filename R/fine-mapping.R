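# Recombinant-breakpoint fine mapping: narrow the causal interval from ordered
# marker genotypes and phenotype classes, and intersect with the BSA interval.

#' Genotypes compatible with a phenotype class
#'
#' Under a semi-dominant locus the phenotype determines the causal genotype
#' uniquely (WT>A, INT>H, MUT>B); dominant and recessive modes leave one class
#' ambiguous (dominant MUT is H or B; recessive WT is A or H). The INT class
#' does not exist under dominant or recessive inheritance.
#'
#' @param phenotype A phenotype class: \code{"WT"}, \code{"INT"} or
#'   \code{"MUT"}.
#' @param mode Inheritance mode.
#' @return Character vector: the compatible genotype codes.
#' @examples
#' expectedCausalGenotypes("INT", "semi-dominant")
#' @export
expectedCausalGenotypes <- function(phenotype, mode) {
  if (!mode %in% .MODES)
    stop("configuration error: unknown inheritance mode '", mode, "'")
  if (!phenotype %in% .PHENO_CLASSES)
    stop("unknown phenotype class '", phenotype, "'")
  sets <- switch(mode,
    "semi-dominant" = list(WT = "A", INT = "H", MUT = "B"),
    "dominant"      = list(WT = "A", MUT = c("H", "B")),
    "recessive"     = list(WT = c("A", "H"), MUT = "B"))
  out <- sets[[phenotype]]
  if (is.null(out))
    stop("input error: phenotype class ", phenotype,
         " does not occur under ", mode, " inheritance")
  out
}

#' Find recombinants between two flanking markers
#'
#' An individual is a recombinant iff its genotype at either flanking marker
#' falls outside its phenotype's compatibility set, or the two marker
#' genotypes differ from each other. Missing genotypes (NA) are
#' non-informative and never trigger either test.
#'
#' @param genoLeft,genoRight Genotype codes (A/H/B/NA) at the left and right
#'   flanking marker, one per individual.
#' @param phenotypes Phenotype classes, one per individual.
#' @param mode Inheritance mode.
#' @param ids Individual identifiers (defaults to indices).
#' @return Vector of ids of the recombinant individuals.
#' @export
findRecombinants <- function(genoLeft, genoRight, phenotypes, mode,
                             ids = seq_along(phenotypes)) {
  stopifnot(length(genoLeft) == length(phenotypes),
            length(genoRight) == length(phenotypes))
  compat <- lapply(phenotypes, expectedCausalGenotypes, mode = mode)
  discord <- function(g) mapply(function(gi, set)
    !is.na(gi) && !gi %in% set, g, compat)
  differ <- !is.na(genoLeft) & !is.na(genoRight) & genoLeft != genoRight
  ids[discord(genoLeft) | discord(genoRight) | differ]
}

#' Narrow the causal interval by recombinant breakpoints
#'
#' A marker is excluded as the causal location as soon as
#' \code{minDiscordant} individuals (default 1) carry a genotype there that is
#' incompatible with their phenotype-implied causal genotype; missing
#' genotypes are non-informative. Each recombinant whose discordant markers
#' form a clean prefix (and/or suffix) of the marker order orients its
#' breakpoint: a prefix discordant up to marker \code{j} places the causal
#' locus strictly right of \code{j}; a suffix discordant from marker \code{j}
#' places it strictly left of \code{j}. The returned interval is the tightest
#' such open interval; its core is the run of non-excluded markers inside it
#' (possibly empty when the two bounding recombinant breakpoints face each
#' other across a single marker gap). Individuals with uninterpretable
#' discordance patterns (e.g. a discordant island flanked by concordant
#' markers, a double-crossover signature) contribute marker exclusions but no
#' directional bound. With no recombinants the interval spans
#' (\code{chromStart}, \code{chromEnd}).
#'
#' @param markerMap data.frame \code{marker}, \code{chrom}, \code{pos}
#'   (single chromosome, positions strictly increasing).
#' @param geno Character matrix (individuals x markers, columns in map order)
#'   of codes A/H/B/NA.
#' @param phenotypes Phenotype classes, one per individual.
#' @param mode Inheritance mode.
#' @param minDiscordant Discordant individuals required to exclude a marker.
#' @param chromStart,chromEnd Bounds used when no recombinant bounds a side.
#' @param ids Individual identifiers.
#' @return A [FineMapResult].
#' @export
narrowInterval <- function(markerMap, geno, phenotypes, mode,
                           minDiscordant = 1L, chromStart = 0,
                           chromEnd = Inf, ids = seq_along(phenotypes)) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(markerMap)),
            nrow(markerMap) >= 3L,
            ncol(geno) == nrow(markerMap),
            nrow(geno) == length(phenotypes))
  if (length(unique(markerMap$chrom)) != 1L)
    stop("markers must lie on a single chromosome")
  if (is.unsorted(markerMap$pos, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  nM <- nrow(markerMap)
  compat <- lapply(phenotypes, expectedCausalGenotypes, mode = mode)
  disc <- matrix(FALSE, nrow(geno), ncol(geno))
  for (i in seq_len(nrow(geno)))
    disc[i, ] <- !is.na(geno[i, ]) & !geno[i, ] %in% compat[[i]]
  excluded <- colSums(disc) >= minDiscordant
  lower <- chromStart; upper <- chromEnd
  leftMarker <- rightMarker <- NA_character_
  for (i in which(rowSums(disc) > 0)) {
    d <- which(disc[i, ])
    informative <- !is.na(geno[i, ])
    # prefix extent: markers 1..k all discordant or missing
    k <- 0L
    while (k < nM && (!informative[k + 1L] || disc[i, k + 1L])) k <- k + 1L
    # suffix extent: markers j..nM all discordant or missing
    j <- nM + 1L
    while (j > 1L && (!informative[j - 1L] || disc[i, j - 1L])) j <- j - 1L
    if (k >= j - 1L) next              # discordant across the whole map
    if (!all(d <= k | d >= j)) next    # interior island: no orientation
    dPre <- d[d <= k]; dSuf <- d[d >= j]
    if (identical(compat[[i]], "H")) {
      # for an implied heterozygote, A-discordance implicates the
      # mutant-carrying gamete and B-discordance the wild one; a mixed block
      # can arise from both gametes recombining around the causal locus and
      # must not orient the breakpoint
      if (length(dPre) && length(unique(geno[i, dPre])) > 1L)
        dPre <- integer(0)
      if (length(dSuf) && length(unique(geno[i, dSuf])) > 1L)
        dSuf <- integer(0)
    }
    if (length(dPre) && markerMap$pos[max(dPre)] > lower) {
      lower <- markerMap$pos[max(dPre)]
      leftMarker <- markerMap$marker[max(dPre)]
    }
    if (length(dSuf) && markerMap$pos[min(dSuf)] < upper) {
      upper <- markerMap$pos[min(dSuf)]
      rightMarker <- markerMap$marker[min(dSuf)]
    }
  }
  if (!(lower < upper))
    stop("inconsistency error: recombinant breakpoints leave no interval ",
         "for the causal locus; check phenotypes, genotypes or the ",
         "inheritance mode")
  core <- which(!excluded & markerMap$pos > lower & markerMap$pos < upper)
  if (length(core) > 1L && any(diff(core) != 1L))
    stop("ambiguity error: multiple disjoint consistent marker runs inside ",
         "the bounded interval: ",
         paste(markerMap$marker[core], collapse = ", "))
  recIdx <- which(rowSums(disc) > 0)
  recombinants <- data.frame(
    id = ids[recIdx],
    markers = vapply(recIdx, function(i)
      paste(markerMap$marker[disc[i, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  methods::new("FineMapResult",
               chrom = markerMap$chrom[1],
               leftMarker = leftMarker, rightMarker = rightMarker,
               coreMarkers = markerMap$marker[core],
               interval = as.numeric(c(lower, upper)),
               recombinants = recombinants,
               excludedMarkers = markerMap$marker[excluded])
}

#' Intersect a fine-mapping interval with BSA candidate intervals
#'
#' Standard interval intersection between the open fine-mapping interval and
#' the closed 1-based BSA intervals on the same chromosome; a bound
#' contributed by the fine-mapping interval stays open, one contributed by a
#' BSA interval stays closed. An empty intersection is allowed and reported
#' with a warning.
#'
#' @param finemap A [FineMapResult].
#' @param bsaIntervals A \link[GenomicRanges]{GRanges} of candidate intervals.
#' @return data.frame with columns \code{chrom}, \code{lower}, \code{upper},
#'   \code{lowerOpen}, \code{upperOpen}; zero rows when disjoint.
#' @export
intersectWithBsa <- function(finemap, bsaIntervals) {
  stopifnot(methods::is(finemap, "FineMapResult"))
  same <- as.character(GenomicRanges::seqnames(bsaIntervals)) == finemap@chrom
  bsa <- bsaIntervals[same]
  out <- data.frame(chrom = character(0), lower = numeric(0),
                    upper = numeric(0), lowerOpen = logical(0),
                    upperOpen = logical(0))
  fl <- finemap@interval[1]; fu <- finemap@interval[2]
  for (i in seq_along(bsa)) {
    s <- GenomicRanges::start(bsa)[i]; e <- GenomicRanges::end(bsa)[i]
    lower <- max(fl, s); upper <- min(fu, e)
    lowerOpen <- fl >= s  # bound contributed by the open finemap interval
    upperOpen <- fu <= e
    nonempty <- if (lowerOpen || upperOpen) lower < upper else lower <= upper
    if (nonempty)
      out <- rbind(out, data.frame(chrom = finemap@chrom, lower = lower,
                                   upper = upper, lowerOpen = lowerOpen,
                                   upperOpen = upperOpen))
  }
  if (nrow(out) == 0)
    warning("fine-mapping interval and BSA intervals are disjoint")
  out
}
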