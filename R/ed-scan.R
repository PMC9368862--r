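# The core genome scan: read-support QC, per-pool allele frequencies, the
# Euclidean-distance (ED) statistic, local tricube fitting, threshold
# computation and candidate-interval calling.

# drop read counts at bases other than ref/alt (what an AD-only VCF carries)
.reduceToRefAlt <- function(panel) {
  s <- panel@sites
  n <- nrow(s)
  keepIdx <- cbind(seq_len(n), match(s$ref, .ACGT))
  altIdx <- cbind(seq_len(n), match(s$alt, .ACGT))
  reduce <- function(m) {
    out <- matrix(0L, n, 4L, dimnames = list(NULL, .ACGT))
    out[keepIdx] <- m[keepIdx]
    out[altIdx] <- m[altIdx]
    out
  }
  methods::new("VariantPanel", sites = s, mutCounts = reduce(panel@mutCounts),
               wtCounts = reduce(panel@wtCounts))
}

#' Read-support filter
#'
#' Removes sites whose total read depth in either pool is below
#' \code{minReads} (default 4). The boundary is inclusive: a site with exactly
#' \code{minReads} reads in both pools is retained.
#'
#' @param panel A [VariantPanel].
#' @param minReads Minimum per-pool depth.
#' @return A list: \code{panel} (retained sites) and \code{log}, a data.frame
#'   of removal counts by reason (\code{low_depth_mut}, \code{low_depth_wt},
#'   \code{removed}, \code{retained}).
#' @examples
#' \dontrun{filterSites(panel, minReads = 4)}
#' @export
filterSites <- function(panel, minReads = 4L) {
  stopifnot(methods::is(panel, "VariantPanel"), minReads >= 0)
  mutDepth <- rowSums(panel@mutCounts)
  wtDepth <- rowSums(panel@wtCounts)
  lowMut <- mutDepth < minReads
  lowWt <- wtDepth < minReads
  removed <- lowMut | lowWt
  log <- data.frame(
    reason = c("low_depth_mut", "low_depth_wt", "removed", "retained"),
    n = c(sum(lowMut), sum(lowWt), sum(removed), sum(!removed)))
  list(panel = panel[!removed], log = log)
}

#' Per-pool allele frequencies
#'
#' @param panel A [VariantPanel].
#' @param pool \code{"mut"} or \code{"wt"}.
#' @return Matrix (sites x 4, columns A,C,G,T) of base frequencies; each row
#'   sums to 1.
#' @export
alleleFrequencies <- function(panel, pool = c("mut", "wt")) {
  pool <- match.arg(pool)
  counts <- poolCounts(panel, pool)
  depth <- rowSums(counts)
  if (any(depth == 0))
    stop("undefined allele frequencies: zero depth in pool '", pool,
         "' at ", sum(depth == 0), " site(s); run filterSites() first")
  counts / depth
}

#' Euclidean-distance statistic
#'
#' For each site, the Euclidean distance between the two pools' allele
#' frequency vectors over the four bases,
#' \code{ED = sqrt(sum_b (f_mut(b) - f_wt(b))^2)}, raised to \code{power}
#' (default 1). For a biallelic site this equals
#' \code{sqrt(2) * |f_mut(alt) - f_wt(alt)|}, so 0 <= ED <= sqrt(2).
#'
#' @param panel A [VariantPanel] with positive depth in both pools at every
#'   site.
#' @param power Exponent applied to the ED value.
#' @return Numeric vector of ED^power values.
#' @export
edStatistic <- function(panel, power = 1) {
  stopifnot(power > 0)
  d <- alleleFrequencies(panel, "mut") - alleleFrequencies(panel, "wt")
  ed <- sqrt(rowSums(d * d))
  ed^power
}

#' Tricube local fit of ED values along a chromosome
#'
#' For each site, a tricube-weighted mean of the ED values of all sites within
#' \code{windowBp/2} of it: weights \code{w(u) = (1 - |u|^3)^3} with
#' \code{u = distance / (windowBp/2)}. The site itself has weight 1, so every
#' fitted value is defined and lies within the range of the raw values in its
#' window.
#'
#' @param positions Sorted physical positions (one chromosome).
#' @param ed Raw ED values aligned to \code{positions}.
#' @param windowBp Full window width in bp (default 1e6).
#' @return Numeric vector of fitted values.
#' @export
fitEdProfile <- function(positions, ed, windowBp = 1e6) {
  stopifnot(length(positions) == length(ed), windowBp > 0)
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(positions)) stop("positions must be sorted")
  half <- windowBp / 2
  lo <- findInterval(positions - half, positions, left.open = TRUE) + 1L
  hi <- findInterval(positions + half, positions)
  vapply(seq_len(n), function(i) {
    j <- lo[i]:hi[i]
    u <- abs(positions[j] - positions[i]) / half
    w <- (1 - pmin(u, 1)^3)^3
    sum(w * ed[j]) / sum(w)
  }, numeric(1))
}

#' Threshold on fitted ED values
#'
#' Three methods: \describe{
#'   \item{\code{fixed}}{returns \code{value} unchanged (reproduces an
#'     externally chosen cutoff such as 0.05).}
#'   \item{\code{quantile_permutation}}{the \code{q}-quantile (default 0.995)
#'     of the fitted values under \code{B} random per-site swaps of the two
#'     pool labels. Because the ED statistic is symmetric under exchanging the
#'     pools, every relabelling reproduces the observed per-site ED exactly,
#'     so the permutation distribution collapses and the result equals the
#'     empirical \code{q}-quantile of the observed fitted values; that closed
#'     form is what is computed.}
#'   \item{\code{median_plus_k_sd}}{median + \code{k} standard deviations
#'     (default k = 3) of the fitted values.}
#' }
#'
#' @param fitted Numeric vector of fitted ED values.
#' @param method One of \code{"quantile_permutation"}, \code{"fixed"},
#'   \code{"median_plus_k_sd"}.
#' @param value Cutoff used by \code{method = "fixed"}.
#' @param q Quantile used by \code{quantile_permutation}.
#' @param B Nominal number of permutation replicates (retained in the
#'   interface; the collapsed closed form does not depend on it).
#' @param k Multiplier used by \code{median_plus_k_sd}.
#' @param seed Seed for the permutation draws (the collapsed result is
#'   seed-invariant; accepted for interface stability).
#' @return A single numeric threshold.
#' @export
computeEdThreshold <- function(fitted,
                               method = c("quantile_permutation", "fixed",
                                          "median_plus_k_sd"),
                               value = 0.05, q = 0.995, B = 200L, k = 3,
                               seed = NULL) {
  method <- tryCatch(match.arg(method), error = function(e)
    stop("configuration error: unknown threshold method '",
         paste(method, collapse = ","), "'"))
  switch(method,
    fixed = value,
    quantile_permutation = {
      if (length(fitted) == 0) stop("no fitted values")
      # see ?computeEdThreshold: pool-label swaps leave ED invariant, so the
      # permutation ECDF is B identical copies of the observed fit; its
      # q-quantile is the type-1 (inverse-ECDF) quantile of the observed
      # fitted values, which is invariant to B
      unname(stats::quantile(fitted, q, type = 1))
    },
    median_plus_k_sd = {
      if (length(fitted) == 0) stop("no fitted values")
      s <- stats::sd(fitted)
      stats::median(fitted) + k * (if (is.na(s)) 0 else s)
    })
}

#' Call candidate intervals from a fitted profile (one chromosome)
#'
#' Intervals are maximal runs of consecutive sites with fitted value strictly
#' above the threshold. Runs whose facing boundary sites are at most
#' \code{mergeGapBp} apart are merged. Each interval spans the positions of
#' its first and last member sites; its peak is the site with the maximal
#' fitted value (leftmost on ties).
#'
#' @param positions Sorted site positions of one chromosome.
#' @param fitted Fitted ED values aligned to \code{positions}.
#' @param threshold Threshold on the fitted values (strict \code{>}).
#' @param mergeGapBp Maximal gap bridged when merging adjacent runs.
#' @param chrom Chromosome name used in the output.
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{peakPos}, \code{peakEd}, \code{nSites} (super-threshold member
#'   sites).
#' @export
callIntervals <- function(positions, fitted, threshold, mergeGapBp = 0,
                          chrom = "chr1") {
  stopifnot(length(positions) == length(fitted))
  empty <- GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  peakPos = integer(0), peakEd = numeric(0),
                                  nSites = integer(0))
  above <- fitted > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  runs <- data.frame(start = startIdx[r$values], end = endIdx[r$values])
  # merge runs whose facing boundary sites are at most mergeGapBp apart
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap <- positions[runs$start[i]] - positions[merged$end[nrow(merged)]]
    if (gap <= mergeGapBp)
      merged$end[nrow(merged)] <- runs$end[i]
    else
      merged <- rbind(merged, runs[i, ])
  }
  peakPos <- peakEd <- numeric(nrow(merged))
  nMember <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    j <- merged$start[i]:merged$end[i]
    pk <- j[which.max(fitted[j])]  # which.max returns the leftmost maximum
    peakPos[i] <- positions[pk]
    peakEd[i] <- fitted[pk]
    nMember[i] <- sum(fitted[j] > threshold)
  }
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(positions[merged$start], positions[merged$end]),
    peakPos = as.integer(peakPos), peakEd = peakEd, nSites = nMember)
}

#' Run the ED scan on a variant panel
#'
#' Applies the read-support filter, computes raw ED values, fits them per
#' chromosome with the tricube smoother, and computes the interval-calling
#' threshold.
#'
#' @param panel A [VariantPanel].
#' @param minReads Read-support filter cutoff (default 4).
#' @param power Exponent on the ED statistic (default 1).
#' @param windowBp Tricube window (default 1e6).
#' @param thresholdMethod,thresholdValue,q,B,k,seed Passed to
#'   [computeEdThreshold()].
#' @return An [EDProfile].
#' @export
edScan <- function(panel, minReads = 4L, power = 1, windowBp = 1e6,
                   thresholdMethod = "quantile_permutation",
                   thresholdValue = 0.05, q = 0.995, B = 200L, k = 3,
                   seed = NULL) {
  flt <- filterSites(panel, minReads)
  panel <- flt$panel
  s <- siteInfo(panel)
  o <- order(s$chrom, s$pos)
  panel <- panel[o]
  s <- siteInfo(panel)
  ed <- edStatistic(panel, power)
  fitted <- unlist(lapply(split(seq_len(nrow(s)), s$chrom), function(idx)
    fitEdProfile(s$pos[idx], ed[idx], windowBp)), use.names = FALSE)
  # split() orders groups by factor level; realign to row order
  idxOrder <- unlist(split(seq_len(nrow(s)), s$chrom), use.names = FALSE)
  fitted[idxOrder] <- fitted
  threshold <- computeEdThreshold(fitted, thresholdMethod,
                                  value = thresholdValue, q = q, B = B, k = k,
                                  seed = seed)
  methods::new("EDProfile",
    sites = data.frame(chrom = s$chrom, pos = s$pos, edRaw = ed,
                       edFitted = fitted, stringsAsFactors = FALSE),
    threshold = threshold, power = power, windowBp = windowBp,
    thresholdMethod = thresholdMethod, filterLog = flt$log)
}

#' Candidate intervals from an ED profile
#'
#' Calls [callIntervals()] chromosome by chromosome.
#'
#' @param profile An [EDProfile].
#' @param mergeGapBp Maximal gap bridged when merging adjacent runs.
#' @return A \link[GenomicRanges]{GRanges} of candidate intervals.
#' @export
candidateIntervals <- function(profile, mergeGapBp = 0) {
  stopifnot(methods::is(profile, "EDProfile"))
  s <- profile@sites
  grl <- lapply(split(seq_len(nrow(s)), s$chrom), function(idx)
    callIntervals(s$pos[idx], s$edFitted[idx], profile@threshold,
                  mergeGapBp, chrom = s$chrom[idx[1]]))
  out <- do.call(c, unname(grl))
  names(out) <- NULL
  out
}

#' Fill interval gene content
#'
#' A gene belongs to an interval iff its span (min CDS start to max CDS end)
#' overlaps the interval by at least 1 bp.
#'
#' @param intervals A \link[GenomicRanges]{GRanges} of candidate intervals.
#' @param genes A [GeneModels].
#' @return \code{intervals} with a \code{geneIds} metadata column (a
#'   \link[IRanges]{CharacterList}).
#' @export
genesInIntervals <- function(intervals, genes) {
  spans <- geneSpans(genes)
  hits <- GenomicRanges::findOverlaps(spans, intervals, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ids <- split(names(spans)[S4Vectors::queryHits(hits)],
               factor(S4Vectors::subjectHits(hits),
                      levels = seq_along(intervals)))
  S4Vectors::mcols(intervals)$geneIds <-
    methods::as(unname(ids), "CharacterList")
  intervals
}
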