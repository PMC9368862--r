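# ED statistic, read-support QC, tricube fitting, thresholds and interval
# calling.

test_that("read-support filter removes sites below the per-pool minimum", {
  panel <- makeBiallelicPanel(
    refCounts = list(mut = c(3L, 4L, 0L), wt = c(20L, 4L, 10L)),
    altCounts = list(mut = c(0L, 0L, 50L), wt = c(20L, 0L, 10L)))
  flt <- filterSites(panel, minReads = 4L)
  # site 1: mut depth 3 < 4 removed despite wt depth 40; site 2: both exactly
  # 4, retained; site 3: retained
  expect_identical(nSites(flt$panel), 2L)
  expect_identical(siteInfo(flt$panel)$pos, c(200L, 300L))
  expect_identical(flt$log$n[flt$log$reason == "low_depth_mut"], 1L)
  expect_identical(flt$log$n[flt$log$reason == "removed"], 1L)
  # minReads 0 retains everything
  expect_identical(nSites(filterSites(panel, 0L)$panel), 3L)
})

test_that("allele frequencies normalize counts and reject zero depth", {
  panel <- makeBiallelicPanel(refCounts = list(mut = 5L, wt = 12L),
                              altCounts = list(mut = 15L, wt = 8L))
  f <- alleleFrequencies(panel, "mut")
  expect_equal(unname(f[1, ]), c(0, 0.25, 0, 0.75))
  expect_equal(sum(f), 1)
  g <- alleleFrequencies(panel, "wt")
  expect_equal(unname(g[1, ]), c(0, 0.6, 0, 0.4))

  onlyA <- makePanel(1L, "A", "G",
                     matrix(c(10L, 0L, 0L, 0L), 1), matrix(c(3L, 0L, 0L, 0L), 1))
  expect_equal(unname(alleleFrequencies(onlyA, "mut")[1, ]), c(1, 0, 0, 0))

  zero <- makePanel(1L, "A", "G", matrix(0L, 1, 4), matrix(c(1L, 0L, 0L, 0L), 1))
  expect_error(alleleFrequencies(zero, "mut"), "zero depth")
})

test_that("the ED statistic matches hand-evaluated cases", {
  # identical count vectors give 0
  same <- makeBiallelicPanel(refCounts = list(mut = 5L, wt = 5L),
                             altCounts = list(mut = 15L, wt = 15L))
  expect_equal(edStatistic(same), 0)
  # fixed alt vs fixed ref gives the biallelic maximum sqrt(2)
  fixed <- makeBiallelicPanel(refCounts = list(mut = 0L, wt = 20L),
                              altCounts = list(mut = 20L, wt = 0L))
  expect_equal(edStatistic(fixed), sqrt(2))
  # mut {C:5, T:15}, wt {C:12, T:8}: sqrt((0.25-0.6)^2 + (0.75-0.4)^2)
  mixed <- makeBiallelicPanel(refCounts = list(mut = 5L, wt = 12L),
                              altCounts = list(mut = 15L, wt = 8L))
  expect_equal(edStatistic(mixed), sqrt(0.245), tolerance = 1e-12)
  expect_equal(edStatistic(mixed, power = 4), sqrt(0.245)^4, tolerance = 1e-12)
})

test_that("ED is symmetric under pool swap and equals sqrt(2)|df_alt| on
           biallelic sites", {
  set.seed(77)
  n <- 300L
  panel <- makeBiallelicPanel(
    refCounts = list(mut = rpois(n, 20) + 1L, wt = rpois(n, 20) + 1L),
    altCounts = list(mut = rpois(n, 20) + 1L, wt = rpois(n, 20) + 1L))
  ed <- edStatistic(panel)
  swapped <- new("VariantPanel", sites = siteInfo(panel),
                 mutCounts = poolCounts(panel, "wt"),
                 wtCounts = poolCounts(panel, "mut"))
  expect_equal(edStatistic(swapped), ed, tolerance = 1e-14)
  fAlt <- function(p, pool) {
    cc <- poolCounts(p, pool)
    cc[, "T"] / rowSums(cc)
  }
  expect_equal(ed, sqrt(2) * abs(fAlt(panel, "mut") - fAlt(panel, "wt")),
               tolerance = 1e-12)
  expect_true(all(ed >= 0 & ed <= sqrt(2) + 1e-12))
})

test_that("tricube fitting reproduces closed-form cases", {
  # constant series stays constant
  expect_equal(fitEdProfile(1:10 * 100, rep(0.3, 10), windowBp = 500),
               rep(0.3, 10))
  # a single site equals its raw value
  expect_equal(fitEdProfile(5000, 0.7), 0.7)
  # three equidistant sites, window covering all: hand-evaluated weights
  pos <- c(1000, 2000, 3000)
  vals <- c(0, 1, 0)
  w <- (1 - (1000 / 2000)^3)^3
  fit <- fitEdProfile(pos, vals, windowBp = 4000)
  expect_equal(fit[2], 1 / (2 * w + 1), tolerance = 1e-12)
  # every fitted value lies within the raw range of its window
  expect_true(all(fit >= 0 & fit <= 1))
  # empty input gives empty output
  expect_identical(fitEdProfile(numeric(0), numeric(0)), numeric(0))
})

test_that("fitting ignores sites with zero weight outside every window", {
  pos <- c(1000, 1500, 2000)
  vals <- c(0.2, 0.9, 0.4)
  base <- fitEdProfile(pos, vals, windowBp = 3000)
  # a site exactly one half-window away carries tricube weight 0
  aug <- fitEdProfile(c(pos, 3500), c(vals, 5), windowBp = 3000)
  expect_equal(aug[1:3], base, tolerance = 1e-12)
})

test_that("threshold methods behave as specified", {
  fitted <- c(0.01, 0.02, 0.03, 0.2)
  expect_identical(computeEdThreshold(fitted, "fixed", value = 0.05), 0.05)
  expect_equal(computeEdThreshold(rep(0.3, 10), "median_plus_k_sd"), 0.3)
  expect_equal(computeEdThreshold(fitted, "median_plus_k_sd", k = 3),
               median(fitted) + 3 * sd(fitted))
  t1 <- computeEdThreshold(fitted, "quantile_permutation", q = 0.9, seed = 1)
  t2 <- computeEdThreshold(fitted, "quantile_permutation", q = 0.9, seed = 99)
  expect_identical(t1, t2)
  expect_error(computeEdThreshold(fitted, "bootstrap"), "configuration error")
})

test_that("the permutation threshold equals a literal swap-and-recompute", {
  set.seed(5)
  n <- 40L
  panel <- makeBiallelicPanel(
    refCounts = list(mut = rpois(n, 15) + 1L, wt = rpois(n, 15) + 1L),
    altCounts = list(mut = rpois(n, 15) + 1L, wt = rpois(n, 15) + 1L))
  pos <- siteInfo(panel)$pos
  fitted <- fitEdProfile(pos, edStatistic(panel), windowBp = 1000)
  # literal permutation: swap the two pools at random sites, recompute the
  # whole fit, pool the B replicates, take the quantile
  perms <- unlist(lapply(1:5, function(b) {
    swap <- runif(n) < 0.5
    mut <- poolCounts(panel, "mut"); wt <- poolCounts(panel, "wt")
    tmp <- mut[swap, , drop = FALSE]
    mut[swap, ] <- wt[swap, , drop = FALSE]; wt[swap, ] <- tmp
    p2 <- new("VariantPanel", sites = siteInfo(panel), mutCounts = mut,
              wtCounts = wt)
    fitEdProfile(pos, edStatistic(p2), windowBp = 1000)
  }))
  # the permutation ECDF is replicate copies of the observed fit, so the
  # inverse-ECDF quantile of the pooled replicates is the method's value
  expect_equal(unname(quantile(perms, 0.99, type = 1)),
               computeEdThreshold(fitted, "quantile_permutation", q = 0.99),
               tolerance = 1e-12)
})

test_that("interval calling matches the hand-enumerated example", {
  pos <- 1:10 * 1000
  fitted <- c(0, 0, .6, .7, .6, 0, 0, .8, .9, 0)
  iv <- callIntervals(pos, fitted, threshold = 0.5, mergeGapBp = 0)
  expect_identical(length(iv), 2L)
  expect_identical(GenomicRanges::start(iv), c(3000L, 8000L))
  expect_identical(GenomicRanges::end(iv), c(5000L, 9000L))
  expect_identical(S4Vectors::mcols(iv)$peakPos, c(4000L, 9000L))
  expect_identical(S4Vectors::mcols(iv)$nSites, c(3L, 2L))

  merged <- callIntervals(pos, fitted, threshold = 0.5, mergeGapBp = 3000)
  expect_identical(length(merged), 1L)
  expect_identical(GenomicRanges::start(merged), 3000L)
  expect_identical(GenomicRanges::end(merged), 9000L)
  expect_identical(S4Vectors::mcols(merged)$peakPos, 9000L)
  expect_identical(S4Vectors::mcols(merged)$nSites, 5L)

  expect_identical(length(callIntervals(pos, fitted, threshold = 1)), 0L)
})

test_that("interval membership is exactly the super-threshold sites at gap 0", {
  set.seed(9)
  pos <- sort(sample.int(1e6, 200))
  fitted <- runif(200)
  thr <- 0.8
  iv <- callIntervals(pos, fitted, thr, mergeGapBp = 0)
  member <- unlist(lapply(seq_along(iv), function(i)
    pos[pos >= GenomicRanges::start(iv)[i] & pos <= GenomicRanges::end(iv)[i] &
          fitted > thr]))
  expect_identical(sort(member), pos[fitted > thr])
  expect_true(all(S4Vectors::mcols(iv)$peakEd > thr))
  # ties break to the leftmost site
  tie <- callIntervals(c(100, 200, 300), c(0.9, 0.9, 0.9), 0.5)
  expect_identical(S4Vectors::mcols(tie)$peakPos, 100L)
})

test_that("gene-interval overlap requires at least one base", {
  genes <- makeGene(c(100, 180), c(149, 200))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 300))
  out <- genesInIntervals(iv, genes)
  expect_identical(unlist(S4Vectors::mcols(out)$geneIds), "m1")  # span 100-200
  before <- makeGene(100, 149)
  out2 <- genesInIntervals(iv, before)
  expect_identical(length(unlist(S4Vectors::mcols(out2)$geneIds)), 0L)
  spanning <- makeGene(10, 999)
  out3 <- genesInIntervals(iv, spanning)
  expect_identical(unlist(S4Vectors::mcols(out3)$geneIds), "m1")
})

test_that("edScan assembles a coherent profile over chromosomes", {
  set.seed(12)
  n <- 60L
  mut <- matrix(0L, n, 4, dimnames = list(NULL, ACGT))
  wt <- mut
  mut[, "C"] <- rpois(n, 10) + 1L; mut[, "T"] <- rpois(n, 10) + 1L
  wt[, "C"] <- rpois(n, 10) + 1L; wt[, "T"] <- rpois(n, 10) + 1L
  panel <- makePanel(rep(1:30 * 1000L, 2), rep("C", n), rep("T", n), mut, wt,
                     chrom = rep(c("chr1", "chr2"), each = 30))
  profile <- edScan(panel, minReads = 1L, windowBp = 5000)
  s <- edValues(profile)
  expect_identical(nrow(s), n)
  expect_true(all(tapply(s$pos, s$chrom, function(p) !is.unsorted(p, TRUE))))
  # per-chromosome fits agree with fitting each chromosome alone
  one <- s[s$chrom == "chr1", ]
  expect_equal(one$edFitted,
               fitEdProfile(one$pos, one$edRaw, windowBp = 5000))
})
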