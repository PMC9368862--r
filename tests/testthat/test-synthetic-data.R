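# The synthetic-data generator: determinism, the EMS mutation spectrum, the
# planted motif and causal lesion, Mendelian structure and the Haldane map.

test_that("reference and gene simulation honours invariants and the seed", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e5), nSnps = 20L,
                          nGenes = 10L, seed = 5L)
  sim <- simulateReferenceAndGenes(cfg)
  expect_identical(length(sim$genes), 10L)
  spans <- geneSpans(sim$genes)
  o <- order(GenomicRanges::start(spans))
  expect_true(all(GenomicRanges::start(spans)[o][-1] >
                    GenomicRanges::end(spans)[o][-10]))  # non-overlapping
  w <- vapply(seq_len(10), function(i)
    sum(GenomicRanges::width(cdsRanges(sim$genes)[[i]])), numeric(1))
  expect_true(all(w %% 3 == 0))
  # at least one translation carries the motif
  prots <- vapply(geneIds(sim$genes), function(id)
    translateGeneModel(sim$genes, id, sim$genome), character(1))
  expect_true(any(grepl("GWPPV", prots, fixed = TRUE)))
  # same seed, same output
  sim2 <- simulateReferenceAndGenes(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(geneSpans(sim$genes), geneSpans(sim2$genes))
})

test_that("EMS variants carry the transition bias and the Pro>Leu causal SNP", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), nSnps = 200L,
                          nGenes = 20L, emsBias = 1, seed = 11L)
  sim <- simulateReferenceAndGenes(cfg)
  v <- simulateEmsVariants(cfg, sim$genome, sim$genes)
  expect_identical(nrow(v), 200L)
  expect_identical(sum(v$causal), 1L)
  # bias 1.0: every SNP is C>T or G>A
  expect_true(all((v$ref == "C" & v$alt == "T") |
                    (v$ref == "G" & v$alt == "A")))
  # the causal change is a proline-codon CCx>CTx giving P>L in the motif
  causal <- v[v$causal, ]
  ann <- classifyVariants(causal, sim$genes, sim$genome, motif = "GWPPV")
  ann <- ann[ann$effect == "missense", ]
  expect_identical(ann$residueBefore, "P")
  expect_identical(ann$residueAfter, "L")
  expect_true(startsWith(ann$codonBefore, "CC"))
  expect_identical(substring(ann$codonAfter, 2, 2), "T")
  expect_true(ann$motifHit)
})

test_that("EMS bias is respected to binomial accuracy", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 5e6), nSnps = 10000L,
                          nGenes = 20L, emsBias = 0.9, seed = 21L)
  sim <- simulateReferenceAndGenes(cfg)
  v <- simulateEmsVariants(cfg, sim$genome, sim$genes)
  v <- v[!v$causal, ]
  transition <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
  # transversions can only come from the unbiased draws, but an unbiased draw
  # can produce a transition by chance: C or G ref (~1/2) with the matching
  # alt (1/3), so P(transition) = bias + (1 - bias) * p(ref in {C,G})/3.
  # Bound generously by 3 binomial SDs around the bias itself plus that slack.
  p <- mean(transition)
  expect_gt(p, 0.9 - 3 * sqrt(0.9 * 0.1 / nrow(v)))
  expect_lt(p, 0.9 + 0.1 / 2 + 3 * sqrt(0.9 * 0.1 / nrow(v)))
})

test_that("phenotype maps follow the inheritance mode", {
  expect_identical(phenotypeFromGenotype(c("A", "H", "B"), "semi-dominant"),
                   c("WT", "INT", "MUT"))
  expect_identical(phenotypeFromGenotype(c("A", "H", "B"), "dominant"),
                   c("WT", "MUT", "MUT"))
  expect_identical(phenotypeFromGenotype(c("A", "H", "B"), "recessive"),
                   c("WT", "WT", "MUT"))
  expect_error(phenotypeFromGenotype("A", "codominant"), "configuration error")
})

test_that("selfed F2 cohorts segregate 1:2:1 at the causal locus", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), seed = 31L)
  loci <- data.frame(chrom = "chr1", pos = c(1e5, 5e5))
  cohort <- simulateF2Cohort(cfg, loci, causal = 2L, n = 10000L)
  counts <- table(factor(genotypes(cohort)[, 2], levels = c("A", "H", "B")))
  # multinomial 3-SD bands around n * (1/4, 1/2, 1/4)
  expect_lt(abs(counts[["A"]] - 2500), 3 * sqrt(10000 * 0.25 * 0.75))
  expect_lt(abs(counts[["H"]] - 5000), 3 * sqrt(10000 * 0.5 * 0.5))
  expect_lt(abs(counts[["B"]] - 2500), 3 * sqrt(10000 * 0.25 * 0.75))
})

test_that("coincident loci are completely linked", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), seed = 32L)
  loci <- data.frame(chrom = "chr1", pos = c(2e5, 2e5 + 1))  # ~0 Morgans apart
  cohort <- simulateF2Cohort(cfg, loci, causal = 1L, n = 500L)
  expect_identical(genotypes(cohort)[, 1], genotypes(cohort)[, 2])
})

test_that("gametes follow Haldane's map function at 0.5 Morgans", {
  # r = (1 - exp(-2 * 0.5)) / 2
  rExp <- (1 - exp(-1)) / 2
  n <- 20000L
  g <- withr::with_seed(33L, edmap:::.simGametes(n, c(0.1, 0.6), 1))
  rHat <- mean(g[, 1] != g[, 2])
  expect_lt(abs(rHat - rExp), 3 * sqrt(rExp * (1 - rExp) / n))
})

test_that("pooled reads reflect selection, error model and depth", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6, chr2 = 1e6),
                          errorRate = 0, depth = 50, seed = 41L)
  # second locus on another chromosome: genuinely unlinked
  loci <- data.frame(chrom = c("chr1", "chr2"), pos = c(1e5, 1e5))
  variants <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = "C",
                         alt = "T", causal = c(TRUE, FALSE))
  cohort <- simulateF2Cohort(cfg, loci, causal = 1L, n = 200L)
  panel <- buildPoolsAndReads(cohort, variants, cfg)
  mc <- poolCounts(panel, "mut"); wc <- poolCounts(panel, "wt")
  # causal site, error 0: the mutant pool is pure alt, the wild-type pool
  # pure ref
  expect_identical(unname(mc[1, "C"]), 0L)
  expect_gt(mc[1, "T"], 0L)
  expect_identical(unname(wc[1, "T"]), 0L)
  expect_gt(wc[1, "C"], 0L)
  # unlinked site: both pools' expected alt frequency is 1/2; average over
  # seeds
  fm <- mean(vapply(1:40, function(s) {
    co <- simulateF2Cohort(cfg, loci, causal = 1L, n = 200L, seed = s)
    p <- buildPoolsAndReads(co, variants, cfg, seed = s + 1000L)
    alleleFrequencies(p, "mut")[2, "T"]
  }, numeric(1)))
  expect_lt(abs(fm - 0.5), 0.05)
})

test_that("zero-depth sites are emitted with zero counts and filtered out", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), depth = 0.2,
                          seed = 42L)
  loci <- data.frame(chrom = "chr1", pos = seq(1e4, 5e5, by = 1e4))
  variants <- data.frame(chrom = "chr1", pos = loci$pos, ref = "C", alt = "T",
                         causal = c(TRUE, rep(FALSE, nrow(loci) - 1)))
  cohort <- simulateF2Cohort(cfg, loci, causal = 1L, n = 100L)
  panel <- buildPoolsAndReads(cohort, variants, cfg)
  depths <- pmin(rowSums(poolCounts(panel, "mut")),
                 rowSums(poolCounts(panel, "wt")))
  expect_true(any(depths == 0))
  flt <- filterSites(panel, minReads = 1L)
  expect_identical(nSites(flt$panel), sum(depths >= 1))
})

test_that("the fine-mapping cross brackets the causal locus and is seeded", {
  cfg <- simulationConfig(seed = 51L)
  cross <- simulateFinemapCross(cfg, causalPos = 5e6)
  mm <- cross$markerMap
  expect_identical(nrow(mm), 13L)
  causalPos <- lociInfo(cross$cohort)$pos[causalLocus(cross$cohort)]
  expect_identical(causalPos, 5e6)
  expect_true(min(mm$pos) < 5e6 && max(mm$pos) > 5e6)
  expect_false(any(mm$pos == 5e6))
  expect_identical(length(cross$cohort), 185L)
  cross2 <- simulateFinemapCross(cfg, causalPos = 5e6)
  expect_identical(genotypes(cross$cohort), genotypes(cross2$cohort))
  expect_error(simulateFinemapCross(cfg, causalPos = 5e6,
                                    markerPositions = c(6e6, 7e6, 8e6)),
               "strictly between")
})

test_that("pool construction demands enough individuals of each class", {
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), poolSize = 20L,
                          seed = 61L)
  loci <- data.frame(chrom = "chr1", pos = 5e5)
  variants <- data.frame(chrom = "chr1", pos = 5e5, ref = "C", alt = "T",
                         causal = TRUE)
  cohort <- simulateF2Cohort(cfg, loci, causal = 1L, n = 30L)
  expect_error(buildPoolsAndReads(cohort, variants, cfg), "generation error")
})
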