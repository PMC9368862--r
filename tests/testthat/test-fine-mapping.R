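# Recombinant-breakpoint fine mapping.

test_that("phenotype-genotype compatibility sets follow the mode", {
  expect_identical(expectedCausalGenotypes("WT", "semi-dominant"), "A")
  expect_identical(expectedCausalGenotypes("INT", "semi-dominant"), "H")
  expect_identical(expectedCausalGenotypes("MUT", "semi-dominant"), "B")
  expect_identical(expectedCausalGenotypes("MUT", "dominant"), c("H", "B"))
  expect_identical(expectedCausalGenotypes("WT", "dominant"), "A")
  expect_identical(expectedCausalGenotypes("WT", "recessive"), c("A", "H"))
  expect_identical(expectedCausalGenotypes("MUT", "recessive"), "B")
  expect_error(expectedCausalGenotypes("INT", "dominant"), "input error")
  expect_error(expectedCausalGenotypes("INT", "recessive"), "input error")
})

test_that("recombinants are flagged by discordance or flanking disagreement", {
  # MUT requires B: (B, H) disagree between markers; (B, B) consistent;
  # missing genotypes never trigger
  ids <- c("p1", "p2", "p3", "p4")
  rec <- findRecombinants(genoLeft = c("B", "B", "A", "H"),
                          genoRight = c("H", "B", NA, "H"),
                          phenotypes = c("MUT", "MUT", "WT", "INT"),
                          mode = "semi-dominant", ids = ids)
  # p1: markers disagree; p2 consistent; p3: A with missing right, consistent;
  # p4: INT wants H at both, consistent
  expect_identical(rec, "p1")
  rec2 <- findRecombinants(c("A", "A"), c("A", "B"), c("WT", "WT"),
                           "semi-dominant")
  expect_identical(rec2, 2L)
})

test_that("the hand-worked five-marker example narrows to (10, 40) kb", {
  map <- data.frame(marker = paste0("M", 1:5), chrom = "chr1",
                    pos = c(10, 20, 30, 40, 50) * 1000)
  # ind1 MUT with (A,B,B,B,B): prefix discordance at M1 -> causal right of M1
  # ind2 WT with (A,A,A,B,B): suffix discordance at M4,M5 -> causal left of M4
  # plus two fully concordant individuals
  geno <- rbind(c("A", "B", "B", "B", "B"),
                c("A", "A", "A", "B", "B"),
                c("B", "B", "B", "B", "B"),
                c("A", "A", "A", "A", "A"))
  phen <- c("MUT", "WT", "MUT", "WT")
  fm <- narrowInterval(map, geno, phen, "semi-dominant")
  expect_identical(fm@coreMarkers, c("M2", "M3"))
  expect_identical(fm@excludedMarkers, c("M1", "M4", "M5"))
  expect_identical(fm@interval, c(10000, 40000))
  expect_identical(fm@leftMarker, "M1")
  expect_identical(fm@rightMarker, "M4")
  expect_identical(fm@recombinants$id, c(1L, 2L))
  expect_identical(fm@recombinants$markers, c("M1", "M4,M5"))
})

test_that("no recombinants leave the whole chromosome", {
  map <- data.frame(marker = paste0("M", 1:3), chrom = "chr1",
                    pos = c(10, 20, 30) * 1000)
  geno <- matrix("H", 4, 3)
  fm <- narrowInterval(map, geno, rep("INT", 4), "semi-dominant",
                       chromStart = 0, chromEnd = 1e6)
  expect_identical(fm@interval, c(0, 1e6))
  expect_identical(fm@coreMarkers, map$marker)
  expect_identical(nrow(fm@recombinants), 0L)
})

test_that("facing breakpoints leave a valid empty-core interval", {
  map <- data.frame(marker = paste0("M", 1:4), chrom = "chr1",
                    pos = c(10, 20, 30, 40) * 1000)
  # both individuals are prefix-discordant through M2, so the causal locus
  # lies right of M2
  geno <- rbind(c("A", "A", "B", "B"),   # MUT: A not in {B} at M1, M2
                c("B", "B", "A", "A"))   # WT: B not in {A} at M1, M2
  phen <- c("MUT", "WT")
  fm <- narrowInterval(map, geno, phen, "semi-dominant")
  expect_identical(fm@interval[1], 20000)
  expect_identical(fm@coreMarkers, c("M3", "M4"))

  # now orient from both sides
  geno2 <- rbind(c("A", "A", "B", "B"),   # MUT, prefix to M2: causal > 20 kb
                 c("A", "A", "B", "B"))   # WT, suffix from M3: causal < 30 kb
  fm2 <- narrowInterval(map, geno2, c("MUT", "WT"), "semi-dominant")
  expect_identical(fm2@interval, c(20000, 30000))
  expect_identical(length(fm2@coreMarkers), 0L)
  expect_identical(fm2@leftMarker, "M2")
  expect_identical(fm2@rightMarker, "M3")
})

test_that("contradictory breakpoints raise an inconsistency error", {
  map <- data.frame(marker = paste0("M", 1:3), chrom = "chr1",
                    pos = c(10, 20, 30) * 1000)
  # one individual puts the causal right of M2, another left of M2
  geno <- rbind(c("A", "A", "B"),   # MUT: prefix to M2 -> causal > 20 kb
                c("B", "A", "A"))   # MUT: suffix from M2 -> causal < 20 kb
  expect_error(narrowInterval(map, geno, c("MUT", "MUT"), "semi-dominant"),
               "inconsistency error")
})

test_that("missing genotypes are non-informative in narrowing", {
  map <- data.frame(marker = paste0("M", 1:4), chrom = "chr1",
                    pos = c(10, 20, 30, 40) * 1000)
  geno <- rbind(c("A", NA, "B", "B"))  # prefix discordant at M1 only
  fm <- narrowInterval(map, geno, "MUT", "semi-dominant", chromEnd = 1e5)
  expect_identical(fm@interval, c(10000, 1e5))
  # the missing genotype neither excludes M2 nor blocks the prefix
  expect_identical(fm@coreMarkers, c("M2", "M3", "M4"))
  expect_false("M2" %in% fm@excludedMarkers)
})

test_that("error-free cohorts always bracket the causal locus", {
  cfg <- simulationConfig(seed = 1L)
  for (s in 1:25) {
    cross <- simulateFinemapCross(cfg, causalPos = 5e6, seed = s)
    ci <- causalLocus(cross$cohort)
    geno <- genotypes(cross$cohort)[, -ci, drop = FALSE]
    fm <- narrowInterval(cross$markerMap, geno, phenotypes(cross$cohort),
                         "semi-dominant", chromStart = 0, chromEnd = 1e7)
    expect_lt(fm@interval[1], 5e6)
    expect_gt(fm@interval[2], 5e6)
  }
})

test_that("adding individuals never widens the interval", {
  cfg <- simulationConfig(seed = 2L)
  cross <- simulateFinemapCross(cfg, causalPos = 5e6, seed = 17L)
  ci <- causalLocus(cross$cohort)
  geno <- genotypes(cross$cohort)[, -ci, drop = FALSE]
  phen <- phenotypes(cross$cohort)
  widths <- vapply(seq(20, length(phen), by = 15), function(n) {
    fm <- narrowInterval(cross$markerMap, geno[1:n, , drop = FALSE],
                         phen[1:n], "semi-dominant", chromStart = 0,
                         chromEnd = 1e7)
    diff(fm@interval)
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("genotyping error degrades fine-mapping monotonically", {
  cfg <- simulationConfig(seed = 3L)
  failRate <- vapply(c(0, 0.01, 0.05), function(eps) {
    fails <- 0L
    for (s in 1:30) {
      cross <- simulateFinemapCross(cfg, causalPos = 5e6, seed = 100L + s)
      ci <- causalLocus(cross$cohort)
      geno <- genotypes(cross$cohort)[, -ci, drop = FALSE]
      if (eps > 0) {
        set.seed(200L + s)
        flip <- which(runif(length(geno)) < eps)
        geno[flip] <- vapply(geno[flip], function(g)
          sample(setdiff(c("A", "H", "B"), g), 1), character(1))
      }
      ok <- tryCatch({
        fm <- narrowInterval(cross$markerMap, geno, phenotypes(cross$cohort),
                             "semi-dominant", chromStart = 0, chromEnd = 1e7)
        fm@interval[1] < 5e6 && 5e6 < fm@interval[2]
      }, error = function(e) FALSE)
      if (!ok) fails <- fails + 1L
    }
    fails / 30
  }, numeric(1))
  expect_identical(failRate[1], 0)
  expect_true(all(diff(failRate) >= 0))
})

test_that("flanking-marker recombinants capture interior breakpoints", {
  # single crossovers always reach one of the outermost markers, so the
  # flanking screen catches them; only double-crossover islands (two
  # exchanges inside the 12 cM marker span) can escape, and those are rare
  cfg <- simulationConfig(seed = 4L)
  nInterior <- nCaptured <- 0L
  for (s in 1:10) {
    cross <- simulateFinemapCross(cfg, causalPos = 5e6, seed = 500L + s)
    ci <- causalLocus(cross$cohort)
    geno <- genotypes(cross$cohort)[, -ci, drop = FALSE]
    phen <- phenotypes(cross$cohort)
    outer <- findRecombinants(geno[, 1], geno[, ncol(geno)], phen,
                              "semi-dominant")
    interior <- which(vapply(seq_along(phen), function(i) {
      compat <- expectedCausalGenotypes(phen[i], "semi-dominant")
      any(!is.na(geno[i, ]) & !geno[i, ] %in% compat)
    }, logical(1)))
    nInterior <- nInterior + length(interior)
    nCaptured <- nCaptured + sum(interior %in% outer)
  }
  expect_gt(nInterior, 100L)           # the screen has material to work with
  expect_gte(nCaptured / nInterior, 0.95)
})

test_that("interval intersection preserves open/closed bounds", {
  fm <- new("FineMapResult", chrom = "chr1", leftMarker = "L",
            rightMarker = "R", coreMarkers = "M", interval = c(10e3, 40e3),
            recombinants = data.frame(id = 1, markers = "L"),
            excludedMarkers = c("L", "R"))
  bsa <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e3, 25e3))
  out <- intersectWithBsa(fm, bsa)
  expect_equal(out$lower, 10e3)
  expect_equal(out$upper, 25e3)
  expect_true(out$lowerOpen)
  expect_false(out$upperOpen)

  disjoint <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50e3, 60e3))
  expect_warning(none <- intersectWithBsa(fm, disjoint), "disjoint")
  expect_identical(nrow(none), 0L)

  containing <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e3, 90e3))
  out3 <- intersectWithBsa(fm, containing)
  expect_equal(c(out3$lower, out3$upper), c(10e3, 40e3))
  expect_true(out3$lowerOpen && out3$upperOpen)
})
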