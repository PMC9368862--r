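---
title: "Mapping EMS-induced mutations from phenotype-selected pools with edmap"
author: "edmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced mutations from phenotype-selected pools with edmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmap)
```

## The problem and the design

An EMS-mutagenized plant line segregates a single causal point mutation among
thousands of background mutations. In a MutMap+-style design, no outcross is
made: heterozygous plants are selfed, the F2 offspring segregate 1:2:1 at every
heterozygous site, and two pools of extreme-phenotype individuals (here 20
mutant-phenotype and 20 wild-type plants) are sequenced as bulks at moderate
depth (~38x per pool). Near the causal locus the two pools are fixed for
opposite alleles; at unlinked sites both pools sample the same 1:2:1
segregation and differ only by sampling noise.

`edmap` implements the computation from the variant calls onward: the
per-SNP Euclidean-distance (ED) statistic between the pools' allele-frequency
vectors, local smoothing and thresholding into candidate intervals, codon-level
annotation of interval genes down to nonsynonymous (optionally motif-hitting)
candidates, Mendelian segregation tests, and recombinant-breakpoint fine
mapping in a separate biparental F2. A seeded generator reproduces the whole
design synthetically, so every stage is testable end to end.

## The ED statistic

For a biallelic SNP with pooled allele frequencies $f_{\mathrm{mut}}$ and
$f_{\mathrm{wt}}$ over the four bases,

$$\mathrm{ED} = \sqrt{\sum_{b \in \{A,C,G,T\}}
  \left(f_{\mathrm{mut}}(b) - f_{\mathrm{wt}}(b)\right)^2}
  = \sqrt{2}\,\lvert \Delta f_{\mathrm{alt}} \rvert,$$

so $0 \le \mathrm{ED} \le \sqrt 2$, the maximum at a site where the pools are
fixed for opposite alleles. An optional exponent (`power`) sharpens peaks;
the default is 1, i.e. the unpowered statistic. For a marker at recombination
fraction $r$ from the causal locus, with homozygous pools selected under
semi-dominance and no sequencing error, the expected pooled frequencies are
$1-r$ and $r$, hence $E[\mathrm{ED}] \approx \sqrt 2\,(1-2r)$ — the closed
form the simulator is validated against. Sites with fewer than `minReads = 4`
reads in either pool are removed before the scan.

## Smoothing, threshold, and intervals

Raw ED values are noisy (at 38x and 20+20 pools the per-site noise mean is
~0.18 even at unlinked sites), so the scan operates on a locally fitted
profile: a tricube-weighted moving average over a physical window
(`windowBp = 1e6`), the standard LOESS-style kernel without iterative
reweighting. Single-site windows reduce to the raw value; fitted values always
lie within the raw range of their window.

Three threshold rules are exposed. `fixed` reproduces an externally chosen
cutoff. `median_plus_k_sd` is a cheap robust-ish rule. The default,
`quantile_permutation`, is defined as the q-quantile of the fitted values
under random per-site swaps of the two pool labels — but the ED statistic is
*symmetric* under exchanging the pools, so every relabelling reproduces the
observed values exactly and the permutation distribution collapses: the method
equals the inverse-ECDF q-quantile of the observed fitted values. We compute
that closed form directly (a test verifies it against a literal
swap-and-recompute loop). The practical reading is that the scan flags the
top $1-q$ fraction of the fitted profile rather than testing against an
exchangeable null; the vignette flags this deliberately, since pool-label
permutation is a degenerate null for a pool-symmetric statistic.

Candidate intervals are maximal runs of consecutive sites with fitted values
strictly above the threshold; runs whose facing boundary sites are at most
`mergeGapBp` apart are merged (the worked example in `?callIntervals` pins the
boundary behaviour), the peak is the leftmost maximal fitted site, and a gene
belongs to an interval iff its span overlaps it by at least 1 bp.

The pipeline's defaults differ from the single-function defaults in two
places, both consequences of the smoother's resolution. First, it thresholds
at the 0.95 quantile rather than 0.995: the linked plateau around a causal
locus spans hundreds of correlated sites, and a more extreme quantile selects
only the plateau's order statistics, which localize no better but can exclude
the causal gene. Second, runs are merged across gaps up to one window
(`mergeGapBp = windowBp`) and genes are collected over the interval padded by
half a window on each side: fitted values aggregate sites up to
`windowBp / 2` away, so interval edges are only defined to that resolution.
Peak localization on the default design is typically within a few hundred
kilobases (the acceptance suite requires 500 kb in at least 90% of seeded
runs).

## Variant annotation

Gene models are ordered CDS segments on one strand; UTRs are not modelled
(variants inside the gene span but outside every CDS segment are "intronic"),
splice-site classes are not assigned, and overlapping genes produce one
annotation per model. Coding coordinates are obtained by summing CDS segment
lengths in coding order — reverse-complemented, reversed-order segments on the
minus strand — and the affected codon is mutated and translated with the
standard nuclear code. Effects are classified in a fixed order: synonymous,
nonsense (new stop), stop_loss, start_loss (codon 1 loses ATG), otherwise
missense. An exhaustive oracle test sweeps all 64 codons x 3 positions x 3
alternates x both strands against a brute-force mutate-and-translate
implementation. Candidate filtering keeps interval genes with at least one
missense/nonsense/start-loss/stop-loss variant; the motif check translates the
full protein and reports whether the affected residue falls inside an exact
occurrence of a protein motif (e.g. the Aux/IAA degron "GWPPV", where the
canonical lesion is a CCx>CTx proline-to-leucine change at the motif's first
proline).

## Segregation tests

`chiSquareGof()` is the uncorrected chi-square goodness-of-fit against a
Mendelian ratio, df = classes - 1, with an optional Yates correction exposed
but off by default (the classical field arithmetic is uncorrected).
For three phenotype classes the 1:2:1 test has df = 2 (critical value 5.99 at
alpha = 0.05); reports that compare three-class counts against the df = 1
critical value 3.84 are conservative in the fits direction, and the package
reports the df = 2 decision. `classifyInheritance()` scores the classical
candidate ratios (3:1, 1:2:1, 15:1, 13:3, 9:7; three-class ratios only for
three observed classes) and returns the non-rejected ratio with the largest
p-value. Note that two-class counts near 9:7 (e.g. 100:100) legitimately fit
9:7, so "none" requires counts away from every candidate.

## Fine mapping by recombinant breakpoints

In the biparental F2, each individual's phenotype implies a causal genotype
(uniquely under semi-dominance: WT to A, INT to H, MUT to B; set-valued under
dominance/recessivity). A marker is excluded once `minDiscordant` individuals
(default 1) are discordant there. Each recombinant whose discordant markers
form a clean prefix (or suffix, or both) of the marker order orients its
breakpoint: prefix discordance up to marker $j$ places the causal locus
strictly to the right of $j$, suffix discordance strictly to the left. The
returned interval is the tightest such open interval — open because a
discordant individual excludes the causal locus *at* a marker but says nothing
beyond it — and its core is the run of consistent markers inside it, which may
be empty when two breakpoints face each other across a single gap (the typical
endpoint of a real fine-mapping experiment). Discordance patterns that cannot
be oriented (interior islands from double crossovers, or discordance across
the whole map) contribute exclusions but no directional bound. For an
implied-heterozygote individual (phenotype class INT under semi-dominance) an
A-discordance implicates the mutant-carrying gamete and a B-discordance the
wild one; a mixed-class block can be produced by the two gametes recombining
on opposite sides of the causal locus, so only constant-class blocks orient —
single-crossover recombinants always satisfy this. Orientation is then exact
unless a double crossover within one gamete flanks the causal locus within
its two adjacent marker gaps, which at the default density (250 kb = 1 cM
gaps) has probability ~1e-5 per gamete. Missing genotypes are non-informative
throughout. Contradictory bounds raise an inconsistency error; disjoint
consistent runs inside the bounds raise an ambiguity error listing the runs.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is validated under:

| parameter | default | meaning |
|---|---|---|
| `chromLengths` | chr1 = 10 Mb | genome size of the scan |
| `nSnps` | 2,000 | EMS SNPs incl. one causal |
| `nGenes` | 200 | non-overlapping gene models (2-6 CDS segments, 100-400 codons) |
| `poolSize` | 20 | individuals per phenotype pool |
| `depth` | 38 | mean pooled depth per site per pool (Poisson) |
| `errorRate` | 0.005 | per-base error, symmetric to the 3 other bases (e/3 each) |
| `cmPerMb` | 4 | uniform recombination rate |
| `mode` | semi-dominant | three distinguishable phenotype classes |
| `cohortSize` | 120 | selfed MutMap+ F2 (expected 30 per homozygous class) |
| `f2Size` | 185 | biparental fine-mapping F2 |
| `nMarkers`, `markerSpacingBp` | 13, 250 kb | fine-mapping marker grid |
| `emsBias` | 0.9 | P(background SNP is a C>T / G>A transition) |
| `motif` | GWPPV | protein motif planted in one gene |

Rationale for values the design itself does not fix: 2,000 SNPs on 10 Mb
matches the genome-wide density of the motivating experiment (~136k reliable
SNPs on a ~1 Gb genome); 200 genes is a typical plant gene density (~20/Mb);
a 120-plant selfed cohort keeps the probability of fewer than 20 individuals
in a homozygous class below 1% (with automatic resimulation otherwise); the
13-marker, 250-kb grid spans ~12 cM between its outer markers, so the expected
number of flanking recombinants among 185 plants is ~40, the magnitude of a
realistic two-stage fine-mapping design; 90% EMS transition bias is a
conservative lower bound on the strongly GC-to-AT-biased EMS spectrum. Gametes
carry Poisson($L$ Morgans) crossovers at uniform positions, which yields
Haldane's map function $r = (1 - e^{-2d})/2$ without interference —
interference is irrelevant at the scan's resolution. Background EMS SNPs
segregate as heterozygous in the selfed parent, in coupling on one homolog
(the worst case for scan noise: every unlinked site segregates 1:2:1 in both
pools); fixed background SNPs would only add ED ~ 0 sites. Pooled reads are
drawn per site and pool as depth ~ Poisson(`depth`) and a 4-base multinomial
with P(alt read) = $f(1-e) + (1-f)e/3$; zero-depth sites are emitted with zero
counts and removed by QC. The causal SNP is always a C>T change at the second
base of a proline codon inside the planted motif, on either strand.

What the generator deliberately does not emulate: read-level artefacts
(mapping bias, indels, base-quality structure), variant-caller error modes,
non-uniform recombination and gene density, multi-gene traits, and stop-free
open reading frames (random codons contain internal stops, which is harmless
to the codon-level logic but means translations are not biologically clean
proteins). Passing tests therefore demonstrate the statistical machinery, not
robustness to alignment or calling artefacts.

## Determinism and numerical choices

Every stochastic function takes a seed and restores the RNG state afterwards;
`runPipeline()` expands one global seed into per-stage child seeds with a
fixed linear-congruential step, so stages can be re-run in isolation from
their persisted inputs. Thresholding uses strict `>`; peak ties break to the
leftmost site; interval merging bridges gaps up to and including
`mergeGapBp`; BED output converts the package's 1-based inclusive coordinates
to 0-based half-open only at the file boundary; chi-square decisions use
`statistic <= critical value`. The scan never smooths across chromosome
boundaries.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 42L)
report <- runPipeline(cfg, outDir = "edmap-run", verbose = TRUE)
report$peak$distance      # bp from the planted causal SNP to the fitted peak
report$uniqueCandidate    # the single nonsynonymous motif-hit gene
report$segregation        # 1:2:1 chi-square for the fine-mapping F2
report$finemap            # open interval bracketing the causal locus
```

Problem sizes used by the test suite: the acceptance checks run 50 seeded
pipeline replicates of the default 10 Mb / 2,000-SNP design, 200 replicates of
the closed-form ED comparison at depth 200, 100 error-free fine-mapping
cohorts, and the full 3,456-case codon sweep.

## Known limitations

The collapse of pool-label permutation (above) means no genuine null
calibration is provided; a practitioner wanting a calibrated threshold should
permute individuals into pools, which requires individual-level data the
pooled design does not produce. Fitted background ED does not shrink to zero
with more sites (it is a folded-noise mean), so thresholds are scans of the
empirical profile, not significance statements. Fine-mapping orientation
assumes at most one crossover per gamete between adjacent markers; genotyping
error is surfaced as inconsistency/ambiguity errors rather than being modelled
probabilistically (`minDiscordant` offers a blunt guard). The annotation
module classifies single-nucleotide substitutions only.
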