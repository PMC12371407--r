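---
title: "Population genomics of a persistent baculovirus epidemic: models and methods"
author: "baculopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics of a persistent baculovirus epidemic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculopop)
```

## The system and the questions

Granuloviruses (family *Baculoviridae*, genus *Betabaculovirus*) persist in
agro-ecosystems as occlusion bodies in soil and recurrently cause epizootics
in their lepidopteran hosts. In a double-cropped rice system, epidemics of
the rice-leaffolder granulovirus recur in three waves (W1, W2, W3) per
growing season, two seasons per year. Whole-genome sequencing of per-larva
virus isolates across years makes three population-genomic questions
tractable:

1. **Structure** — are isolates genetically differentiated by year, season
   and wave (annual reservoir cycling versus continual reintroduction)?
2. **Diversity** — how much nucleotide diversity exists between hosts and
   within single infected hosts, and how does it change over the waves of a
   season (transmission bottlenecks)?
3. **Multiplicity** — are individual larvae infected by one, two, or more
   virus strains, and does the mixed-infection fraction decline over waves?

`baculopop` implements the full analysis path from standard files (FASTA
consensus genomes, a multi-sample VCF with per-sample allele depths, GFF3
ORF annotations, a CSV of year/season/wave labels) to these answers, plus a
seeded epidemic simulator so every stage can be validated against known
truth.

## Data model

The central container is `VariantMatrix`, a `SummarizedExperiment` of
haploid consensus genotypes (sites x samples; 0 = reference, k = k-th
alternative allele, `NA` = missing) with `refDepth`/`altDepth` assays
holding per-sample read support. Positions are 0-based internally; VCF and
GFF3 coordinates are converted exactly once at the file boundary
(`vcfToInternal()` / `internalToVcf()`). Diploid genotype records are
collapsed to a single haploid call (the virus is effectively clonal at the
consensus level); heterozygous calls resolve toward the allele with more
read support. Circularity of the genome is metadata only — reference
coordinates already linearize it.

## Site selection

Two site filters reproduce standard practice:

* `filterBiallelicMaf()` keeps biallelic SNPs whose minor allele frequency
  among non-missing calls is strictly greater than 5% (indels and
  multiallelic records removed) — the structure-analysis set.
* `findSegregatingSites()` defines a segregating site as one whose
  alternative allele is carried by **strictly more than** `min_carriers`
  samples (default 7, i.e. at least 8; with ~140 isolates this is the ~5%
  convention). Missing calls are never carriers, and carrier counting uses
  consensus-level calls, not read-level frequencies, because segregating
  sites are a between-consensus concept.

Both filters are idempotent and order-preserving; these properties are
tested, as is the exact behaviour at the minor-allele-frequency boundary.

## Diversity estimators

**Between hosts.** Per site,
$\pi_{site} = \frac{n}{n-1}\left(1 - \sum_a f_a^2\right)$ with $f_a$ the
allele frequencies among the $n$ non-missing consensus calls. This is
algebraically identical to the mean number of pairwise differences per
site, and that identity is the test oracle (exhaustive pairwise counting on
1,000 fuzzed matrices, agreement to 1e-12). `piBetweenHosts()` averages
over a chosen site set, or divides the summed per-site values by the genome
length — both scales are reported in the field (genome-wide diversity is
orders of magnitude below diversity at segregating sites), so the
denominator is always an explicit argument.

**Within hosts.** From read-level alternative-allele fractions $p$ at depth
$D$, $\pi_{site} = 2p(1-p)\cdot\frac{D}{D-1}$ — heterozygosity with the
read-pair sampling correction, which makes the estimator unbiased for the
true within-host heterozygosity at every depth. The uncorrected $2p(1-p)$
form is available via `corrected = FALSE`. Sites with fewer than two reads
are skipped; sites absent from a host's profile are treated as fixed with
unknown depth and skipped likewise. The exact estimator used upstream of
the published within-host ranges is not fully specified in the literature
this package follows, so the correction choice is surfaced prominently as a
potential source of small discrepancies.

**Watterson's theta.** $\theta = S/(a_n L)$ per site, with $S$ polymorphic
columns inside an ORF, $a_n = \sum_{i=1}^{n-1} 1/i$, and $L$ the ORF
length. `thetaPerOrf()` applies this per annotation row;
`dNDensityByGroup()` summarizes nonsynonymous SNVs per kbp per ORF and per
functional group (replication, transcription, per os infection, virion
assembly/packaging, auxiliary, unknown).

## Variant effects and genome features

`classifySnv()` recomputes the affected codon on the coding strand;
changes in an ORF's first codon or terminal stop codon are called
`translation_start_site_SNV` / `termination_site_SNV` with positional
precedence over the synonymous/nonsynonymous distinction. Overlapping ORFs
each receive a call (baculovirus genomes are compact; discarding either
would lose per-gene counts). `classifyIndel()` separates frameshift
(length change not a multiple of three) from inframe events, refined by
`classifyMicrosatellite()`: a unit length u in 1..4 is assigned when the
event is a whole number of copies of a u-mer and the reference context
carries at least three tandem copies; the smallest qualifying u wins.
Unit lengths 1/3/4 correspond to microsatellite Types I/III/IV; Type II is
supported for completeness. `scanHrs()` finds homologous-repeat regions by
scanning for the 10-bp palindrome `TTTACGTAAA` (its own reverse complement,
so one strand suffices) with up to one mismatch, merging hits within 500 bp
and dropping regions with fewer than two repeats; window and mismatch
tolerance are exposed because published hr counts do not state detection
parameters.

## Population structure (DAPC)

`genotypePca()` performs a column-centred singular value decomposition of
the samples x sites 0/1 matrix (missing calls mean-imputed per site);
eigenvalues are component variances, and retaining all components
reconstructs the centred data exactly (a tested identity).
`findClusters()` scores k-means solutions (best of 20 seeded restarts,
`stats::kmeans`) for each candidate K with the k-means BIC

$$BIC(K) = n\,\ln(WSS_K/n) + K\,\ln(n),$$

and the most likely number of genetic groups minimizes the curve. Note a
property of this criterion: the penalty does not grow with the embedding
dimension, so on low-dimensional data it splits Gaussian clusters too
eagerly; cluster-number recovery is reliable when the retained score space
is moderately high-dimensional, which genotype data provide naturally.
`selectNPca()` chooses the number of retained principal components by
stratified cross-validation of assignment error (root mean squared error
over folds; ties resolve toward fewer components). `fitDapc()` fits the
discriminant axes with `MASS::lda` on the retained components; assignment
probabilities are the per-group Gaussian posteriors in discriminant space,
and `assignmentRate()` is the fraction of samples whose maximum-posterior
group matches their a priori label. The number of discriminant axes
defaults to `min(groups - 1, nPca)`.

## Infection-multiplicity patterns

Within-host allele-frequency distributions at segregating sites fall into
three classes: A (one strain — all frequencies near 0/1), B (two strains —
bimodal), C (more than two strains — diverse without clean bimodality).
`classifyPattern()` operationalizes this:

1. Frequencies inside the intermediate band [0.10, 0.90] are
   "intermediate"; if their fraction is at most 0.05 the host is Pattern A.
2. Otherwise 1..4 one-dimensional Gaussian mixtures (`mclust`,
   equal-variance components — read-sampling noise is near-homoskedastic
   inside the band) are fitted to the intermediate frequencies and the
   component count chosen by BIC. Three or more components is Pattern C.
3. Two components: two haploid strains at proportions q and 1-q produce
   *mirrored* frequency modes, so the two fitted means must sum to ~1. If
   they do (within 0.1) the host is Pattern B; if not, the asymmetry
   requires at least a third strain and the host is Pattern C
   (`"asymmetric-modes"` note).
4. One component is Pattern B with a `"merged-modes"` note: a single
   intermediate peak near 0.5 can arise from two strains at ~50:50 but not
   from one strain.

Hosts with fewer than 10 usable sites (depth >= 10) are `"undetermined"`,
never silently A. The whole procedure is invariant to flipping every
frequency p -> 1-p (band, mixture and complementarity rule are all
label-symmetric), and this is asserted host-by-host in the tests. Hosts
whose within-host pi falls in the published A/B overlap zone are decided by
distribution shape, not by pi, which can relabel borderline isolates
relative to analyses that threshold on pi.

`mixedToSingleRatio()` computes (#B + #C)/#A per (year, season, wave)
stratum (infinite ratios are flagged, not dropped) and rank-correlates the
ratio with the wave ordinal, with a permutation p-value (pattern labels
shuffled across hosts; one-sided toward the bottleneck-driven negative
trend).

## Wave-level trends

`medianPiByWave()` reports the median within-host pi per (year, season,
wave) stratum over the full grid, marking empty strata as missing.
`imputeMissingWave()` fills a missing stratum with the arithmetic mean of
the same wave's medians from the other growing seasons (flagged, zero
count, donors untouched); a wave missing everywhere is an error.
`testWaveDecline()` tests the headline contrast median(pi | W1) -
median(pi | W2 u W3) by permuting wave labels *within* (year, season)
strata — respecting the season blocking — with
$p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$. An ordered-decline
alternative (negative rank correlation with wave) is available via
`alternative = "ordered"`. The permutation test was chosen over rank-sum
tests to respect the blocking; its type-I error is calibrated by
simulation in the test suite (1,000 null cohorts, nominal 5%).

## The epidemic generator

`simulateCohort()` produces cohorts with the statistical structure the
analysis assumes. Its default configuration is the reference condition set of the simulated
system;
none of its parameters are adjusted by tests.

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 112,000 bp | circular genome, reference coordinates |
| `gc_content` | 0.35 | AT-rich baculovirus base composition |
| `n_years` x `seasons_per_year` x `waves_per_season` | 4 x 2 x 3 | sampling design |
| `hosts_per_wave` | 6 | 144 isolates (~140-isolate cohort scale) |
| `reservoir_size` / `n_lineages` | 80 / one per year | soil strain pool |
| `reservoir_mutation_rate` | 2.5e-3 | lineage-ancestor divergence (~0.5% between years) |
| `within_lineage_rate` | 1e-3 | strain divergence within a lineage |
| `carryover_fraction` | 0.15 | founder mass drawn from other years' lineages |
| `founder_count_per_wave` | 20 / 5 / 2 | transmission bottleneck sizes |
| `multiplicity_probs` | rows (0.30,0.25,0.45), (0.55,0.22,0.23), (0.85,0.08,0.07) | P(1 / 2 / >2 strain draws) per wave |
| `mixture_concentration` | 1 | Dirichlet concentration of strain proportions |
| `read_depth` | 100 | Poisson mean coverage |
| `background_fraction` | 0.02 | ambient wave-pool trace in every host's reads |
| `error_rate` | 0 | per-base sequencing error |
| `consensus_noise_rate` | 0.01 | per-site consensus miscall probability |
| `indel_rate` | 0 | optional strain-level indels (variant table only) |
| `n_hr` | 12 | planted palindrome-repeat regions |

Design choices that deserve explanation:

* **Annual lineages with soil carryover.** Each year's founders come
  mostly from a year-specific reservoir lineage (annual genetic
  differentiation, as observed in multi-year epidemics) but with a 15%
  chance per founding particle of coming from another year's lineage (the
  soil reservoir accumulates across years). Carryover is what gives the
  simulation its deeply divergent co-infections — within-host diversity at
  segregating sites in the observed range (up to ~0.2) — its wave-graded
  diversity floor (alien strains are progressively purged by the W2/W3
  bottlenecks), and its imperfect year assignment, mirroring field data.
* **Bottlenecks as multinomial founder draws.** Wave w+1 is founded by
  `founder_count_per_wave[w+1]` particles drawn with replacement from the
  realized strain frequencies of wave w (founder effect plus replication
  drift in one step; the simplest law that produces founder effects). Each
  host likewise draws k particles (k ~ `multiplicity_probs`) with
  replacement from the wave pool and deduplicates, so a wave founded by a
  single strain yields single-strain hosts even when k = 2 is drawn, and
  skewed wave frequencies reduce *effective* multiplicity — the mechanism
  behind the declining mixed-infection ratio.
* **Wave-specific multiplicity.** The mixed fraction declines 70% -> 45%
  -> 15% across waves, averaging to roughly 57% single / 18% two-strain /
  25% multi-strain infections — the declining mixed:single ratio reported
  for this system, with the overall pattern-class proportions in the
  observed neighbourhood.
* **Read-level observation.** Depth is Poisson; alternative-read counts
  are binomial at the strain-proportion-weighted allele frequency, blended
  with `background_fraction` of the ambient wave pool (trace inoculum
  below consensus level). The background term is why single-strain hosts
  show a small, wave-dependent diversity floor instead of exactly zero —
  matching the nonzero Pattern-A diversity observed in real isolates.
  Consensus calls take the majority allele and are then flipped with
  probability `consensus_noise_rate`, a stand-in for whole-genome
  amplification chimeras and assembly miscalls, which perturb consensus
  genomes but not read-level frequencies.
* **What the generator does not model:** within-host continuous-time
  replication dynamics, recombination, selection, migration between
  sampling sites, and (by default) indels — consensus lengths are all
  equal to `genome_length`, unlike real assemblies. Optional indel events
  (`indel_rate > 0`) enter the variant table only, to exercise the effect
  classifier. Passing tests on this generator therefore demonstrate
  correctness of the estimators and recovery of the *simulated* structure;
  they do not certify behaviour under real-data pathologies (uneven
  coverage, mapping artefacts, assembly chimeras beyond the flip model).

### The controlled-separability structure cohort

The BIC cluster scan on exact consensus haplotypes legitimately detects
sub-annual structure under the default conditions: drift-amplified strains
form tight haplotype clumps and cross-year admixed hosts form bridges, and
k-means BIC counts them. Cluster-number recovery (K = number of years) is
therefore assessed on a dedicated structure configuration in which
separability is controlled: no carryover, a larger reservoir
(`reservoir_size = 160`, so the two seasons of a year draw mostly disjoint
founder subsets), weak within-lineage divergence (1e-4), and a higher
consensus-noise rate (0.05) providing diffuse within-year variation. Under
that configuration the scan selects K = 4 and a-priori year DAPC assigns
>= 90% of isolates correctly, reproducibly across 100 seeds; under the
default (carryover) conditions the scan typically returns K of 4-6 and
year assignment sits near 95%.

## Numerical and procedural choices

* Ties in consensus calls (equal ref/alt read counts) resolve to the
  reference; zero-depth sites are missing calls.
* k-means uses up to 50 Lloyd iterations and 20 seeded restarts; the
  restart count is exposed because cluster-number recovery depends on it.
  The BIC scan skips K >= n with a warning; within-cluster sums of squares
  are floored at 1e-12 before the logarithm so that exact-duplicate
  degeneracies stay finite.
* Mixture fits use equal-variance components with mclust's deterministic
  hierarchical initialization, making pattern calls reproducible without a
  seed; the component cap is `min(4, #distinct values, n/2)`.
* All Monte-Carlo machinery (generator, permutation tests, k-means
  restarts, CV folds) is driven by explicit integer seeds.
* Test-suite problem sizes: the statistical validation runs on 12–20 kb
  genomes, scan ranges 1:15 (one full 1:40 curve is exercised), and
  199–499 permutations; these are stated sizes of the package's validation
  experiments, chosen so the full suite runs in minutes while keeping every
  per-site rate, bottleneck size, multiplicity and depth at its default.
  `scripts/acceptance.R` runs the full 112 kb default cohort.

## Known limitations

* Within-host pi at segregating sites is blind to co-infection by strains
  whose discriminating sites are population-rare: only variation that is
  frequent at the cohort level (carried by >7 consensus genomes) enters
  the segregating-site set. This is a property of the segregating-site
  definition, not of the estimator.
* The pattern classifier's complementarity rule assumes two-strain hosts
  have a single mirrored mode pair; a three-strain host whose mixture
  happens to produce complementary modes is (rarely) labelled B.
* The k-means BIC has no dimension term; on low-dimensional inputs it
  over-splits, and on clumpy haplotype data the "true" K it reports is the
  number of haplotype clusters, which may exceed the number of years.
* Structural variants and large indels are out of scope; unparseable
  effect inputs surface as errors rather than silent categories.
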