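# generator tests run on deliberately small genomes; the condition parameters
# (rates, founder counts, multiplicity, depth) stay at their defaults unless a
# limit case is the point of the test

test_that("zero mutation rate yields identical haplotypes and zero diversity", {
    cfg <- simConfig(genome_length = 4000L, reservoir_size = 6L,
                     n_lineages = 1L, reservoir_mutation_rate = 0, n_hr = 0L)
    expect_warning(pool <- buildReservoir(cfg, seed = 1), "zero polymorphic")
    expect_length(pool$positions, 0L)
    hap <- strainHaplotypes(pool)
    expect_identical(length(unique(as.character(hap))), 1L)

    co <- suppressWarnings(simulateCohort(
        simConfig(genome_length = 4000L, reservoir_size = 6L, n_lineages = 1L,
                  reservoir_mutation_rate = 0, hosts_per_wave = 2L,
                  n_years = 1L, n_hr = 0L),
        seed = 2, sequences = FALSE))
    expect_identical(nrow(co$vm), 0L)
    expect_length(findSegregatingSites(co$vm, 0L)$positions, 0L)
})

test_that("the reservoir is reproducible and matches the divergence oracle", {
    cfg <- simConfig(genome_length = 20000L, reservoir_size = 12L,
                     n_lineages = 1L, reservoir_mutation_rate = 0.0025,
                     n_hr = 0L)
    p1 <- buildReservoir(cfg, seed = 42)
    p2 <- buildReservoir(cfg, seed = 42)
    expect_identical(as.character(strainHaplotypes(p1)),
                     as.character(strainHaplotypes(p2)))

    # expected pairwise difference per site between two strains mutated
    # independently from one reference at rate r is 2 r (1 - r); compare the
    # empirical mean over 50 pairs (counted directly on the haplotypes)
    # against that closed form within 3 standard errors
    r <- 0.0025
    hap <- as.character(strainHaplotypes(p1))
    pairs <- t(combn(length(hap), 2))[1:50, ]
    div <- apply(pairs, 1, function(ij) {
        a <- strsplit(hap[ij[1]], "")[[1]]
        b <- strsplit(hap[ij[2]], "")[[1]]
        mean(a != b)
    })
    expected <- 2 * r * (1 - r)
    se <- sd(div) / sqrt(length(div))
    expect_lt(abs(mean(div) - expected), 3 * se + 1e-12)
})

test_that("single-strain hosts have read frequencies fixed at 0 or 1", {
    cfg <- simConfig(genome_length = 8000L, reservoir_size = 8L,
                     n_lineages = 1L, hosts_per_wave = 3L, n_years = 1L,
                     seasons_per_year = 1L,
                     founder_count_per_wave = c(8L, 5L, 2L),
                     multiplicity_probs = c(1, 0, 0),
                     background_fraction = 0, consensus_noise_rate = 0,
                     n_hr = 0L)
    pool <- buildReservoir(cfg, seed = 3)
    s <- simulateSeason(pool, cfg, seed = 4)
    for (id in sampleIds(s$vm)) {
        expect_identical(s$truth[[id]]$multiplicity, 1L)
        prof <- alleleProfile(s$vm, id)
        expect_true(all(prof$p %in% c(0, 1)))
    }
})

test_that("a bottleneck of one founder makes later waves monomorphic", {
    cfg <- simConfig(genome_length = 8000L, reservoir_size = 10L,
                     n_lineages = 1L, hosts_per_wave = 4L, n_years = 1L,
                     seasons_per_year = 1L,
                     founder_count_per_wave = c(8L, 1L, 1L),
                     background_fraction = 0, consensus_noise_rate = 0,
                     n_hr = 0L)
    pool <- buildReservoir(cfg, seed = 5)
    s <- simulateSeason(pool, cfg, seed = 6)
    gt <- genotypes(s$vm)
    for (w in c("W2", "W3")) {
        cols <- s$meta$wave == w
        expect_identical(s$truth[[which(cols)[1]]]$multiplicity, 1L)
        expect_true(all(apply(gt[, cols, drop = FALSE], 1,
                              function(g) length(unique(g)) == 1L)))
    }
})

test_that("founder counts exceeding the pool are capped with a warning", {
    cfg <- simConfig(genome_length = 6000L, reservoir_size = 4L,
                     n_lineages = 1L, hosts_per_wave = 2L, n_years = 1L,
                     seasons_per_year = 1L,
                     founder_count_per_wave = c(50L, 5L, 2L), n_hr = 0L)
    pool <- buildReservoir(cfg, seed = 7)
    expect_warning(simulateSeason(pool, cfg, seed = 8), "capped")
})

test_that("strain proportions in the truth sum to one", {
    co <- simulateCohort(simConfig(genome_length = 6000L, n_years = 2L,
                                   hosts_per_wave = 3L, n_hr = 0L),
                         seed = 9, sequences = FALSE)
    for (h in co$truth) {
        expect_equal(sum(h$proportions), 1, tolerance = 1e-12)
        expect_identical(length(h$strains), h$multiplicity)
    }
})

test_that("emitted cohorts round-trip through the readers byte-stably", {
    cfg <- simConfig(genome_length = 5000L, n_years = 2L, hosts_per_wave = 2L,
                     n_hr = 2L)
    co <- simulateCohort(cfg, seed = 11)
    d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
    emitCohort(co, d1)
    expect_error(emitCohort(co, d1), "overwrite")

    co2 <- simulateCohort(cfg, seed = 11)
    emitCohort(co2, d2)
    for (f in c("consensus.fasta", "variants.vcf", "metadata.csv",
                "truth.json")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }

    # VCF round trip recovers genotypes and exact AD counts
    vm <- readVariants(file.path(d1, "variants.vcf"))
    expect_identical(unname(genotypes(vm)), unname(genotypes(co$vm)))
    expect_identical(unname(refDepth(vm)), unname(refDepth(co$vm)))
    expect_identical(unname(altDepth(vm)), unname(altDepth(co$vm)))
    expect_identical(variantPositions(vm), variantPositions(co$vm))

    # consensus FASTA parses and matches the in-memory genomes
    seqs <- readConsensusSet(file.path(d1, "consensus.fasta"))
    expect_identical(as.character(seqs), as.character(co$genomes))

    # metadata round trip; truth lists every sample exactly once
    meta <- readMetadata(file.path(d1, "metadata.csv"))
    expect_identical(meta$sample_id, co$meta$sample_id)
    truth <- jsonlite::read_json(file.path(d1, "truth.json"))
    expect_identical(sort(names(truth$hosts)), sort(co$meta$sample_id))
})

test_that("consensus genotypes equal the majority-allele truth", {
    cfg <- simConfig(genome_length = 8000L, n_years = 1L, hosts_per_wave = 3L,
                     consensus_noise_rate = 0, background_fraction = 0,
                     n_hr = 0L)
    co <- simulateCohort(cfg, seed = 13, sequences = FALSE)
    gt <- genotypes(co$vm)
    for (id in co$meta$sample_id) {
        tr <- co$truth[[id]]
        fHost <- as.numeric(tr$proportions %*%
                            co$pool$carriage[tr$strains, , drop = FALSE])
        ad <- altDepth(co$vm)[, id]; rd <- refDepth(co$vm)[, id]
        expect_identical(unname(gt[, id]),
                         ifelse(ad + rd == 0L, NA_integer_,
                                ifelse(ad > rd, 1L, 0L)))
        # reads at fixed sites cannot contradict the strain content
        expect_true(all(ad[fHost == 0] == 0))
        expect_true(all(rd[fHost == 1] == 0))
    }
})

test_that("tighter founder bottlenecks do not increase late-wave diversity", {
    mild <- simConfig(genome_length = 6000L, n_years = 1L,
                      seasons_per_year = 1L, hosts_per_wave = 4L,
                      founder_count_per_wave = c(12L, 8L, 8L), n_hr = 0L)
    severe <- simConfig(genome_length = 6000L, n_years = 1L,
                        seasons_per_year = 1L, hosts_per_wave = 4L,
                        founder_count_per_wave = c(12L, 2L, 1L), n_hr = 0L)
    w3pi <- function(cfg, seed) {
        co <- simulateCohort(cfg, seed = seed, sequences = FALSE)
        keep <- co$meta$wave == "W3"
        vm <- co$vm[, keep]
        poly <- findSegregatingSites(vm, 0L)
        if (!length(poly$positions)) return(0)
        suppressWarnings(piBetweenHosts(vm, NULL))
    }
    piMild <- vapply(1:60, function(s) w3pi(mild, s), numeric(1))
    piSevere <- vapply(1:60, function(s) w3pi(severe, 1000 + s), numeric(1))
    expect_lt(mean(piSevere), mean(piMild))
})

test_that("synthetic ORF tilings are valid annotations", {
    orfs <- syntheticOrfs(20000L, seed = 1)
    expect_true(all(orfs$end > orfs$start))
    expect_true(all((orfs$end - orfs$start) %% 3L == 0L))
    expect_true(all(orfs$end <= 20000L))
    expect_false(any(duplicated(orfs$name)))
    # non-overlapping
    expect_true(all(orfs$start[-1] >= head(orfs$end, -1)))
})
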