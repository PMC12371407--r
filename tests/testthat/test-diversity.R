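test_that("between-host pi matches hand-computed cases", {
    # monomorphic cohort
    expect_equal(piBetweenHosts(makeVm(matrix(0L, 10, 4))), 0)

    # 2 samples differing at 2 of 10 sites: per differing site
    # n/(n-1) * (1 - sum f^2) = 2 * 0.5 = 1, mean over 10 sites = 0.2
    gt <- matrix(0L, 10, 2)
    gt[c(3, 7), 2] <- 1L
    expect_equal(piBetweenHosts(makeVm(gt)), 0.2)

    # 3 samples, columns (A,A,T) and (A,T,T):
    # pi_site = 3/2 * (1 - 4/9 - 1/9) = 2/3 at both sites
    gt3 <- cbind(c(0L, 0L), c(0L, 1L), c(1L, 1L))
    expect_equal(piBetweenHosts(makeVm(gt3)), 2 / 3, tolerance = 1e-12)
})

test_that("between-host pi equals the exhaustive pairwise oracle", {
    pairwiseOracle <- function(gt) {
        perSite <- apply(gt, 1, function(g) {
            g <- g[!is.na(g)]
            if (length(g) < 2) return(NA_real_)
            d <- outer(g, g, "!=")
            mean(d[upper.tri(d)])
        })
        mean(perSite, na.rm = TRUE)
    }
    set.seed(5)
    for (rep in 1:40) {
        gt <- randomGt(sample(3:30, 1), sample(3:20, 1), pAlt = runif(1, .1, .6))
        # ensure every site has >= 2 non-missing calls to avoid skip warnings
        keep <- rowSums(!is.na(gt)) >= 2
        gt <- gt[keep, , drop = FALSE]
        if (!nrow(gt)) next
        expect_equal(piBetweenHosts(makeVm(gt)), pairwiseOracle(gt),
                     tolerance = 1e-12)
    }
})

test_that("between-host pi supports the genome-length denominator", {
    gt <- matrix(0L, 4, 2); gt[1, 2] <- 1L
    vm <- makeVm(gt)
    bySites <- piBetweenHosts(vm)
    byGenome <- piBetweenHosts(vm, denominator = "genome", genomeLength = 1000)
    expect_equal(byGenome, bySites * 4 / 1000)
    expect_error(piBetweenHosts(vm, denominator = "genome"), "genomeLength")
})

test_that("within-host pi evaluates the read-pair estimator exactly", {
    prof <- data.frame(position = 10L, p = 0.5, depth = 100L)
    expect_equal(piWithinHost(prof, 10L), 2 * 0.25 * 100 / 99,
                 tolerance = 1e-9)
    prof2 <- data.frame(position = c(10L, 20L), p = c(0.2, 0),
                        depth = c(50L, 50L))
    expect_equal(piWithinHost(prof2, c(10L, 20L)),
                 (2 * 0.2 * 0.8 * 50 / 49 + 0) / 2, tolerance = 1e-9)
    # fixed alleles give exactly zero
    prof3 <- data.frame(position = c(1L, 2L), p = c(0, 1), depth = c(40L, 40L))
    expect_equal(piWithinHost(prof3, c(1L, 2L)), 0)
    # uncorrected variant drops the D/(D-1) factor
    expect_equal(piWithinHost(prof, 10L, corrected = FALSE), 0.5)
    expect_error(piWithinHost(prof, integer(0)), "empty site set")
})

test_that("within-host pi is invariant to site order and skips low depth", {
    prof <- data.frame(position = c(5L, 15L, 25L), p = c(0.3, 0.6, 0.1),
                       depth = c(60L, 80L, 100L))
    sites <- c(5L, 15L, 25L)
    expect_equal(piWithinHost(prof, sites),
                 piWithinHost(prof[c(3, 1, 2), ], rev(sites)))
    # a D < 2 site and an absent site are both skipped
    prof$depth[2] <- 1L
    expect_equal(piWithinHost(prof, c(sites, 999L)),
                 mean(2 * c(0.3 * 0.7 * 60 / 59, 0.1 * 0.9 * 100 / 99)))
})

test_that("Watterson's theta matches the harmonic-sum formula", {
    expect_equal(wattersonTheta(3, 4, 100), 3 / ((1 + 1/2 + 1/3) * 100),
                 tolerance = 1e-9)
    expect_equal(round(wattersonTheta(3, 4, 100), 6), 0.016364)
    expect_equal(wattersonTheta(0, 10, 500), 0)     # no polymorphism
    expect_equal(wattersonTheta(7, 2, 100), 7 / 100) # a_2 = 1 base case
    expect_error(wattersonTheta(3, 1, 100), "n >= 2")

    # monotone in S, strictly decreasing in n
    expect_true(all(diff(sapply(0:10, wattersonTheta, n = 8, L = 100)) >= 0))
    expect_true(all(diff(sapply(2:12, function(n)
        wattersonTheta(5, n, 100))) < 0))
})

test_that("per-ORF theta counts polymorphic columns inside each ORF", {
    gt <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
    vm <- makeVm(gt, position = c(50L, 150L, 250L, 350L))
    orfs <- data.frame(name = c("a", "b"), start = c(0L, 200L),
                       end = c(198L, 500L), strand = "+",
                       functional_group = "unknown")
    th <- thetaPerOrf(vm, orfs)
    # ORF a: sites 50 (poly), 150 (mono) -> S=1; ORF b: 250 poly, 350 fixed-alt
    expect_equal(unname(th["a"]), wattersonTheta(1, 3, 198))
    expect_equal(unname(th["b"]), wattersonTheta(1, 3, 300))
})

test_that("nonsynonymous densities per ORF and group average correctly", {
    orfs <- data.frame(name = c("a", "b", "c"),
                       start = c(0L, 1000L, 3000L),
                       end = c(1000L, 3000L, 4000L), strand = "+",
                       functional_group = c("auxiliary", "auxiliary",
                                            "replication"))
    eff <- data.frame(position = c(1L, 2L, 3L, 4L, 5L, 1500L, 1600L, 3500L),
                      orf = c(rep("a", 5L), "b", "b", "c"),
                      effect = c(rep("nonsynonymous_SNV", 5L),
                                 "nonsynonymous_SNV", "synonymous_SNV",
                                 "nonsynonymous_SNV"))
    expect_warning(d <- dNDensityByGroup(eff, orfs), "omitted")
    expect_equal(unname(d$per_orf["a"]), 5)      # 5 per 1 kbp
    expect_equal(unname(d$per_orf["b"]), 0.5)    # 1 per 2 kbp
    expect_equal(unname(d$per_group["auxiliary"]), mean(c(5, 0.5)))
    expect_equal(unname(d$per_group["replication"]), 1)

    none <- eff[0, ]
    expect_warning(d0 <- dNDensityByGroup(none, orfs))
    expect_true(all(d0$per_orf == 0))
})

test_that("single-strain hosts show only noise-level within-host diversity", {
    pool <- makeFlatPool(91, n_strains = 6L, L = 8000L)
    piw <- replicate(20, {
        prof <- simulateHostProfile(pool, strains = sample.int(6L, 1L),
                                    depth = 100)
        piWithinHost(prof, pool$positions)
    })
    expect_true(all(piw <= 3 / 100))
})
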