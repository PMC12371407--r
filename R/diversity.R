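#' Between-host nucleotide diversity from consensus calls
#'
#' Per site, \eqn{\pi_{site} = \frac{n}{n-1}\,(1 - \sum_a f_a^2)} where
#' \eqn{f_a} are allele frequencies among non-missing consensus calls and
#' \eqn{n} is the non-missing sample count — the sample-size-corrected
#' heterozygosity, algebraically identical to the average number of pairwise
#' differences per site. The result is the mean of \eqn{\pi_{site}} over the
#' chosen site set, or the sum divided by `genomeLength` when
#' `denominator = "genome"` (both scales are reported in the field:
#' genome-wide diversity is orders of magnitude below diversity at
#' segregating sites).
#'
#' @param vm a [VariantMatrix-class].
#' @param sites a `SegregatingSites`, integer vector of 0-based positions, or
#'   `NULL` for all sites in `vm`.
#' @param denominator `"sites"` (mean over the site set) or `"genome"`
#'   (sum over sites divided by `genomeLength`).
#' @param genomeLength required for `denominator = "genome"`.
#' @return A single numeric value.
#' @export
piBetweenHosts <- function(vm, sites = NULL,
                           denominator = c("sites", "genome"),
                           genomeLength = NULL) {
    denominator <- match.arg(denominator)
    if (ncol(vm) < 2L) stop("need at least 2 samples")
    pos <- .sitePositions(sites, vm)
    if (!length(pos)) stop("empty site set")
    idx <- match(pos, variantPositions(vm))
    gt <- genotypes(vm)
    piSite <- numeric(0)
    skipped <- 0L
    for (i in idx) {
        g <- if (is.na(i)) integer(0) else gt[i, ][!is.na(gt[i, ])]
        if (length(g) < 2L) {
            # a requested position absent from vm is monomorphic by definition
            if (is.na(i)) piSite <- c(piSite, 0) else skipped <- skipped + 1L
            next
        }
        n <- length(g)
        f <- tabulate(g + 1L, nbins = max(g) + 1L) / n
        piSite <- c(piSite, n / (n - 1) * (1 - sum(f^2)))
    }
    if (skipped > 0L)
        warning(skipped, " site(s) with < 2 non-missing calls skipped")
    if (!length(piSite)) stop("no usable sites")
    if (denominator == "genome") {
        if (is.null(genomeLength)) stop("genomeLength required")
        sum(piSite) / genomeLength
    } else mean(piSite)
}

#' Extract a sample's read-level allele profile
#'
#' @param vm a [VariantMatrix-class] with depth assays.
#' @param sample sample id or column index.
#' @return data.frame with columns `position` (0-based), `p` (alternative
#'   read fraction) and `depth` (total reads), restricted to covered sites.
#' @export
alleleProfile <- function(vm, sample) {
    j <- if (is.character(sample)) match(sample, sampleIds(vm)) else sample
    if (is.na(j)) stop("unknown sample: ", sample)
    rd <- refDepth(vm)[, j]
    ad <- altDepth(vm)[, j]
    if (all(is.na(rd))) stop("no allele depths recorded for sample ", sample)
    tot <- rd + ad
    keep <- !is.na(tot) & tot >= 1L
    data.frame(position = variantPositions(vm)[keep],
               p = ad[keep] / tot[keep], depth = tot[keep])
}

#' Within-host nucleotide diversity from read-level allele frequencies
#'
#' Per site, \eqn{\pi_{site} = 2p(1-p)\cdot D/(D-1)}: the read-pair estimator
#' of heterozygosity, where \eqn{p} is the alternative-read fraction and
#' \eqn{D} the read depth; the \eqn{D/(D-1)} factor removes the downward
#' sampling bias (set `corrected = FALSE` for plain \eqn{2p(1-p)}). Sites in
#' the requested set that are absent from the profile are treated as fixed
#' (\eqn{p = 0}) with unknown depth and, like any site with \eqn{D < 2},
#' are skipped. The result is the mean over the used sites, or the sum
#' divided by `genomeLength` when `denominator = "genome"`.
#'
#' @param profile data.frame from [alleleProfile()] (columns `position`, `p`,
#'   `depth`).
#' @param sites a `SegregatingSites` or integer vector of 0-based positions.
#' @param corrected apply the D/(D-1) correction (default `TRUE`).
#' @param denominator `"sites"` or `"genome"`.
#' @param genomeLength required for `denominator = "genome"`.
#' @return A single numeric value.
#' @export
piWithinHost <- function(profile, sites, corrected = TRUE,
                         denominator = c("sites", "genome"),
                         genomeLength = NULL) {
    denominator <- match.arg(denominator)
    pos <- .sitePositions(sites)
    if (!length(pos)) stop("empty site set: within-host pi undefined")
    hit <- profile[match(pos, profile$position), , drop = FALSE]
    use <- !is.na(hit$depth) & hit$depth >= 2L
    p <- hit$p[use]; d <- hit$depth[use]
    piSite <- 2 * p * (1 - p)
    if (corrected) piSite <- piSite * d / (d - 1)
    if (denominator == "genome") {
        if (is.null(genomeLength)) stop("genomeLength required")
        return(sum(piSite) / genomeLength)
    }
    if (!length(piSite)) return(NA_real_)
    mean(piSite)
}

#' Within-host pi for every sample of a cohort
#'
#' @param vm a [VariantMatrix-class] with depth assays.
#' @inheritParams piWithinHost
#' @return Named numeric vector, one value per sample.
#' @export
piWithinCohort <- function(vm, sites, corrected = TRUE,
                           denominator = "sites", genomeLength = NULL) {
    vapply(sampleIds(vm), function(s)
        piWithinHost(alleleProfile(vm, s), sites, corrected = corrected,
                     denominator = denominator, genomeLength = genomeLength),
        numeric(1))
}

#' Watterson's theta
#'
#' \eqn{\theta = S / (a_n L)} per site, where \eqn{S} is the number of
#' segregating (polymorphic) columns, \eqn{a_n = \sum_{i=1}^{n-1} 1/i} the
#' harmonic number of the sample size, and \eqn{L} the sequence length in bp.
#'
#' @param S number of segregating sites.
#' @param n number of sampled sequences (>= 2).
#' @param L sequence length in bp (>= 1).
#' @return theta per site.
#' @examples
#' wattersonTheta(3, 4, 100)  # 0.016364
#' @export
wattersonTheta <- function(S, n, L) {
    if (n < 2L) stop("Watterson's theta requires n >= 2")
    if (L < 1L) stop("L must be >= 1")
    a_n <- sum(1 / seq_len(n - 1L))
    S / (a_n * L)
}

#' Per-ORF Watterson's theta for a cohort
#'
#' For each ORF, S counts the polymorphic variant columns (>= 2 observed
#' alleles among non-missing consensus calls) whose position falls inside the
#' ORF, n is the cohort size, and L the ORF length.
#'
#' @param vm a [VariantMatrix-class].
#' @param orfs data.frame from [readOrfs()].
#' @return Named numeric vector of theta per site, one entry per ORF.
#' @export
thetaPerOrf <- function(vm, orfs) {
    gt <- genotypes(vm)
    poly <- vapply(seq_len(nrow(vm)), function(i) {
        g <- gt[i, ][!is.na(gt[i, ])]
        length(unique(g)) >= 2L
    }, logical(1))
    polyPos <- variantPositions(vm)[poly]
    vapply(seq_len(nrow(orfs)), function(k) {
        S <- sum(polyPos >= orfs$start[k] & polyPos < orfs$end[k])
        wattersonTheta(S, ncol(vm), orfs$end[k] - orfs$start[k])
    }, numeric(1)) |> setNames(orfs$name)
}

#' Nonsynonymous variant density per ORF and per functional group
#'
#' Per ORF: nonsynonymous SNV count divided by ORF length in kbp. Per
#' functional group: the mean density over member ORFs (groups without ORFs
#' are omitted with a warning).
#'
#' @param effects data.frame of effect calls (see [classifyVariants()]).
#' @param orfs data.frame from [readOrfs()].
#' @return list with `per_orf` (named numeric, per kbp) and `per_group`
#'   (named numeric, per kbp).
#' @export
dNDensityByGroup <- function(effects, orfs) {
    dn <- table(factor(effects$orf[effects$effect == "nonsynonymous_SNV"],
                       levels = orfs$name))
    lenKb <- (orfs$end - orfs$start) / 1000
    perOrf <- as.numeric(dn) / lenKb
    names(perOrf) <- orfs$name
    groups <- unique(orfs$functional_group)
    perGroup <- vapply(groups, function(g)
        mean(perOrf[orfs$functional_group == g]), numeric(1))
    empty <- setdiff(c("replication", "transcription", "per_os_infection",
                       "virion_assembly_packaging", "auxiliary", "unknown"),
                     groups)
    if (length(empty))
        warning("functional group(s) without ORFs omitted: ",
                paste(empty, collapse = ", "))
    list(per_orf = perOrf, per_group = perGroup)
}

#' Cohort diversity summary
#'
#' Bundles the headline diversity statistics: between-host pi at the
#' segregating sites, within-host pi per sample (at segregating sites and
#' genome-wide), and per-ORF Watterson's theta.
#'
#' @param vm a [VariantMatrix-class] with depth assays.
#' @param sites a `SegregatingSites` (see [findSegregatingSites()]).
#' @param orfs optional data.frame from [readOrfs()].
#' @param genomeLength genome length in bp for the genome-wide scale.
#' @return list with elements `pi_between`, `pi_within` (named vector),
#'   `pi_all_sites` (named vector, genome-length denominator) and, when
#'   `orfs` is given, `theta_per_orf`.
#' @export
diversitySummary <- function(vm, sites, orfs = NULL, genomeLength = NULL) {
    out <- list(pi_between = piBetweenHosts(vm, sites),
                pi_within = piWithinCohort(vm, sites))
    if (!is.null(genomeLength))
        out$pi_all_sites <- piWithinCohort(vm, variantPositions(vm),
                                           denominator = "genome",
                                           genomeLength = genomeLength)
    if (!is.null(orfs)) out$theta_per_orf <- thetaPerOrf(vm, orfs)
    out
}
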