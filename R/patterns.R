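#' @importFrom mclust Mclust mclustBIC
NULL

#' Classify a host's within-host allele-frequency pattern
#'
#' Operationalizes the three infection patterns seen in within-host
#' allele-frequency distributions at segregating sites:
#' \describe{
#'   \item{A}{single strain — essentially all frequencies near 0 or 1.}
#'   \item{B}{exactly two strains — a bimodal distribution of intermediate
#'     frequencies.}
#'   \item{C}{more than two strains — high diversity without bimodality.}
#' }
#' Sites with frequency inside `intermediate_band` are "intermediate". If
#' their fraction is at most `max_intermediate_fraction_for_A` the host is
#' Pattern A. Otherwise 1..`max_components` one-dimensional Gaussian
#' mixtures are fitted to the intermediate frequencies and the component
#' count selected by BIC: 2 components is Pattern B, 3 or more Pattern C,
#' and 1 component is Pattern B with a `"merged-modes"` note (two strains
#' near 50:50 produce a single peak at 0.5, which one strain cannot).
#' Hosts with fewer than `min_sites` usable sites are `"undetermined"`,
#' never silently A.
#'
#' @param profile data.frame from [alleleProfile()].
#' @param sites a `SegregatingSites` or integer vector of 0-based positions.
#' @param intermediate_band numeric length-2: the intermediate frequency
#'   band (inclusive).
#' @param max_intermediate_fraction_for_A maximum intermediate fraction for
#'   a Pattern A call.
#' @param max_components maximum number of mixture components.
#' @param min_sites,min_depth minimum usable sites (with depth >=
#'   `min_depth`) required for a call.
#' @param sample_id optional id copied into the result.
#' @return A one-row data.frame (`PatternCall`): `sample_id`, `pattern`
#'   (`"A"`, `"B"`, `"C"` or `"undetermined"`), `n_sites`,
#'   `n_intermediate_sites`, `intermediate_fraction`, `n_modes`,
#'   `pi_within`, `note`.
#' @export
classifyPattern <- function(profile, sites,
                            intermediate_band = c(0.10, 0.90),
                            max_intermediate_fraction_for_A = 0.05,
                            max_components = 4L,
                            min_sites = 10L, min_depth = 10L,
                            sample_id = NA_character_) {
    pos <- .sitePositions(sites)
    hit <- profile[profile$position %in% pos, , drop = FALSE]
    hit <- hit[!is.na(hit$p) & hit$depth >= min_depth, , drop = FALSE]
    piW <- if (nrow(hit) >= 1L)
        piWithinHost(profile, sites) else NA_real_
    res <- function(pattern, nModes, note = NA_character_,
                    nInt = NA_integer_, frac = NA_real_) {
        data.frame(sample_id = sample_id, pattern = pattern,
                   n_sites = nrow(hit), n_intermediate_sites = nInt,
                   intermediate_fraction = frac, n_modes = nModes,
                   pi_within = piW, note = note, stringsAsFactors = FALSE)
    }
    if (nrow(hit) < min_sites)
        return(res("undetermined", NA_integer_, note = "too few usable sites"))
    inter <- hit$p >= intermediate_band[1L] & hit$p <= intermediate_band[2L]
    frac <- mean(inter)
    if (frac <= max_intermediate_fraction_for_A)
        return(res("A", 1L, nInt = sum(inter), frac = frac))
    x <- hit$p[inter]
    gMax <- max(1L, min(max_components, length(unique(x)), length(x) %/% 2L))
    fit <- suppressWarnings(Mclust(x, G = seq_len(gMax), modelNames = "E",
                                   verbose = FALSE))
    g <- if (is.null(fit)) 1L else fit$G
    if (g >= 3L) return(res("C", as.integer(g), nInt = sum(inter),
                            frac = frac))
    if (g == 2L) {
        # two haploid strains produce mirrored frequencies q and 1 - q; a
        # two-mode fit whose means do not sum to ~1 implies a third strain
        mu <- sort(as.numeric(fit$parameters$mean))
        if (abs(sum(mu) - 1) > 0.1)
            return(res("C", 3L, note = "asymmetric-modes",
                       nInt = sum(inter), frac = frac))
        return(res("B", 2L, nInt = sum(inter), frac = frac))
    }
    res("B", 2L, note = "merged-modes", nInt = sum(inter), frac = frac)
}

#' Classify every host of a cohort
#'
#' @param vm a [VariantMatrix-class] with depth assays.
#' @param sites a `SegregatingSites` (see [findSegregatingSites()]).
#' @param ... passed to [classifyPattern()].
#' @return data.frame with one `PatternCall` row per sample.
#' @export
classifyCohortPatterns <- function(vm, sites, ...) {
    out <- lapply(sampleIds(vm), function(s)
        classifyPattern(alleleProfile(vm, s), sites, sample_id = s, ...))
    do.call(rbind, out)
}

#' Mixed-to-single infection ratio by epidemic stratum
#'
#' Per (year, season, wave) stratum the ratio (#B + #C) / #A of mixed to
#' single infections; strata without Pattern A calls are reported as `Inf`
#' and flagged. The ratio is rank-correlated (Spearman) against the wave
#' ordinal (W1 = 1, W2 = 2, W3 = 3) pooled across seasons, with a
#' permutation p-value obtained by shuffling the pattern calls across hosts
#' (one-sided toward negative correlation, the direction of a
#' transmission-bottleneck-driven decline of mixed infections).
#'
#' @param calls data.frame from [classifyCohortPatterns()].
#' @param meta metadata data.frame (see [readMetadata()]).
#' @param n_permutations permutation count for the p-value.
#' @param seed optional integer seed.
#' @return list with `table` (per-stratum counts and ratio), `rho`
#'   (Spearman), `p_value`, and `flag` (`"undefined"` when the correlation
#'   cannot be computed, `"infinite-ratio"` when some stratum has no
#'   Pattern A, otherwise `NA`).
#' @export
mixedToSingleRatio <- function(calls, meta, n_permutations = 10000L,
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    df <- merge(calls, meta, by = "sample_id")
    df <- df[df$pattern %in% c("A", "B", "C") & !is.na(df$wave), ,
             drop = FALSE]
    if (!nrow(df)) stop("no classified hosts with wave metadata")
    strat <- function(patterns) {
        agg <- aggregate(list(n = rep(1L, nrow(df))),
                         by = list(year = df$year, season = df$season,
                                   wave = df$wave, single = patterns == "A"),
                         FUN = sum)
        key <- unique(agg[c("year", "season", "wave")])
        key$n_single <- key$n_mixed <- 0L
        for (i in seq_len(nrow(agg))) {
            j <- which(key$year == agg$year[i] & key$season == agg$season[i] &
                       key$wave == agg$wave[i])
            if (agg$single[i]) key$n_single[j] <- agg$n[i]
            else key$n_mixed[j] <- agg$n[i]
        }
        key$ratio <- ifelse(key$n_single > 0L, key$n_mixed / key$n_single,
                            Inf)
        key
    }
    rhoOf <- function(tab) {
        if (nrow(tab) < 2L) return(NA_real_)
        waveOrd <- as.integer(factor(tab$wave, levels = c("W1", "W2", "W3")))
        r <- rank(tab$ratio)
        if (isTRUE(sd(r) == 0) || isTRUE(sd(waveOrd) == 0) ||
            is.na(sd(r))) return(NA_real_)
        stats::cor(r, rank(waveOrd))
    }
    tab <- strat(df$pattern)
    tab <- tab[order(tab$year, tab$season, tab$wave), ]
    rownames(tab) <- NULL
    rho <- rhoOf(tab)
    flag <- if (is.na(rho)) "undefined"
            else if (any(is.infinite(tab$ratio))) "infinite-ratio"
            else NA_character_
    p <- NA_real_
    if (!is.na(rho)) {
        cnt <- 0L
        for (b in seq_len(n_permutations)) {
            rp <- rhoOf(strat(sample(df$pattern)))
            if (!is.na(rp) && rp <= rho) cnt <- cnt + 1L
        }
        p <- (1 + cnt) / (1 + n_permutations)
    }
    list(table = tab, rho = rho, p_value = p, flag = flag)
}
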