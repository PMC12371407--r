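#' @importFrom stats aggregate cor
NULL

## join a named pi vector with metadata; drop samples without wave labels
.trendFrame <- function(pi_within, meta) {
    df <- meta[match(names(pi_within), meta$sample_id), , drop = FALSE]
    if (anyNA(df$sample_id))
        stop("pi values for sample(s) missing from metadata: ",
             paste(names(pi_within)[is.na(df$sample_id)], collapse = ", "))
    df$pi <- as.numeric(pi_within)
    df$wave <- factor(as.character(df$wave), c("W1", "W2", "W3"))
    df$season <- factor(as.character(df$season), c("EARLY", "LATE"))
    df[!is.na(df$wave) & !is.na(df$season) & !is.na(df$pi), , drop = FALSE]
}

#' Median within-host diversity per epidemic stratum
#'
#' Builds the full (year, season) x wave grid over the strata present in the
#' metadata and reports the sample median of within-host pi per stratum;
#' strata without isolates are marked missing (`NA` median, zero count).
#'
#' @param pi_within named numeric vector of within-host pi (names are sample
#'   ids; see [piWithinCohort()]).
#' @param meta metadata data.frame (see [readMetadata()]).
#' @return A `WaveTrend` data.frame: `year`, `season`, `wave`, `median_pi`,
#'   `n`, `imputed`.
#' @export
medianPiByWave <- function(pi_within, meta) {
    df <- .trendFrame(pi_within, meta)
    if (!nrow(df)) stop("no isolates with wave metadata and pi values")
    seasons <- unique(df[c("year", "season")])
    grid <- merge(seasons, data.frame(wave = levels(droplevels(df$wave))),
                  by = NULL)
    grid$median_pi <- NA_real_
    grid$n <- 0L
    for (i in seq_len(nrow(grid))) {
        v <- df$pi[df$year == grid$year[i] & df$season == grid$season[i] &
                   df$wave == grid$wave[i]]
        grid$n[i] <- length(v)
        if (length(v)) grid$median_pi[i] <- median(v)
    }
    grid$imputed <- FALSE
    grid <- grid[order(grid$year, grid$season, grid$wave), ]
    rownames(grid) <- NULL
    class(grid) <- c("WaveTrend", "data.frame")
    grid
}

#' Impute missing wave medians from the other growing seasons
#'
#' A stratum with no isolates receives the arithmetic mean of the same
#' wave's medians from the other (year, season) growing seasons, and is
#' flagged as imputed (its isolate count stays zero). A wave missing from
#' every season is an error — there is nothing to average. Non-missing
#' strata are never altered.
#'
#' @param trend a `WaveTrend` from [medianPiByWave()].
#' @return The trend with missing strata filled in and `imputed` set.
#' @export
imputeMissingWave <- function(trend) {
    miss <- which(is.na(trend$median_pi))
    for (i in miss) {
        donors <- trend$median_pi[trend$wave == trend$wave[i] &
                                  !is.na(trend$median_pi) & !trend$imputed]
        if (!length(donors))
            stop("wave ", trend$wave[i],
                 " missing in all growing seasons; nothing to average")
        trend$median_pi[i] <- mean(donors)
        trend$imputed[i] <- TRUE
    }
    trend
}

## permutation engine: statistic on wave labels permuted within
## (year, season) strata
.permuteWaves <- function(waves, strata) {
    out <- waves
    for (s in unique(strata)) {
        idx <- which(strata == s)
        out[idx] <- waves[idx][sample.int(length(idx))]
    }
    out
}

#' Permutation test of the wave-over-wave diversity decline
#'
#' One-sided test of whether within-host diversity is higher in the first
#' epidemic wave than in the later waves. The default statistic is
#' `median(pi | W1) - median(pi | W2 u W3)` (the headline contrast: initial
#' wave versus subsequent waves); `alternative = "ordered"` uses the
#' negative Spearman correlation of pi with the wave ordinal instead (an
#' ordered-decline alternative). Wave labels are permuted within
#' (year, season) strata, respecting the season blocking, and
#' \eqn{p = (1 + \#\{permuted \ge observed\}) / (1 + n_{perm})}.
#'
#' @param pi_within named numeric vector of within-host pi.
#' @param meta metadata data.frame (see [readMetadata()]).
#' @param n_permutations number of permutations.
#' @param seed optional integer seed.
#' @param alternative `"pooled"` (W1 vs W2+W3 medians) or `"ordered"`.
#' @return list with `statistic`, `p_value`, `method`, `n_permutations`.
#' @export
testWaveDecline <- function(pi_within, meta, n_permutations = 10000L,
                            seed = NULL,
                            alternative = c("pooled", "ordered")) {
    alternative <- match.arg(alternative)
    if (!is.null(seed)) set.seed(seed)
    df <- .trendFrame(pi_within, meta)
    waves <- as.character(df$wave)
    tab <- table(waves)
    if (length(tab) < 2L || any(tab < 3L))
        stop("need >= 2 waves with >= 3 isolates each (have: ",
             paste(names(tab), tab, sep = "=", collapse = ", "), ")")
    strata <- paste(df$year, df$season)
    statOf <- if (alternative == "pooled") {
        function(w) median(df$pi[w == "W1"]) - median(df$pi[w != "W1"])
    } else {
        function(w) -cor(rank(df$pi),
                         rank(as.integer(factor(w, c("W1", "W2", "W3")))))
    }
    obs <- statOf(waves)
    cnt <- 0L
    for (b in seq_len(n_permutations))
        if (statOf(.permuteWaves(waves, strata)) >= obs) cnt <- cnt + 1L
    list(statistic = obs, p_value = (1 + cnt) / (1 + n_permutations),
         method = paste0("stratified wave-label permutation (",
                         alternative, ")"),
         n_permutations = as.integer(n_permutations))
}
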