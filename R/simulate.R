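#' @importFrom stats rbinom rpois rgamma runif median setNames
NULL

#' Configuration for the synthetic epidemic generator
#'
#' Defaults emulate a persistent granulovirus epidemic on a
#' ~112 kb, 35% GC circular genome, sampled over 4 years x 2 rice-growing
#' seasons x 3 epidemic waves, with founder bottlenecks between waves and a
#' mixture of single-, two- and multi-strain infections whose mixed fraction
#' declines over the waves (overall roughly 57% single / 18% two-strain /
#' 25% multi-strain infections).
#'
#' @param genome_length genome size in bp.
#' @param gc_content G+C fraction of the random reference.
#' @param n_years number of sampled years.
#' @param seasons_per_year growing seasons per year (max 2: EARLY, LATE).
#' @param waves_per_season epidemic waves per season (max 3: W1, W2, W3).
#' @param reservoir_size number of distinct strains in the soil reservoir.
#' @param n_lineages number of reservoir lineages; `NULL` means one lineage
#'   per year (annual cohorts are then genetically differentiated). Set to 1
#'   for a flat, star-shaped reservoir.
#' @param reservoir_mutation_rate substitutions per site separating lineage
#'   ancestors from the reference (flat reservoir: separating each strain
#'   from the reference, so expected pairwise strain divergence is ~2x rate).
#' @param within_lineage_rate substitutions per site separating strains from
#'   their lineage ancestor (ignored for a flat reservoir).
#' @param founder_count_per_wave integer vector of founding-particle counts
#'   per wave (the transmission bottleneck sizes).
#' @param hosts_per_wave isolates sampled per (year, season, wave).
#' @param carryover_fraction probability mass that a season's founding
#'   strains are drawn from *other* years' reservoir lineages (soil
#'   carryover between years); produces occasional cross-lineage
#'   co-infections and imperfect year assignment, as observed in real
#'   epidemics.
#' @param mixture_concentration Dirichlet concentration for within-host
#'   strain proportions.
#' @param multiplicity_probs probabilities of a host being founded by 1, 2,
#'   or >2 strain draws. Either a length-3 vector (all waves) or a
#'   waves x 3 matrix (one row per wave).
#' @param read_depth mean sequencing depth (Poisson).
#' @param background_fraction fraction of each host's reads contributed by
#'   the ambient wave strain pool (trace inoculum below consensus level);
#'   gives single-strain hosts their nonzero within-host diversity floor.
#' @param error_rate per-base sequencing error rate.
#' @param consensus_noise_rate per-site probability that a host's consensus
#'   call at a variant site is miscalled (flipped); models whole-genome
#'   amplification chimeras and assembly error, which affect consensus
#'   genomes but not read-level allele frequencies.
#' @param indel_rate per-site rate of strain-level small indel events
#'   (variant-table only; consensus sequences reflect substitutions only).
#' @param n_hr number of homologous-repeat regions planted in the reference.
#' @param hr_motif the 10-bp palindromic repeat unit.
#' @param start_year first calendar year label.
#' @param seed default seed used by [simulateCohort()].
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(genome_length = 112000L,
                      gc_content = 0.35,
                      n_years = 4L,
                      seasons_per_year = 2L,
                      waves_per_season = 3L,
                      reservoir_size = 80L,
                      n_lineages = NULL,
                      reservoir_mutation_rate = 0.0025,
                      within_lineage_rate = 1e-3,
                      founder_count_per_wave = c(20L, 5L, 2L),
                      hosts_per_wave = 6L,
                      carryover_fraction = 0.15,
                      mixture_concentration = 1,
                      multiplicity_probs = rbind(W1 = c(0.30, 0.25, 0.45),
                                                 W2 = c(0.55, 0.22, 0.23),
                                                 W3 = c(0.85, 0.08, 0.07)),
                      read_depth = 100,
                      background_fraction = 0.02,
                      error_rate = 0,
                      consensus_noise_rate = 0.01,
                      indel_rate = 0,
                      n_hr = 12L,
                      hr_motif = "TTTACGTAAA",
                      start_year = 2017L,
                      seed = NULL) {
    cfg <- list(genome_length = as.integer(genome_length),
                gc_content = gc_content, n_years = as.integer(n_years),
                seasons_per_year = as.integer(seasons_per_year),
                waves_per_season = as.integer(waves_per_season),
                reservoir_size = as.integer(reservoir_size),
                n_lineages = if (is.null(n_lineages)) as.integer(n_years)
                             else as.integer(n_lineages),
                reservoir_mutation_rate = reservoir_mutation_rate,
                within_lineage_rate = within_lineage_rate,
                founder_count_per_wave = as.integer(founder_count_per_wave),
                hosts_per_wave = as.integer(hosts_per_wave),
                carryover_fraction = carryover_fraction,
                mixture_concentration = mixture_concentration,
                multiplicity_probs = multiplicity_probs,
                read_depth = read_depth,
                background_fraction = background_fraction,
                error_rate = error_rate,
                consensus_noise_rate = consensus_noise_rate,
                indel_rate = indel_rate,
                n_hr = as.integer(n_hr), hr_motif = hr_motif,
                start_year = as.integer(start_year), seed = seed)
    stopifnot(cfg$genome_length >= 1L,
              cfg$gc_content >= 0, cfg$gc_content <= 1,
              cfg$n_years >= 1L, cfg$seasons_per_year >= 1L,
              cfg$seasons_per_year <= 2L,
              cfg$waves_per_season >= 1L, cfg$waves_per_season <= 3L,
              cfg$reservoir_size >= 1L, cfg$n_lineages >= 1L,
              all(cfg$founder_count_per_wave >= 1L),
              length(cfg$founder_count_per_wave) >= cfg$waves_per_season,
              cfg$hosts_per_wave >= 1L,
              cfg$carryover_fraction >= 0, cfg$carryover_fraction < 1,
              cfg$mixture_concentration > 0,
              cfg$read_depth > 0,
              cfg$background_fraction >= 0, cfg$background_fraction < 1,
              cfg$error_rate >= 0, cfg$error_rate < 0.5,
              cfg$consensus_noise_rate >= 0, cfg$consensus_noise_rate < 0.5)
    mp <- cfg$multiplicity_probs
    if (is.matrix(mp)) {
        if (ncol(mp) != 3L) stop("multiplicity_probs matrix must have 3 columns")
        if (any(abs(rowSums(mp) - 1) > 1e-9))
            stop("multiplicity_probs rows must sum to 1")
    } else {
        if (length(mp) != 3L || abs(sum(mp) - 1) > 1e-9)
            stop("multiplicity_probs must be 3 probabilities summing to 1")
    }
    class(cfg) <- "SimConfig"
    cfg
}

## sample() treats a length-1 numeric x as 1:x; this never does
.sampleFrom <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
}

.multProbs <- function(config, wave) {
    mp <- config$multiplicity_probs
    if (is.matrix(mp)) mp[min(wave, nrow(mp)), ] else mp
}

## random reference genome with planted hr regions
.randomReference <- function(config) {
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    chars <- sample(names(p), config$genome_length, replace = TRUE, prob = p)
    hr <- data.frame(start = integer(0), end = integer(0),
                     n_repeats = integer(0))
    motif <- strsplit(config$hr_motif, "")[[1L]]
    if (config$n_hr > 0L) {
        blockMax <- 8L * length(motif)
        if (config$genome_length > config$n_hr * (blockMax + 200L)) {
            span <- config$genome_length %/% config$n_hr
            for (i in seq_len(config$n_hr)) {
                copies <- sample(3:8, 1L)
                len <- copies * length(motif)
                at <- (i - 1L) * span + sample.int(span - len - 1L, 1L)  # 0-based
                chars[(at + 1L):(at + len)] <- rep(motif, copies)
                hr <- rbind(hr, data.frame(start = at, end = at + len,
                                           n_repeats = copies))
            }
        }
    }
    list(sequence = paste(chars, collapse = ""), hr = hr)
}

#' Build a reservoir of viral strains
#'
#' Generates a random reference genome and derives `reservoir_size` strain
#' haplotypes from it by placing substitutions. With more than one lineage
#' (the default: one per year) a lineage ancestor is first mutated away from
#' the reference at `reservoir_mutation_rate` and strains are then mutated
#' from their ancestor at `within_lineage_rate`; with `n_lineages = 1` every
#' strain derives directly from the reference at `reservoir_mutation_rate`.
#' A variant truth table records every polymorphic site and which strains
#' carry the alternative allele.
#'
#' @param config a [simConfig()].
#' @param seed optional integer seed.
#' @return A list of class `StrainPool` with elements `reference` (character
#'   genome), `positions` (0-based, sorted), `ref`/`alt` alleles, `carriage`
#'   (strains x sites logical matrix), `lineage` (strain lineage index),
#'   `hr` (planted repeat regions), `indels` (optional strain-level indel
#'   events) and `config`.
#' @export
buildReservoir <- function(config = simConfig(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    ref <- .randomReference(config)
    refChars <- strsplit(ref$sequence, "")[[1L]]
    L <- config$genome_length
    nS <- config$reservoir_size
    nL <- min(config$n_lineages, nS)
    lineage <- rep(seq_len(nL), length.out = nS)
    lineage <- sort(lineage)

    altOf <- new.env(parent = emptyenv())  # position -> fixed alt base
    drawAlt <- function(pos0) {
        key <- as.character(pos0)
        hit <- get0(key, envir = altOf)
        if (!is.null(hit)) return(hit)
        a <- sample(setdiff(c("A", "C", "G", "T"), refChars[pos0 + 1L]), 1L)
        assign(key, a, envir = altOf)
        a
    }
    mutate <- function(rate) {
        n <- rbinom(1L, L, rate)
        if (n == 0L) return(integer(0))
        sort(sample.int(L, n) - 1L)
    }

    ancRate <- if (nL > 1L) config$reservoir_mutation_rate else 0
    strainRate <- if (nL > 1L) config$within_lineage_rate
                  else config$reservoir_mutation_rate
    ancMuts <- lapply(seq_len(nL), function(i) mutate(ancRate))
    strainSites <- vector("list", nS)
    for (s in seq_len(nS)) {
        own <- mutate(strainRate)
        strainSites[[s]] <- sort(union(ancMuts[[lineage[s]]], own))
    }
    positions <- sort(unique(unlist(strainSites)))
    if (length(positions) == 0L)
        warning("mutation rate yields zero polymorphic sites; ",
                "downstream diversity statistics degenerate to zero")
    carriage <- matrix(FALSE, nS, length(positions))
    if (length(positions)) {
        idx <- setNames(seq_along(positions), as.character(positions))
        for (s in seq_len(nS))
            carriage[s, idx[as.character(strainSites[[s]])]] <- TRUE
    }
    alt <- vapply(positions, drawAlt, character(1))

    indels <- NULL
    if (config$indel_rate > 0) {
        nEv <- rbinom(1L, L, config$indel_rate)
        if (nEv > 0L) {
            at <- sort(sample.int(L - 10L, nEv) - 1L)
            at <- setdiff(at, positions)
            indels <- data.frame(
                position = at,
                length = sample(c(1:4, 6), length(at), replace = TRUE),
                insertion = sample(c(TRUE, FALSE), length(at), replace = TRUE))
            indels$carrier <- sample.int(nS, nrow(indels), replace = TRUE)
        }
    }

    structure(list(reference = ref$sequence, positions = positions,
                   ref = refChars[positions + 1L], alt = alt,
                   carriage = carriage, lineage = lineage, hr = ref$hr,
                   indels = indels, config = config),
              class = "StrainPool")
}

#' @export
print.StrainPool <- function(x, ...) {
    cat("StrainPool:", nrow(x$carriage), "strains,",
        length(x$positions), "polymorphic sites,",
        nchar(x$reference), "bp reference\n")
    invisible(x)
}

#' Strain haplotype sequences
#'
#' @param pool a `StrainPool`.
#' @param which integer indices of strains (default all).
#' @return A [Biostrings::DNAStringSet], one haplotype per strain.
#' @export
strainHaplotypes <- function(pool, which = seq_len(nrow(pool$carriage))) {
    refChars <- strsplit(pool$reference, "")[[1L]]
    seqs <- vapply(which, function(s) {
        x <- refChars
        hit <- pool$positions[pool$carriage[s, ]]
        x[hit + 1L] <- pool$alt[match(hit, pool$positions)]
        paste(x, collapse = "")
    }, character(1))
    DNAStringSet(setNames(seqs, paste0("strain", which)))
}

## Simulate read-level observation of one host.
## strains: integer indices into the pool; props: proportions summing to 1;
## poolFreq: ambient allele frequency of the wave strain pool per site.
.observeHost <- function(pool, strains, props, poolFreq, config) {
    nSite <- length(pool$positions)
    fHost <- if (nSite)
        as.numeric(props %*% pool$carriage[strains, , drop = FALSE])
        else numeric(0)
    bg <- config$background_fraction
    f <- (1 - bg) * fHost + bg * poolFreq
    e <- config$error_rate
    f <- f * (1 - e) + (1 - f) * e
    f <- pmin(pmax(f, 0), 1)  # guard against floating-point drift
    depth <- rpois(nSite, config$read_depth)
    altReads <- rbinom(nSite, depth, f)
    refReads <- depth - altReads
    gt <- ifelse(depth == 0L, NA_integer_,
                 ifelse(altReads > refReads, 1L, 0L))
    q <- config$consensus_noise_rate
    if (q > 0 && nSite) {
        flip <- runif(nSite) < q
        gt[flip & !is.na(gt)] <- 1L - gt[flip & !is.na(gt)]
    }
    list(genotype = gt, refDepth = refReads, altDepth = altReads)
}

#' Simulate read-level allele counts for a single constructed host
#'
#' Convenience wrapper used to build hosts with known strain content (e.g.
#' for validating the infection-pattern classifier).
#'
#' @param pool a `StrainPool`.
#' @param strains integer strain indices carried by the host.
#' @param proportions strain proportions (normalized internally).
#' @param depth mean read depth (overrides the pool config).
#' @param background_fraction,error_rate override the pool config (default 0).
#' @return data.frame with columns `position`, `p` (alt-read fraction),
#'   `depth`, plus attribute `genotype` (consensus calls).
#' @export
simulateHostProfile <- function(pool, strains, proportions = NULL,
                                depth = NULL,
                                background_fraction = 0, error_rate = 0) {
    cfg <- pool$config
    cfg$background_fraction <- background_fraction
    cfg$error_rate <- error_rate
    if (!is.null(depth)) cfg$read_depth <- depth
    if (is.null(proportions)) proportions <- rep(1, length(strains))
    proportions <- proportions / sum(proportions)
    obs <- .observeHost(pool, strains, proportions,
                        poolFreq = rep(0, length(pool$positions)), cfg)
    tot <- obs$refDepth + obs$altDepth
    out <- data.frame(position = pool$positions,
                      p = ifelse(tot > 0, obs$altDepth / tot, NA_real_),
                      depth = tot)
    attr(out, "genotype") <- obs$genotype
    out
}

## one (year, season): the three-wave transmission chain
.simulateSeasonCore <- function(pool, config, founderWeights, year, season,
                                idOffset) {
    nSite <- length(pool$positions)
    founder <- config$founder_count_per_wave
    hosts <- list(); meta <- list(); truth <- list()
    gt <- rd <- ad <- matrix(integer(0), nSite, 0L)
    counter <- idOffset

    # W1 founders: distinct strains drawn from the reservoir, weighted by
    # the year's founder weights (own lineage plus soil carryover)
    avail <- which(founderWeights > 0)
    f1 <- min(founder[1L], length(avail))
    if (founder[1L] > length(avail))
        warning("founder count ", founder[1L], " exceeds available strains (",
                length(avail), "); capped")
    waveStrains <- sort(.sampleFrom(seq_along(founderWeights), f1,
                                    prob = founderWeights))
    waveFreq <- rep(1 / f1, f1)

    for (w in seq_len(config$waves_per_season)) {
        poolFreq <- if (nSite)
            as.numeric(waveFreq %*% pool$carriage[waveStrains, , drop = FALSE])
            else numeric(0)
        realized <- setNames(numeric(length(waveStrains)),
                             as.character(waveStrains))
        mp <- .multProbs(config, w)
        for (h in seq_len(config$hosts_per_wave)) {
            counter <- counter + 1L
            cls <- sample.int(3L, 1L, prob = mp)
            k <- switch(cls, 1L, 2L,
                        sample(3:5, 1L, prob = c(0.5, 0.3, 0.2)))
            draws <- .sampleFrom(waveStrains, k, replace = TRUE, prob = waveFreq)
            strains <- sort(unique(draws))
            props <- rgamma(length(strains),
                            shape = config$mixture_concentration)
            if (all(props == 0)) props <- rep(1, length(strains))
            props <- props / sum(props)
            obs <- .observeHost(pool, strains, props, poolFreq, config)
            sid <- sprintf("S%04d", counter)
            gt <- cbind(gt, obs$genotype)
            rd <- cbind(rd, obs$refDepth)
            ad <- cbind(ad, obs$altDepth)
            hosts <- c(hosts, sid)
            meta[[sid]] <- data.frame(sample_id = sid, year = year,
                                      season = season, wave = paste0("W", w),
                                      stringsAsFactors = FALSE)
            truth[[sid]] <- list(sample_id = sid, year = year, season = season,
                                 wave = paste0("W", w), k_drawn = k,
                                 multiplicity = length(strains),
                                 strains = strains, proportions = props)
            realized[as.character(strains)] <-
                realized[as.character(strains)] + props
        }
        if (w < config$waves_per_season) {
            freq <- realized / sum(realized)
            particles <- .sampleFrom(waveStrains, founder[w + 1L], replace = TRUE,
                                prob = freq)
            tab <- table(particles)
            waveStrains <- as.integer(names(tab))
            waveFreq <- as.numeric(tab) / sum(tab)
        }
    }
    list(genotype = gt, refDepth = rd, altDepth = ad,
         sample_ids = unlist(hosts),
         meta = do.call(rbind, unname(meta)), truth = truth,
         counter = counter)
}

#' Simulate one growing season of a baculovirus epidemic
#'
#' Wave 1 hosts are founded by strains drawn from the supplied pool; each
#' subsequent wave is founded by a multinomial draw of
#' `founder_count_per_wave[w]` particles from the realized strain content of
#' the previous wave (founder effect + replication drift). Each host draws
#' `k` founding particles (`k` ~ `multiplicity_probs`) with replacement from
#' the wave pool; the distinct strains among them receive
#' Dirichlet(`mixture_concentration`) proportions. Per-site alternative-read
#' counts are binomial at Poisson(`read_depth`) coverage; the consensus call
#' is the majority allele.
#'
#' @param pool a `StrainPool` from [buildReservoir()].
#' @param config a [simConfig()]; defaults to the pool's.
#' @param year calendar year label.
#' @param season `"EARLY"` or `"LATE"`.
#' @param strains integer indices of the strains available to this season
#'   (default: all strains in the pool).
#' @param seed optional integer seed.
#' @return A list with elements `vm` ([VariantMatrix-class] including the
#'   metadata as colData), `meta` (data.frame), `truth` (per-host strain
#'   identities and proportions).
#' @export
simulateSeason <- function(pool, config = pool$config,
                           year = config$start_year, season = "EARLY",
                           strains = seq_len(nrow(pool$carriage)),
                           seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    w <- numeric(nrow(pool$carriage))
    w[strains] <- 1
    core <- .simulateSeasonCore(pool, config, w, year, season, 0L)
    vm <- .cohortVariantMatrix(pool, core)
    list(vm = vm, meta = core$meta, truth = core$truth)
}

.cohortVariantMatrix <- function(pool, core) {
    gt <- core$genotype
    if (is.null(gt)) gt <- matrix(NA_integer_, length(pool$positions), 0L)
    colnames(gt) <- core$sample_ids
    vm <- VariantMatrix(position = pool$positions, ref = pool$ref,
                        alt = pool$alt, genotype = gt,
                        refDepth = core$refDepth, altDepth = core$altDepth,
                        sampleIds = core$sample_ids)
    if (!is.null(core$meta)) {
        cd <- core$meta
        rownames(cd) <- cd$sample_id
        colData(vm) <- DataFrame(cd[colnames(vm), , drop = FALSE])
    }
    vm
}

#' Simulate a full multi-year epidemic cohort
#'
#' Runs [buildReservoir()] and then [simulateSeason()] for every
#' (year, season). Each year's founders are drawn from that year's reservoir
#' lineage, so annual cohorts are genetically differentiated; both seasons of
#' a year draw from the same lineage.
#'
#' @param config a [simConfig()].
#' @param seed integer seed driving all randomness (default `config$seed`).
#' @param sequences logical; also build per-isolate consensus genome
#'   sequences (needed by [emitCohort()], skippable for speed).
#' @return A list of class `SimCohort`: `vm` ([VariantMatrix-class] with
#'   metadata in colData), `meta`, `truth`, `pool`, and (optionally)
#'   `genomes` (a [Biostrings::DNAStringSet]).
#' @export
simulateCohort <- function(config = simConfig(), seed = config$seed,
                           sequences = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    pool <- buildReservoir(config)
    nL <- max(pool$lineage)
    seasons <- c("EARLY", "LATE")[seq_len(config$seasons_per_year)]
    allGt <- allRd <- allAd <- matrix(integer(0), length(pool$positions), 0L)
    ids <- character(0); metas <- list(); truth <- list()
    counter <- 0L
    for (y in seq_len(config$n_years)) {
        own <- pool$lineage == ((y - 1L) %% nL) + 1L
        cf <- if (any(!own)) config$carryover_fraction else 0
        w <- numeric(length(own))
        w[own] <- (1 - cf) / sum(own)
        if (any(!own)) w[!own] <- cf / sum(!own)
        for (se in seasons) {
            core <- .simulateSeasonCore(pool, config, w,
                                        config$start_year + y - 1L, se,
                                        counter)
            counter <- core$counter
            allGt <- cbind(allGt, core$genotype)
            allRd <- cbind(allRd, core$refDepth)
            allAd <- cbind(allAd, core$altDepth)
            ids <- c(ids, core$sample_ids)
            metas <- c(metas, list(core$meta))
            truth <- c(truth, core$truth)
        }
    }
    core <- list(genotype = allGt, refDepth = allRd, altDepth = allAd,
                 sample_ids = ids, meta = do.call(rbind, metas))
    vm <- .cohortVariantMatrix(pool, core)
    out <- list(vm = vm, meta = core$meta, truth = truth, pool = pool,
                seed = seed)
    if (sequences) out$genomes <- .consensusGenomes(pool, vm)
    class(out) <- "SimCohort"
    out
}

#' @export
print.SimCohort <- function(x, ...) {
    cat("SimCohort:", ncol(x$vm), "isolates,", nrow(x$vm),
        "variant sites over", nchar(x$pool$reference), "bp\n")
    invisible(x)
}

.consensusGenomes <- function(pool, vm) {
    refChars <- strsplit(pool$reference, "")[[1L]]
    gt <- genotypes(vm)
    seqs <- vapply(seq_len(ncol(gt)), function(j) {
        x <- refChars
        hit <- which(!is.na(gt[, j]) & gt[, j] >= 1L)
        x[pool$positions[hit] + 1L] <- pool$alt[hit]
        paste(x, collapse = "")
    }, character(1))
    DNAStringSet(setNames(seqs, colnames(gt)))
}

## minimal deterministic VCF writer (round-trip-tested through readVariants)
.writeVcf <- function(vm, path, contig = "genome", contigLength = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 if (!is.null(contigLength))
                     sprintf("##contig=<ID=%s,length=%d>", contig, contigLength)
                 else sprintf("##contig=<ID=%s>", contig),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", sampleIds(vm)), collapse = "\t")),
               con)
    gt <- genotypes(vm); rd <- refDepth(vm); ad <- altDepth(vm)
    pos <- variantPositions(vm)
    for (i in seq_len(nrow(vm))) {
        cells <- vapply(seq_len(ncol(vm)), function(j) {
            g <- gt[i, j]
            gs <- if (is.na(g)) "." else as.character(g)
            if (is.na(rd[i, j])) gs
            else paste0(gs, ":", rd[i, j], ",", ad[i, j])
        }, character(1))
        fmt <- if (all(is.na(rd[i, ]))) "GT" else "GT:AD"
        writeLines(paste(c(contig, internalToVcf(pos[i]), ".",
                           refAllele(vm)[i], altAllele(vm)[i], ".", "PASS",
                           ".", fmt, cells), collapse = "\t"), con)
    }
    invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the same file set the real-data path consumes: `consensus.fasta`,
#' `variants.vcf` (AD fields equal the simulated read counts exactly),
#' `metadata.csv` and `truth.json` (per-host strain identities, proportions
#' and the driving seed). Output is byte-stable for a fixed seed.
#'
#' @param cohort a `SimCohort` from [simulateCohort()] (with sequences).
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `outdir`, invisibly.
#' @export
emitCohort <- function(cohort, outdir, overwrite = FALSE) {
    if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
        stop("output directory exists and is not empty: ", outdir,
             " (use overwrite = TRUE)")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(cohort$genomes))
        stop("cohort was simulated without sequences; ",
             "rerun simulateCohort(sequences = TRUE)")
    writeConsensusSet(cohort$genomes, file.path(outdir, "consensus.fasta"))
    .writeVcf(cohort$vm, file.path(outdir, "variants.vcf"),
              contigLength = nchar(cohort$pool$reference))
    write.table(cohort$meta, file.path(outdir, "metadata.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    truth <- list(seed = cohort$seed,
                  n_samples = ncol(cohort$vm),
                  positions = cohort$pool$positions,
                  hosts = cohort$truth)
    writeResultsJson(truth, file.path(outdir, "truth.json"))
    invisible(outdir)
}

#' Synthetic ORF annotation for a simulated genome
#'
#' Tiles the genome with non-overlapping ORFs of baculovirus-typical length
#' (multiples of 3) separated by short intergenic gaps, assigning functional
#' groups round-robin. Purely synthetic: used to exercise per-gene statistics
#' (Watterson's theta, nonsynonymous density) on simulated cohorts.
#'
#' @param genome_length genome size in bp.
#' @param orf_length ORF length in bp (forced to a multiple of 3).
#' @param gap intergenic gap in bp.
#' @param seed optional seed (strand assignment is random).
#' @return data.frame in the format of [readOrfs()].
#' @export
syntheticOrfs <- function(genome_length, orf_length = 900L, gap = 60L,
                          seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    orf_length <- (as.integer(orf_length) %/% 3L) * 3L
    groups <- c("replication", "transcription", "per_os_infection",
                "virion_assembly_packaging", "auxiliary", "unknown")
    starts <- seq(gap, genome_length - orf_length - gap,
                  by = orf_length + gap)
    data.frame(name = sprintf("orf%03d", seq_along(starts)),
               start = as.integer(starts),
               end = as.integer(starts + orf_length),
               strand = sample(c("+", "-"), length(starts), replace = TRUE),
               functional_group = rep_len(groups, length(starts)),
               stringsAsFactors = FALSE)
}
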