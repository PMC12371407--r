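#' @importFrom Biostrings DNAString matchPattern GENETIC_CODE
NULL

.ORF_LENGTH_CHANGING <- c("translation_start_site_SNV", "termination_site_SNV",
                          "inframe_insertion", "inframe_deletion",
                          "frameshift_insertion", "frameshift_deletion",
                          "microsatellite_ins", "microsatellite_del",
                          "microsatellite_frameshift_ins",
                          "microsatellite_frameshift_del")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.effectRow <- function(position, orf, effect, unit = NA_integer_,
                       note = NA_character_) {
    data.frame(position = position, orf = orf, effect = effect,
               repeat_unit_length = unit, note = note,
               stringsAsFactors = FALSE)
}

.orfsAt <- function(orfs, position, width = 1L) {
    orfs[position + width > orfs$start & position < orfs$end, , drop = FALSE]
}

#' Classify a single-nucleotide variant by coding consequence
#'
#' The affected codon is recomputed on the coding strand. A change in the
#' ORF's first codon is a `translation_start_site_SNV` and a change in its
#' terminal (stop) codon a `termination_site_SNV`; these positional
#' categories take precedence over synonymous/nonsynonymous. Positions in
#' overlapping ORFs yield one call per ORF (baculovirus genomes are compact;
#' discarding either would lose per-gene counts). Positions outside every
#' ORF are `intergenic`.
#'
#' @param position 0-based genomic position.
#' @param ref_base,alt_base single reference/alternative bases.
#' @param orfs data.frame from [readOrfs()].
#' @param genome genome sequence (character or [Biostrings::DNAString]).
#' @return data.frame of effect calls (columns `position`, `orf`, `effect`,
#'   `repeat_unit_length`, `note`), one row per overlapping ORF.
#' @export
classifySnv <- function(position, ref_base, alt_base, orfs, genome) {
    genome <- as.character(genome)
    if (position < 0L || position >= nchar(genome))
        stop("position outside genome")
    have <- substr(genome, position + 1L, position + 1L)
    if (have != ref_base)
        stop("reference base mismatch at position ", position,
             ": genome has ", have, ", variant says ", ref_base)
    hits <- .orfsAt(orfs, position)
    if (nrow(hits) == 0L)
        return(.effectRow(position, NA_character_, "intergenic"))
    out <- lapply(seq_len(nrow(hits)), function(k) {
        o <- hits[k, ]
        if (o$strand == "+") {
            offset <- position - o$start
            refC <- ref_base; altC <- alt_base
        } else {
            offset <- (o$end - 1L) - position
            refC <- .complement[[ref_base]]; altC <- .complement[[alt_base]]
        }
        codonIdx <- offset %/% 3L
        inCodon <- offset %% 3L
        nCodon <- (o$end - o$start) %/% 3L
        cds <- as.character(orfSequence(genome, o))
        from <- codonIdx * 3L + 1L
        codon <- substr(cds, from, from + 2L)
        newCodon <- codon
        substr(newCodon, inCodon + 1L, inCodon + 1L) <- altC
        effect <- if (codonIdx == 0L) "translation_start_site_SNV"
            else if (codonIdx == nCodon - 1L &&
                     GENETIC_CODE[[codon]] == "*") "termination_site_SNV"
            else if (GENETIC_CODE[[codon]] == GENETIC_CODE[[newCodon]])
                "synonymous_SNV"
            else "nonsynonymous_SNV"
        .effectRow(position, o$name, effect)
    })
    do.call(rbind, out)
}

#' Classify a microsatellite indel
#'
#' Returns the repeat-unit length u in 1..4 iff the inserted/deleted
#' sequence is a whole number of copies of a unit of length u and the
#' reference around the event contains at least `min_copies` tandem copies
#' of that unit; the smallest qualifying u wins, `NULL` otherwise.
#' (Unit lengths 1/3/4 correspond to microsatellite Types I/III/IV; Type II
#' is supported for completeness.)
#'
#' @param position 0-based position of the VCF-style anchored alleles.
#' @param ref_allele,alt_allele VCF-style alleles (shared leading anchor).
#' @param genome genome sequence (character or [Biostrings::DNAString]).
#' @param min_copies minimum tandem copies in the reference context.
#' @return integer unit length or `NULL`.
#' @export
classifyMicrosatellite <- function(position, ref_allele, alt_allele, genome,
                                   min_copies = 3L) {
    genome <- as.character(genome)
    ev <- .indelEvent(position, ref_allele, alt_allele)
    if (is.null(ev) || !nzchar(ev$seq)) return(NULL)
    for (u in 1:4) {
        if (nchar(ev$seq) %% u != 0L) next
        unit <- substr(ev$seq, 1L, u)
        copies <- nchar(ev$seq) %/% u
        if (strrep(unit, copies) != ev$seq) next
        if (.tandemCopies(genome, ev$at, unit) >= min_copies) return(u)
    }
    NULL
}

## extract the inserted/deleted sequence and its 0-based genomic start from
## VCF-style anchored alleles; NULL for non-indel or complex substitutions
.indelEvent <- function(position, ref_allele, alt_allele) {
    nr <- nchar(ref_allele); na <- nchar(alt_allele)
    if (nr == na) return(NULL)
    # strip the longest common prefix
    k <- 0L
    while (k < min(nr, na) &&
           substr(ref_allele, k + 1L, k + 1L) ==
           substr(alt_allele, k + 1L, k + 1L)) k <- k + 1L
    if (nr > na) {
        list(type = "deletion", seq = substr(ref_allele, k + 1L, nr),
             at = position + k)
    } else {
        list(type = "insertion", seq = substr(alt_allele, k + 1L, na),
             at = position + k)
    }
}

## count tandem copies of `unit` in the reference overlapping position `at`
.tandemCopies <- function(genome, at, unit) {
    u <- nchar(unit)
    L <- nchar(genome)
    # find the phase-aligned run of `unit` copies covering or adjacent to at
    best <- 0L
    for (phase in 0:(u - 1L)) {
        s <- at - phase
        # extend left
        left <- s
        while (left - u >= 0L &&
               substr(genome, left - u + 1L, left) == unit) left <- left - u
        # extend right
        right <- s
        while (right + u <= L &&
               substr(genome, right + 1L, right + u) == unit) right <- right + u
        best <- max(best, (right - left) %/% u)
    }
    best
}

#' Classify an insertion/deletion by coding consequence
#'
#' Indels whose net length change is not a multiple of three are frameshift
#' variants, others inframe; microsatellite context (see
#' [classifyMicrosatellite()]) refines the category. Indels outside every
#' ORF are `intergenic`. Complex substitutions (both alleles longer than one
#' base and of unequal length) are classified by their net length change and
#' carry a `"complex"` note.
#'
#' @inheritParams classifyMicrosatellite
#' @param orfs data.frame from [readOrfs()].
#' @return data.frame of effect calls, one row per overlapping ORF.
#' @export
classifyIndel <- function(position, ref_allele, alt_allele, orfs, genome,
                          min_copies = 3L) {
    genome <- as.character(genome)
    nr <- nchar(ref_allele); na <- nchar(alt_allele)
    if (nr == na) stop("not an indel: alleles have equal length")
    diffLen <- na - nr
    complex <- nr > 1L && na > 1L
    note <- if (complex) "complex" else NA_character_
    hits <- .orfsAt(orfs, position, width = nr)
    if (nrow(hits) == 0L)
        return(.effectRow(position, NA_character_, "intergenic", note = note))
    frameshift <- abs(diffLen) %% 3L != 0L
    direction <- if (diffLen > 0L) "insertion" else "deletion"
    unit <- if (!complex)
        classifyMicrosatellite(position, ref_allele, alt_allele, genome,
                               min_copies) else NULL
    effect <- if (!is.null(unit)) {
        paste0(if (frameshift) "microsatellite_frameshift_" else
               "microsatellite_",
               if (direction == "insertion") "ins" else "del")
    } else {
        paste0(if (frameshift) "frameshift_" else "inframe_", direction)
    }
    out <- lapply(hits$name, function(nm)
        .effectRow(position, nm, effect,
                   unit = if (is.null(unit)) NA_integer_ else unit,
                   note = note))
    do.call(rbind, out)
}

#' Classify every variant of a cohort
#'
#' Runs [classifySnv()] / [classifyIndel()] over all sites and alternative
#' alleles of a [VariantMatrix-class].
#'
#' @param vm a [VariantMatrix-class].
#' @param orfs data.frame from [readOrfs()].
#' @param genome reference genome (character or [Biostrings::DNAString]).
#' @param min_copies microsatellite context threshold.
#' @return data.frame of effect calls with an extra `alt_index` column.
#' @export
classifyVariants <- function(vm, orfs, genome, min_copies = 3L) {
    genome <- as.character(genome)
    pos <- variantPositions(vm)
    out <- list()
    for (i in seq_len(nrow(vm))) {
        alts <- strsplit(altAllele(vm)[i], ",", fixed = TRUE)[[1L]]
        for (a in seq_along(alts)) {
            ref <- refAllele(vm)[i]
            calls <- if (nchar(ref) == 1L && nchar(alts[a]) == 1L)
                classifySnv(pos[i], ref, alts[a], orfs, genome)
            else
                classifyIndel(pos[i], ref, alts[a], orfs, genome, min_copies)
            calls$alt_index <- a
            out[[length(out) + 1L]] <- calls
        }
    }
    if (!length(out))
        return(.effectRow(integer(0), character(0), character(0))[0, ])
    do.call(rbind, out)
}

#' Scan a genome for homologous repeat (hr) regions
#'
#' Finds occurrences of the 10-bp palindromic repeat motif with up to
#' `max_mismatches` mismatches on the forward strand (the default motif is
#' its own reverse complement, so one strand suffices; a non-palindromic
#' motif triggers a warning). Hits within `cluster_window` bp of the
#' previous hit merge into one region; regions with fewer than `min_repeats`
#' hits are dropped.
#'
#' @param genome genome sequence (character or [Biostrings::DNAString]).
#' @param motif repeat unit (default the baculovirus hr palindrome).
#' @param max_mismatches allowed mismatches per hit.
#' @param cluster_window maximum gap (bp) between hits of one region.
#' @param min_repeats minimum hits per reported region.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `n_repeats`, and a list column `hit_positions` (0-based motif starts).
#' @export
scanHrs <- function(genome, motif = "TTTACGTAAA", max_mismatches = 1L,
                    cluster_window = 500L, min_repeats = 2L) {
    if (is.character(genome)) genome <- DNAString(genome)
    if (length(genome) == 0L) stop("empty genome")
    m <- DNAString(motif)
    if (as.character(reverseComplement(m)) != as.character(m))
        warning("motif is not its own reverse complement; ",
                "only the forward strand is scanned")
    hits <- sort(Biostrings::start(
        matchPattern(m, genome, max.mismatch = max_mismatches))) - 1L
    empty <- data.frame(start = integer(0), end = integer(0),
                        n_repeats = integer(0))
    empty$hit_positions <- list()
    if (!length(hits)) return(empty)
    grp <- cumsum(c(1L, as.integer(diff(hits) > cluster_window)))
    regions <- lapply(split(hits, grp), function(h) {
        data.frame(start = min(h), end = max(h) + nchar(motif),
                   n_repeats = length(h),
                   hit_positions = I(list(h)))
    })
    out <- do.call(rbind, regions)
    out <- out[out$n_repeats >= min_repeats, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Waterfall summary of ORF-length-changing variants
#'
#' Tabulates, per (ORF, isolate), the set of variant categories that change
#' ORF length (start/stop-codon SNVs, inframe and frameshift indels,
#' microsatellite indels), with marginal counts per ORF and per isolate.
#'
#' @param effects data.frame from [classifyVariants()].
#' @param vm the [VariantMatrix-class] the effects were computed from (used
#'   to resolve which isolates carry each variant).
#' @return list with `cells` (data.frame: `orf`, `sample_id`, `categories`,
#'   `n_variants`), `orf_counts` and `sample_counts` (named integer vectors
#'   of affected isolates per ORF and affected ORFs per isolate).
#' @export
orfLengthVariantSummary <- function(effects, vm) {
    lenChg <- effects[effects$effect %in% .ORF_LENGTH_CHANGING &
                      !is.na(effects$orf), , drop = FALSE]
    gt <- genotypes(vm)
    pos <- variantPositions(vm)
    rows <- list()
    for (i in seq_len(nrow(lenChg))) {
        e <- lenChg[i, ]
        site <- match(e$position, pos)
        if (is.na(site)) next
        carriers <- sampleIds(vm)[!is.na(gt[site, ]) & gt[site, ] == e$alt_index]
        for (s in carriers)
            rows[[length(rows) + 1L]] <-
                data.frame(orf = e$orf, sample_id = s, category = e$effect,
                           stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
        cells <- data.frame(orf = character(0), sample_id = character(0),
                            categories = character(0),
                            n_variants = integer(0))
        return(list(cells = cells, orf_counts = integer(0),
                    sample_counts = integer(0)))
    }
    long <- do.call(rbind, rows)
    key <- paste(long$orf, long$sample_id, sep = "\r")
    cells <- do.call(rbind, lapply(split(long, key), function(d)
        data.frame(orf = d$orf[1L], sample_id = d$sample_id[1L],
                   categories = paste(sort(unique(d$category)),
                                      collapse = ","),
                   n_variants = nrow(d), stringsAsFactors = FALSE)))
    rownames(cells) <- NULL
    list(cells = cells,
         orf_counts = c(table(cells$orf)),
         sample_counts = c(table(cells$sample_id)))
}
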