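#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement
#' @importFrom utils read.csv write.table read.delim
NULL

## -- coordinate convention -----------------------------------------------
## Internal coordinates are 0-based half-open; VCF and GFF3 are 1-based at
## the file boundary. Conversion happens in exactly one place per reader.

#' Convert between 1-based file coordinates and 0-based internal coordinates
#'
#' VCF and GFF3 use 1-based inclusive coordinates; all positions inside this
#' package are 0-based (half-open for intervals). The two helpers are exact
#' inverses.
#'
#' @param pos integer vector of positions.
#' @return integer vector of converted positions.
#' @examples
#' vcfToInternal(100L)  # 99
#' internalToVcf(99L)   # 100
#' @export
vcfToInternal <- function(pos) as.integer(pos) - 1L

#' @rdname vcfToInternal
#' @export
internalToVcf <- function(pos) as.integer(pos) + 1L

## -- consensus genomes ----------------------------------------------------

#' Read a set of consensus genomes from FASTA
#'
#' Reads per-isolate consensus genomes, uppercases lowercase bases, and
#' rejects any character outside \{A, C, G, T, N\}. The `circular` flag is
#' genome metadata only; no coordinate wrap-around is applied (reference
#' coordinates already linearize the circular genome).
#'
#' @param path FASTA file.
#' @param circular logical, stored on each record as metadata.
#' @return A [Biostrings::DNAStringSet] with unique names and an mcols column
#'   `circular`.
#' @export
readConsensusSet <- function(path, circular = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- readDNAStringSet(path)
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    if (anyDuplicated(names(seqs)))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
    seqs <- DNAStringSet(toupper(as.character(seqs)))
    freq <- Biostrings::alphabetFrequency(seqs)
    extra <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                          drop = FALSE])
    if (any(extra > 0)) {
        bad <- which(extra > 0)[1L]
        chars <- strsplit(as.character(seqs[[bad]]), "")[[1L]]
        at <- which(!chars %in% c("A", "C", "G", "T", "N"))[1L]
        stop("record '", names(seqs)[bad], "' contains disallowed character '",
             chars[at], "' at position ", at)
    }
    if (any(Biostrings::width(seqs) == 0L))
        stop("zero-length sequence in ", path)
    S4Vectors::mcols(seqs)$circular <- rep(isTRUE(circular), length(seqs))
    seqs
}

#' Write consensus genomes to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConsensusSet <- function(seqs, path) {
    writeXStringSet(seqs, path, width = 70L)
    invisible(path)
}

## -- VCF ------------------------------------------------------------------

## Pre-scan a plain-text VCF so malformed records can be reported with their
## line number, which readVcf() does not do.
.prescanVcf <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^#CHROM\t", lines)
    if (length(hdr) != 1L)
        stop("malformed VCF (no single #CHROM header line): ", path)
    nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
    body <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
    for (i in body) {
        if (!nzchar(lines[i])) next
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) != nfield)
            stop("malformed VCF record at line ", i, ": expected ", nfield,
                 " fields, found ", length(f))
        if (is.na(suppressWarnings(as.integer(f[2L]))))
            stop("malformed VCF record at line ", i, ": non-numeric POS '",
                 f[2L], "'")
    }
    invisible(TRUE)
}

## Collapse one GT string to a haploid allele index (NA = missing).
## Diploid calls are collapsed to the majority allele; heterozygous calls
## break the tie toward the allele with greater read depth (ref on equality).
.collapseGt <- function(gt, rd, ad) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(gt, "[/|]")[[1L]]
    parts <- parts[parts != "."]
    if (!length(parts)) return(NA_integer_)
    idx <- suppressWarnings(as.integer(parts))
    if (anyNA(idx)) return(NA_integer_)
    if (length(unique(idx)) == 1L) return(idx[1L])
    # heterozygous diploid record
    if (!is.na(rd) && !is.na(ad) && ad > rd) return(max(idx))
    min(idx)
}

#' Read a multi-sample VCF into a VariantMatrix
#'
#' Reads SNP and indel records with haploid or diploid `GT` and a per-sample
#' allelic depth field (`AD`). 1-based VCF positions are converted to 0-based
#' internal positions. Multiallelic records are preserved; site filtering is
#' a later stage ([filterBiallelicMaf()]). Diploid genotypes are collapsed to
#' a single haploid call with a warning (the virus is effectively clonal per
#' consensus).
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A [VariantMatrix-class]. When the VCF has no `AD` field, depth
#'   assays are `NA` and a warning is emitted.
#' @export
readVariants <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    .prescanVcf(path)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
    rr <- SummarizedExperiment::rowRanges(vcf)
    pos <- vcfToInternal(GenomicRanges::start(rr))
    ref <- as.character(rr$REF)
    alt <- vapply(rr$ALT, function(a) paste(as.character(a), collapse = ","),
                  character(1))
    gtRaw <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gtRaw)) stop("VCF has no GT field: ", path)
    nSite <- nrow(gtRaw); nSamp <- ncol(gtRaw)

    refD <- altD <- matrix(NA_integer_, nSite, nSamp)
    if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
        adRaw <- VariantAnnotation::geno(vcf)$AD
        for (i in seq_len(nSite)) for (j in seq_len(nSamp)) {
            v <- if (is.list(adRaw)) adRaw[[i, j]] else adRaw[i, j, ]
            v <- suppressWarnings(as.integer(v))
            if (length(v) >= 2L && !anyNA(v[1:2])) {
                refD[i, j] <- v[1L]
                altD[i, j] <- sum(v[-1L])
            }
        }
    } else {
        warning("VCF has no AD field; allele depths marked unknown: ", path)
    }

    gt <- matrix(NA_integer_, nSite, nSamp)
    diploidSeen <- FALSE
    for (i in seq_len(nSite)) for (j in seq_len(nSamp)) {
        g <- gtRaw[i, j]
        if (!is.na(g) && grepl("[/|]", g) && !g %in% c("./.", ".|."))
            diploidSeen <- TRUE
        gt[i, j] <- .collapseGt(g, refD[i, j], altD[i, j])
    }
    if (diploidSeen)
        warning("diploid genotypes collapsed to the majority allele")

    ord <- order(pos)
    vm <- VariantMatrix(position = pos[ord], ref = ref[ord], alt = alt[ord],
                        genotype = gt[ord, , drop = FALSE],
                        refDepth = refD[ord, , drop = FALSE],
                        altDepth = altD[ord, , drop = FALSE],
                        sampleIds = colnames(gtRaw))
    metadata(vm)$source <- path
    vm
}

## -- metadata -------------------------------------------------------------

#' Read isolate metadata (sample_id, year, season, wave)
#'
#' Seasons must be `EARLY`/`LATE` and waves `W1`/`W2`/`W3`; empty strings and
#' `NA` are allowed (structure-only runs), any other value is an error.
#'
#' @param path CSV file with columns `sample_id`, `year`, `season`, `wave`.
#' @return data.frame with `sample_id` (character), `year` (integer),
#'   `season` and `wave` (factors with the full level sets).
#' @export
readMetadata <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "year", "season", "wave")
    if (!all(need %in% colnames(df)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in metadata: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
    canon <- function(x, levels, what) {
        x <- as.character(x)
        x[!nzchar(x) | is.na(x)] <- NA
        bad <- !is.na(x) & !x %in% levels
        if (any(bad))
            stop("unknown ", what, " value(s): ",
                 paste(unique(x[bad]), collapse = ", "))
        factor(x, levels = levels)
    }
    data.frame(sample_id = as.character(df$sample_id),
               year = as.integer(df$year),
               season = canon(df$season, c("EARLY", "LATE"), "season"),
               wave = canon(df$wave, c("W1", "W2", "W3"), "wave"),
               stringsAsFactors = FALSE)
}

## -- ORF annotations ------------------------------------------------------

#' Read ORF annotations from GFF3
#'
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' The functional group is taken from a `functional_group` attribute when
#' present, else `"unknown"`; allowed groups follow the standard baculovirus
#' classification (replication, transcription, per_os_infection,
#' virion_assembly_packaging, auxiliary, unknown).
#'
#' @param path GFF3 file.
#' @return data.frame with columns `name`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`) and `functional_group`.
#' @export
readOrfs <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    name <- if ("Name" %in% colnames(mc)) as.character(mc$Name)
            else if ("ID" %in% colnames(mc)) as.character(mc$ID)
            else paste0("orf", seq_along(gr))
    grp <- if ("functional_group" %in% colnames(mc))
               as.character(mc$functional_group) else rep("unknown", length(gr))
    grp[is.na(grp)] <- "unknown"
    okGroups <- c("replication", "transcription", "per_os_infection",
                  "virion_assembly_packaging", "auxiliary", "unknown")
    if (any(!grp %in% okGroups))
        stop("unknown functional group(s): ",
             paste(unique(grp[!grp %in% okGroups]), collapse = ", "))
    orfs <- data.frame(name = name,
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       strand = as.character(GenomicRanges::strand(gr)),
                       functional_group = grp,
                       stringsAsFactors = FALSE)
    if (any(orfs$strand == "*"))
        stop("ORF(s) without strand: ",
             paste(orfs$name[orfs$strand == "*"], collapse = ", "))
    if (any(orfs$end <= orfs$start))
        stop("ORF(s) with end <= start")
    dup <- duplicated(orfs$name)
    if (any(dup))
        stop("duplicate ORF name(s): ", paste(unique(orfs$name[dup]),
                                              collapse = ", "))
    ntIn3 <- (orfs$end - orfs$start) %% 3L != 0L
    if (any(ntIn3))
        warning("ORF length not a multiple of 3: ",
                paste(orfs$name[ntIn3], collapse = ", "))
    orfs[order(orfs$start), , drop = FALSE]
}

#' Extract the coding sequence of one ORF from a genome
#'
#' Minus-strand ORFs return the reverse complement of the genomic slice, so
#' the result always reads 5'->3' on the coding strand.
#'
#' @param genome a [Biostrings::DNAString] or single character string.
#' @param orf one row of the data.frame returned by [readOrfs()].
#' @return A [Biostrings::DNAString].
#' @export
orfSequence <- function(genome, orf) {
    if (is.character(genome)) genome <- DNAString(genome)
    s <- Biostrings::subseq(genome, start = orf$start + 1L, end = orf$end)
    if (orf$strand == "-") s <- reverseComplement(s)
    s
}

## -- result tables --------------------------------------------------------

#' Write and re-read result tables
#'
#' TSV serialization keeping 15 significant digits so numeric round-trips are
#' exact to better than 1e-12 relative error; a JSON writer is provided for
#' nested results.
#'
#' @param df data.frame to serialize.
#' @param path output file.
#' @return `path` invisibly (`writeResultsTable`), or the re-read data.frame
#'   (`readResultsTable`).
#' @export
writeResultsTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writeResultsTable
#' @param x list to serialize as JSON.
#' @export
writeResultsJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

## -- cross-file validation ------------------------------------------------

#' Check cross-file consistency of a cohort
#'
#' Samples present in the metadata but absent from the genotype data are
#' tolerated with a warning; genotyped samples without metadata are an error
#' for trend analyses.
#'
#' @param vm a [VariantMatrix-class].
#' @param meta metadata data.frame from [readMetadata()].
#' @param genomes optional [Biostrings::DNAStringSet] of consensus genomes.
#' @return `TRUE` invisibly on success.
#' @export
validateCohort <- function(vm, meta, genomes = NULL) {
    vmIds <- sampleIds(vm)
    extraMeta <- setdiff(meta$sample_id, vmIds)
    if (length(extraMeta))
        warning("metadata samples absent from genotype data: ",
                paste(extraMeta, collapse = ", "))
    orphan <- setdiff(vmIds, meta$sample_id)
    if (length(orphan))
        stop("genotyped samples missing from metadata: ",
             paste(orphan, collapse = ", "))
    if (!is.null(genomes)) {
        noSeq <- setdiff(vmIds, names(genomes))
        if (length(noSeq))
            warning("genotyped samples without consensus genome: ",
                    paste(noSeq, collapse = ", "))
    }
    invisible(TRUE)
}
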