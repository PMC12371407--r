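# shared fixture builders; everything is generated in code at test time

# small VariantMatrix from a genotype matrix (sites x samples)
makeVm <- function(gt, position = seq_len(nrow(gt)) * 10L,
                   ref = rep("A", nrow(gt)), alt = rep("T", nrow(gt)),
                   refDepth = NULL, altDepth = NULL, class = NULL) {
    gt <- as.matrix(gt)
    if (is.null(colnames(gt))) colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
    VariantMatrix(position = position, ref = ref, alt = alt, genotype = gt,
                  refDepth = refDepth, altDepth = altDepth, class = class)
}

# random haploid genotype matrix with missingness, biallelic 0/1
randomGt <- function(nSite, nSamp, pAlt = 0.3, pMiss = 0.1) {
    gt <- matrix(rbinom(nSite * nSamp, 1L, pAlt), nSite, nSamp)
    gt[matrix(runif(nSite * nSamp) < pMiss, nSite, nSamp)] <- NA_integer_
    storage.mode(gt) <- "integer"
    gt
}

# phylogenetically structured pool: strains share lineage-ancestor alleles,
# so co-infections produce frequency levels at partial proportion sums
makeStructuredPool <- function(seed, n_strains = 12L, L = 20000L) {
    buildReservoir(simConfig(genome_length = L, reservoir_size = n_strains,
                             n_lineages = 4L,
                             reservoir_mutation_rate = 0.0025,
                             within_lineage_rate = 1.5e-3, n_hr = 0L),
                   seed = seed)
}

# flat (star-shaped) strain pool for read-level host construction
makeFlatPool <- function(seed, n_strains = 10L, L = 20000L, rate = 0.0025) {
    buildReservoir(simConfig(genome_length = L, reservoir_size = n_strains,
                             n_lineages = 1L, reservoir_mutation_rate = rate,
                             n_hr = 0L),
                   seed = seed)
}

# genome with one or more plus/minus-strand ORFs at known codons, for
# variant-effect tests; returns list(genome, orfs)
makeCodingFixture <- function() {
    # ORF1 (+): ATG AAA CCC TGG TAA  at [10, 25)
    # ORF2 (-): revcomp(ATG GCT AGA TAA) at [40, 52)
    orf1 <- "ATGAAACCCTGGTAA"
    orf2rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTAGATAA")))
    pad <- function(n) paste(rep("C", n), collapse = "")
    genome <- paste0(pad(10), orf1, pad(15), orf2rc, pad(20),
                     # microsatellite tracts used by indel tests:
                     "AAAAA", pad(5), "ACGACGACG", pad(10))
    orfs <- data.frame(name = c("orfP", "orfM"),
                       start = c(10L, 40L), end = c(25L, 52L),
                       strand = c("+", "-"),
                       functional_group = c("replication", "auxiliary"),
                       stringsAsFactors = FALSE)
    list(genome = genome, orfs = orfs)
}

# a minimal multi-sample VCF written as text; returns the path
writeTinyVcf <- function(path, withAd = TRUE) {
    fmt <- if (withAd) "GT:AD" else "GT"
    cell <- function(g, r, a) if (withAd) sprintf("%s:%d,%d", g, r, a) else g
    lines <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=genome,length=5000>",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if (withAd)
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", "sA", "sB", "sC", "sD"), collapse = "\t"),
        paste(c("genome", "100", ".", "A", "T", ".", "PASS", ".", fmt,
                cell("0", 30, 0), cell("1", 2, 28), cell(".", 0, 0),
                cell("0", 25, 1)), collapse = "\t"),
        paste(c("genome", "200", ".", "G", "C,A", ".", "PASS", ".", fmt,
                cell("2", 1, 29), cell("0", 30, 0), cell("1", 3, 27),
                cell("0", 28, 0)), collapse = "\t"),
        paste(c("genome", "300", ".", "CT", "C", ".", "PASS", ".", fmt,
                cell("1", 0, 30), cell("0", 29, 1), cell("0", 30, 0),
                cell("1", 1, 27)), collapse = "\t"))
    writeLines(lines, path)
    path
}

mkMeta <- function(years, seasons, waves, perStratum) {
    g <- expand.grid(year = years, season = seasons, wave = waves,
                     h = seq_len(perStratum), stringsAsFactors = FALSE)
    g$sample_id <- sprintf("s%04d", seq_len(nrow(g)))
    data.frame(sample_id = g$sample_id, year = g$year,
               season = factor(g$season, c("EARLY", "LATE")),
               wave = factor(g$wave, c("W1", "W2", "W3")))
}
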