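test_that("SNVs classify by codon consequence with positional precedence", {
    fx <- makeCodingFixture()
    g <- fx$genome; orfs <- fx$orfs
    # ORF1 spans [10,25): ATG AAA CCC TGG TAA
    # third position of AAA codon (offset 5 -> genome pos 15): A->G is Lys->Lys
    call <- classifySnv(15L, "A", "G", orfs, g)
    expect_identical(call$effect, "synonymous_SNV")
    expect_identical(call$orf, "orfP")
    # second position of AAA (pos 14): A->C is Lys->Thr
    expect_identical(classifySnv(14L, "A", "C", orfs, g)$effect,
                     "nonsynonymous_SNV")
    # first codon: ATG -> ATA
    expect_identical(classifySnv(12L, "G", "A", orfs, g)$effect,
                     "translation_start_site_SNV")
    # terminal stop codon TAA
    expect_identical(classifySnv(23L, "A", "C", orfs, g)$effect,
                     "termination_site_SNV")
    # outside every ORF
    expect_identical(classifySnv(2L, "C", "T", orfs, g)$effect, "intergenic")
    # reference-base mismatch is rejected
    expect_error(classifySnv(15L, "T", "G", orfs, g), "mismatch")
})

test_that("minus-strand classification equals plus-strand on the complement", {
    fx <- makeCodingFixture()
    g <- fx$genome; orfs <- fx$orfs
    # ORF2 (-) at [40,52) codes ATG GCT AGA TAA; genome carries its revcomp.
    # Mutate the wobble base of GCT (Ala): coding-strand T, genomic strand A
    # at genomic position 46 (offset 5 from the coding 3' view).
    pos <- 52L - 1L - 5L
    refBase <- substr(g, pos + 1L, pos + 1L)
    call <- classifySnv(pos, refBase, "G", orfs, g)  # coding T->C, Ala->Ala
    expect_identical(call$effect, "synonymous_SNV")
    expect_identical(call$orf, "orfM")

    # property: classifying the reverse-complemented genome with a
    # plus-strand copy of the ORF gives the same category
    L <- nchar(g)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    orfsRc <- data.frame(name = "orfM", start = L - 52L, end = L - 40L,
                         strand = "+", functional_group = "auxiliary")
    posRc <- L - 1L - pos
    callRc <- classifySnv(posRc, "T", "C", orfsRc, rc)
    expect_identical(callRc$effect, call$effect)
})

test_that("indels split into frameshift/inframe by length modulo three", {
    fx <- makeCodingFixture()
    g <- fx$genome; orfs <- fx$orfs
    at <- 13L
    ref4 <- substr(g, at + 1L, at + 4L)
    ref3 <- substr(g, at + 1L, at + 3L)
    a1 <- substr(g, at + 1L, at + 1L)
    # 3-bp deletion inside ORF1
    expect_identical(classifyIndel(at, ref4, a1, orfs, g)$effect,
                     "inframe_deletion")
    # 2-bp deletion inside ORF1 (TGG codon: no tandem repeat context)
    at2 <- 19L
    ref3b <- substr(g, at2 + 1L, at2 + 3L)
    a1b <- substr(g, at2 + 1L, at2 + 1L)
    expect_identical(classifyIndel(at2, ref3b, a1b, orfs, g)$effect,
                     "frameshift_deletion")
    # insertions mirror deletions
    expect_identical(classifyIndel(at, a1, paste0(a1, "TGA"), orfs, g)$effect,
                     "inframe_insertion")
    expect_identical(classifyIndel(at, a1, paste0(a1, "TG"), orfs, g)$effect,
                     "frameshift_insertion")
    # a 4-bp insertion in intergenic sequence stays intergenic
    ig <- 30L
    igBase <- substr(g, ig + 1L, ig + 1L)
    expect_identical(classifyIndel(ig, igBase, paste0(igBase, "ACGT"),
                                   orfs, g)$effect, "intergenic")
    # complex substitutions carry a note
    cpx <- classifyIndel(at, ref3, paste0(a1, "G"), orfs, g)
    expect_identical(cpx$note, "complex")
    expect_identical(cpx$effect, "frameshift_deletion")
    expect_error(classifyIndel(at, "AC", "GT", orfs, g), "equal length")
})

test_that("microsatellite units are detected from tandem reference context", {
    fx <- makeCodingFixture()
    g <- fx$genome
    # the fixture genome carries AAAAA at [72,77) and ACGACGACG at [82,91)
    aRun <- regexpr("AAAAA", g)[1] - 1L
    acg <- regexpr("ACGACGACG", g)[1] - 1L
    # deletion of one A inside the A-run: Type I (unit length 1)
    anchor <- substr(g, aRun + 1L, aRun + 1L)
    expect_identical(
        classifyMicrosatellite(aRun, paste0(anchor, "A"), anchor, g), 1L)
    # insertion of ACG adjacent to three tandem ACG copies: Type III
    pre <- substr(g, acg, acg)
    expect_identical(
        classifyMicrosatellite(acg - 1L, pre, paste0(pre, "ACG"), g), 3L)
    # deletion in non-repetitive context: no unit
    expect_null(classifyMicrosatellite(10L, "ATG", "A", g))

    # the categorical label combines unit with frameshift status
    orfRun <- data.frame(name = "ms", start = aRun - 3L, end = aRun + 12L,
                         strand = "+", functional_group = "unknown")
    expect_identical(
        classifyIndel(aRun, paste0(anchor, "A"), anchor, orfRun, g)$effect,
        "microsatellite_frameshift_del")
    orfAcg <- data.frame(name = "ms3", start = acg - 3L, end = acg + 12L,
                         strand = "+", functional_group = "unknown")
    expect_identical(
        classifyIndel(acg - 1L, pre, paste0(pre, "ACG"), orfAcg, g)$effect,
        "microsatellite_ins")
})

test_that("hr scanning finds clustered palindrome repeats", {
    motif <- "TTTACGTAAA"
    expect_identical(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif))), motif)

    # 1-kb motif-free sequence (constructed without A so no hit is possible)
    noHit <- paste(rep("CGGC", 250), collapse = "")
    expect_identical(nrow(scanHrs(noHit, max_mismatches = 0L)), 0L)

    # 2-kb sequence with exact motifs at offsets 100/220/340
    base <- strsplit(paste(rep("CG", 1000), collapse = ""), "")[[1]]
    for (at in c(100L, 220L, 340L))
        base[(at + 1L):(at + 10L)] <- strsplit(motif, "")[[1]]
    twoKb <- paste(base, collapse = "")
    hrs <- scanHrs(twoKb, max_mismatches = 0L)
    expect_identical(nrow(hrs), 1L)
    expect_identical(hrs$n_repeats, 3L)
    expect_identical(hrs$start, 100L)
    expect_identical(hrs$end, 350L)
    expect_identical(hrs$hit_positions[[1]], c(100L, 220L, 340L))

    # exact hits are a subset of 1-mismatch hits
    h0 <- scanHrs(twoKb, max_mismatches = 0L, min_repeats = 1L)
    h1 <- scanHrs(twoKb, max_mismatches = 1L, min_repeats = 1L)
    expect_true(all(unlist(h0$hit_positions) %in% unlist(h1$hit_positions)))

    # far-apart hits do not merge
    far <- base
    far[(1500L + 1L):(1500L + 10L)] <- strsplit(motif, "")[[1]]
    hrsFar <- scanHrs(paste(far, collapse = ""), max_mismatches = 0L,
                      cluster_window = 500L, min_repeats = 1L)
    expect_identical(nrow(hrsFar), 2L)

    expect_warning(scanHrs(twoKb, motif = "TTTTTTTTTT"), "reverse complement")
})

test_that("ORF-length variant summary tabulates cells and marginals", {
    fx <- makeCodingFixture()
    g <- fx$genome; orfs <- fx$orfs
    # no length-changing variants -> empty table
    gtSyn <- matrix(c(1L, 0L, 0L), 1)
    vmSyn <- makeVm(gtSyn, position = 15L, ref = "A", alt = "G")
    effSyn <- classifyVariants(vmSyn, orfs, g)
    empty <- orfLengthVariantSummary(effSyn, vmSyn)
    expect_identical(nrow(empty$cells), 0L)

    # one frameshift carried by one isolate: one cell, both marginals 1
    at <- 13L
    ref3 <- substr(g, at + 1L, at + 3L)
    a1 <- substr(g, at + 1L, at + 1L)
    gt <- matrix(c(1L, 0L, 0L), 1)
    vm <- makeVm(gt, position = at, ref = ref3, alt = a1)
    eff <- classifyVariants(vm, orfs, g)
    ws <- orfLengthVariantSummary(eff, vm)
    expect_identical(nrow(ws$cells), 1L)
    expect_identical(ws$cells$orf, "orfP")
    expect_identical(ws$cells$sample_id, "s01")
    expect_identical(unname(ws$orf_counts["orfP"]), 1L)
    expect_identical(unname(ws$sample_counts["s01"]), 1L)

    # marginals equal a brute-force recount of the cell matrix
    gt2 <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L))
    vm2 <- makeVm(gt2, position = c(13L, 44L),
                  ref = c(ref3, substr(g, 45L, 47L)),
                  alt = c(a1, substr(g, 45L, 45L)))
    eff2 <- classifyVariants(vm2, orfs, g)
    ws2 <- orfLengthVariantSummary(eff2, vm2)
    expect_identical(unname(c(ws2$orf_counts)),
                     unname(c(table(ws2$cells$orf))))
    expect_identical(unname(c(ws2$sample_counts)),
                     unname(c(table(ws2$cells$sample_id))))
})
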