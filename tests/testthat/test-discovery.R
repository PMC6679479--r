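test_that("a planted intron is recovered at exact coordinates", {
    set.seed(5)
    # 45-nt intron: donor(7) + interior(25) + BP/acceptor(13)
    intron <- paste0("GTAAGTC", randomDna(25), "GCTAACAAACTAG")
    pre <- randomDna(120)
    seq <- paste0(pre, intron, randomDna(135))
    cand <- scanGenomeForIntrons(c(g = seq))
    expect_length(cand, 1L)
    expect_equal(GenomicRanges::start(cand), nchar(pre) + 1L)
    expect_equal(GenomicRanges::end(cand), nchar(pre) + 45L)
    expect_equal(cand$five_ss, "GTAAGTC")
    expect_equal(cand$intron_seq, intron)
    # branch adenosine: 5th position of the fused motif
    expect_equal(substr(intron, cand$branch_a_offset, cand$branch_a_offset),
                 "A")
})

test_that("an anchor without an upstream donor yields no candidate", {
    set.seed(6)
    seq <- paste0(randomDna(150, gc = 1), "GCTAACAAACTAG", randomDna(50))
    expect_length(scanGenomeForIntrons(c(g = seq)), 0L)
})

test_that("configuration contract: bad length bounds are rejected", {
    expect_error(scanGenomeForIntrons(c(g = "ACGT"), minLen = 50L,
                                      maxLen = 40L), "exceeds")
    expect_error(scanGenomeForIntrons(c(g = "ACGT"), minLen = 10L), ">= 15")
})

test_that("displaced-acceptor mode finds a Rps15-like intron", {
    set.seed(7)
    # BP core not fused to the acceptor: 15 nt then CTAG
    intron <- paste0("GTAAGTC", randomDna(20), "GCTAACAAA",
                     randomDna(12), "CTAG")
    seq <- paste0(randomDna(100), intron, randomDna(100))
    plain <- scanGenomeForIntrons(c(g = seq))
    expect_length(plain, 0L)
    disp <- scanGenomeForIntrons(c(g = seq), displaced = TRUE)
    expect_true(length(disp) >= 1L)
    expect_true(any(disp$displaced_3ss &
                    GenomicRanges::start(disp) == 101L &
                    GenomicRanges::end(disp) == 100L + nchar(intron)))
})

test_that("translation follows the ciliate and standard codes", {
    expect_equal(translateSeq("TAATAGTGA", 0, "ciliate"), "QQ*")
    expect_equal(translateSeq("TAATAGTGA", 0, "standard"), "***")
    expect_equal(translateSeq("ATGGCA", 0, "ciliate"), "MA")
    # frame shift + trailing partial codon dropped
    expect_equal(translateSeq("ATGGCAC", 1, "ciliate"), "WH")
    expect_equal(translateSeq("ATGGCAC", 2, "ciliate"), "G")
})

test_that("ORF disruption detects in-frame stops and frameshifts", {
    # 45-nt intron containing TGA in frame 0 (intron offset 22, i.e. 1 mod 3)
    intron <- paste0("GTAAGTT", strrep("C", 14), "TGA", strrep("C", 8),
                     "GCTAACAAACTAG")
    gene <- paste0("ATGGCA", intron, "GCATGA")
    r <- assessOrfDisruption(gene, 7L, 6L + 45L, cdsFrame = 0L)
    expect_true(r$in_frame_stop)
    expect_false(r$frameshift)

    # 43-nt intron without an in-frame TGA: frameshift only
    intron43 <- paste0("GTAAGTT", strrep("C", 23), "GCTAACAAACTAG")
    gene <- paste0("ATGGCA", intron43, "GCATGA")
    r <- assessOrfDisruption(gene, 7L, 6L + 43L, cdsFrame = 0L)
    expect_false(r$in_frame_stop)
    expect_true(r$frameshift)

    expect_error(assessOrfDisruption("ACGTACGT", 5L, 20L), "outside")
})

test_that("every in-frame codon agrees with the codon-table oracle", {
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    for (cod in codons) {
        intron <- paste0("GTAAGTT", "CC", cod, "CCC", "GCTAACAAACTAG")
        gene <- paste0("ATG", intron, "TGA")
        # cdsFrame 0 at the boundary; codon planted at in-frame position 10
        r <- assessOrfDisruption(gene, 4L, 3L + nchar(intron), cdsFrame = 0L)
        inFrameCodons <- substring(intron,
                                   seq(1, nchar(intron) - 2, by = 3),
                                   seq(3, nchar(intron), by = 3))
        expect_equal(r$in_frame_stop, "TGA" %in% inFrameCodons,
                     info = cod)
    }
})

test_that("intron annotation reports extended donor, pyrimidine motif and phase", {
    a <- annotateIntron("GTAAGTCTAAACCCCCCCCGCTAACAAACTAG", bpMotifStart = 20)
    expect_true(a$extended_5ss)

    # pyrimidine motif ending at the BP motif start (shared purine)
    intron <- "GTAAGTTCCCCCCAACTTTGCTAACAAACTAG"
    a <- annotateIntron(intron, bpMotifStart = 20, cdsUpstream = 3L)
    expect_length(a$pyrimidine_hits, 1L)
    expect_equal(a$phase, 0L)
    expect_true(a$start_codon_intron)

    # no CDS context: phase unknown, motifs still computed
    a <- annotateIntron(intron, bpMotifStart = 20)
    expect_true(is.na(a$phase))
    expect_false(a$start_codon_intron)
    expect_length(a$pyrimidine_hits, 1L)
})

test_that("emitted candidates always match both consensus patterns", {
    set.seed(88)
    tr <- simulateGenome(nContigs = 1, contigLen = 12000, nGenes = 5,
                         nIntrons = 5, seed = 88)
    cand <- scanGenomeForIntrons(genomeSeqs(tr))
    p5 <- compilePattern("GTAAGTY")
    pa <- compilePattern("RCTAACAARHTAG")
    for (i in seq_along(cand)) {
        iseq <- cand$intron_seq[i]
        expect_equal(scanMotifBrute(substr(iseq, 1, 7), p5)$start, 1L)
        expect_equal(scanMotifBrute(substr(iseq, nchar(iseq) - 12,
                                           nchar(iseq)), pa)$start, 1L)
    }
})
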