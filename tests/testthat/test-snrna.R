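test_that("a designed U5-like locus is found as a full candidate", {
    set.seed(21)
    locus <- intronoscope:::buildU5Locus(37)
    g <- paste0(randomDna(400), locus, randomDna(400))
    res <- findU5Candidates(c(g = g))
    expect_gte(nrow(res), 1L)
    full <- res[res$full, , drop = FALSE]
    expect_gte(nrow(full), 1L)
    expect_true(any(full$start > 400 & full$end <= 400 + nchar(locus)))
    expect_equal(full$loop_mismatches[1], 0L)
    expect_gte(full$stem_pairs[1], 6L)
})

test_that("loop hits beyond the mismatch allowance are rejected", {
    # three substitutions in the loop consensus
    loop3 <- "TGGCTTTTGCA"     # TGCCTTTTACY with 3 changes
    g <- paste0(strrep("G", 50), "CCCCCC", loop3, "GGGGGG", strrep("C", 50))
    res <- findU5Candidates(c(g = g))
    expect_equal(nrow(res), 0L)
    expect_equal(u5LoopMismatches(loop3), 3L)
})

test_that("reported U5 candidates re-validate against standalone predicates", {
    set.seed(22)
    gs <- simulateU5Genomes(nGenomes = 3, genomeLen = 20000, seed = 22)
    for (g in gs) {
        res <- findU5Candidates(genomeSeqs(g))
        for (r in seq_len(nrow(res))) {
            row <- res[r, ]
            sq <- asPlus <- as.character(genomeSeqs(g)[[1]])
            if (row$strand == "-") {
                sq <- intronoscope::revComp(asPlus)
                s <- nchar(asPlus) - row$end + 1L
                e <- nchar(asPlus) - row$start + 1L
            } else { s <- row$start; e <- row$end }
            loop <- substr(sq, s, e)
            expect_lte(u5LoopMismatches(loop), 2L)
            expect_gte(closingStemPairs(substr(sq, s - 6L, s - 1L),
                                        substr(sq, e + 1L, e + 6L)), 6L)
            if (row$full) {
                sm <- smSiteHits(row$window_seq)
                expect_gte(nrow(sm), 1L)
                expect_gte(row$n_helix, 3L)
                expect_gte(row$n_internal, 2L)
            }
        }
    }
})

test_that("U5 recall is 1.0 on genomes with planted loci", {
    gs <- simulateU5Genomes(nGenomes = 4, genomeLen = 30000, seed = 23)
    rec <- vapply(gs, function(g) {
        res <- findU5Candidates(genomeSeqs(g))
        tru <- plantedSnrnas(g)
        full <- res[res$full, , drop = FALSE]
        nrow(full) > 0 &&
            any(full$strand == as.character(GenomicRanges::strand(tru)) &
                full$start >= GenomicRanges::start(tru) &
                full$end <= GenomicRanges::end(tru))
    }, logical(1))
    expect_true(all(rec))
})

test_that("U2 branch-point pairing bulges exactly the branch adenosine", {
    r <- checkU2Features("AAGUAGUAGG", bpRegion = "UACUAAC")
    expect_true(r$bp_interaction)
    expect_equal(r$bp_window, "GUAGUA")
    expect_true(r$bulge_unique)

    # no helix-I motifs
    r <- checkU2Features("AAAUUUAAAUUU")
    expect_equal(nrow(r$helix1_motifs), 0L)

    # poly-A candidate: all features absent
    r <- checkU2Features(strrep("A", 40))
    expect_false(r$bp_interaction)
    expect_equal(nrow(r$helix1_motifs), 0L)
    expect_equal(nrow(r$sm_site), 0L)
})

test_that("U2 helix-I and Sm motifs are located", {
    r <- checkU2Features("GCUAAGAUCAAAUUUUGGAAGUAGUA")
    expect_setequal(unique(r$helix1_motifs$motif), c("GCU", "GAUC"))
    expect_gte(nrow(r$sm_site), 1L)
})
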