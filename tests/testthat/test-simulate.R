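test_that("genome generation is byte-identical under a fixed seed", {
    t1 <- simulateGenome(nContigs = 2, contigLen = 8000, nGenes = 3,
                         nIntrons = 3, seed = 42)
    t2 <- simulateGenome(nContigs = 2, contigLen = 8000, nGenes = 3,
                         nIntrons = 3, seed = 42)
    expect_identical(as.character(genomeSeqs(t1)),
                     as.character(genomeSeqs(t2)))
    expect_identical(grKey(plantedIntrons(t1)), grKey(plantedIntrons(t2)))
    t3 <- simulateGenome(nContigs = 2, contigLen = 8000, nGenes = 3,
                         nIntrons = 3, seed = 43)
    expect_false(identical(as.character(genomeSeqs(t1)),
                           as.character(genomeSeqs(t3))))
})

test_that("planted introns satisfy the consuming modules' invariants", {
    tr <- simulateGenome(nContigs = 1, contigLen = 12000, nGenes = 5,
                         nIntrons = 5, seed = 44)
    introns <- plantedIntrons(tr)
    expect_length(introns, 5L)
    p5 <- compilePattern("GTAAGTY")
    pa <- compilePattern("RCTAACAARHTAG")
    lens <- nchar(introns$intron_seq)
    expect_true(all(lens >= 40 & lens <= 120))
    for (i in seq_along(introns)) {
        iseq <- introns$intron_seq[i]
        expect_equal(scanMotifBrute(substr(iseq, 1, 7), p5)$start, 1L)
        expect_equal(
            scanMotifBrute(substr(iseq, nchar(iseq) - 12, nchar(iseq)),
                           pa)$start, 1L)
        # guaranteed disruption: frameshift or in-frame TGA
        ph <- introns$phase[i]
        f <- (3L - ph) %% 3L
        codons <- substring(iseq, seq(1 + f, nchar(iseq) - 2, 3),
                            seq(3 + f, nchar(iseq), 3))
        expect_true(nchar(iseq) %% 3L != 0L || "TGA" %in% codons)
    }
    # features lie within their contigs (TruthSet validity)
    expect_true(validObject(tr))
})

test_that("structured introns fold to the requested spatial-distance band", {
    tr <- simulateGenome(nContigs = 1, contigLen = 12000, nGenes = 3,
                         nIntrons = 3, structuredFraction = 1,
                         structuredBand = c(35, 45), seed = 45)
    introns <- plantedIntrons(tr)
    expect_true(all(introns$structured))
    for (i in seq_along(introns)) {
        iseq <- introns$intron_seq[i]
        n <- nchar(iseq)
        mask <- c(1:7, (n - 12):n)
        st <- foldConstrained(iseq, unpaired = mask, nBest = 1L)[[1]]
        sd <- spatialDistance(st)$spatial_distance
        expect_gte(sd, 35)
        expect_lte(sd, 45)
    }
})

test_that("junction generator produces the labels it promises", {
    tr <- simulateGenome(nContigs = 1, contigLen = 20000, nGenes = 3,
                         nIntrons = 3, seed = 46)
    # perfect fidelity: every artifact is a 5/5 repeat
    sj <- simulateJunctions(tr, nReal = 0, nArtifact = 40,
                            repeatFidelity = 1, seed = 46)
    expect_true(all(sj$junctions$label_best == 5))

    # no artifacts: a seeded clean set has no perfect repeats
    sj0 <- simulateJunctions(tr, nReal = 3, nArtifact = 0, seed = 46)
    res <- filterJunctionCandidates(sj0$genome, sj0$junctions)
    expect_equal(res$summary$frac_perfect,
                 mean(sj0$junctions$label_best == 5))
    expect_equal(res$summary$n_artifact, sum(sj0$junctions$label_best == 5))

    # mixed fidelity: detector fractions equal realized label fractions
    sj2 <- simulateJunctions(tr, nReal = 40, nArtifact = 60,
                             repeatFidelity = 0.5, seed = 47)
    res2 <- filterJunctionCandidates(sj2$genome, sj2$junctions)
    expect_equal(res2$summary$frac_perfect,
                 mean(sj2$junctions$label_best == 5))
    expect_equal(res2$summary$frac_nearmiss,
                 mean(sj2$junctions$label_best == 4))
})

test_that("ortholog families honor the loss probability extremes", {
    fam0 <- simulateOrthologFamily(nSpecies = 6, indelRate = 0,
                                   lossProb = 0, seed = 48)
    expect_equal(nrow(fam0$sites), 6L * nrow(fam0$truth))
    r <- callHomologousIntrons(fam0$alignment, fam0$sites)
    expect_equal(length(unique(r$sites$group)), nrow(fam0$truth))

    fam1 <- simulateOrthologFamily(nSpecies = 6, lossProb = 1, seed = 49)
    expect_equal(nrow(fam1$sites), 0L)
})
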