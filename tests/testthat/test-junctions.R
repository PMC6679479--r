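test_that("planted direct repeats score as constructed", {
    set.seed(12)
    rep5 <- "ACGTC"
    g <- paste0(randomDna(50), rep5, randomDna(95), rep5, randomDna(50))
    # intron from 51 (repeat start) to 150; repeat recurs at 151
    ts <- templateSwitchScore(c(g = g), "g", donor = 51L, acceptor = 150L)
    expect_equal(ts$best_match, 5L)
    expect_equal(ts$best_offset, 0L)

    # one substitution, repeat planted at offset +3: best is 4/5
    # (donor flank all-A, acceptor flank all-G so nothing else matches)
    g2 <- paste0(strrep("A", 53), "ACGTC", strrep("A", 42),
                 strrep("G", 53), "ACTTC", strrep("G", 47))
    ts <- templateSwitchScore(c(g = g2), "g", donor = 51L, acceptor = 150L)
    expect_equal(ts$best_match, 4L)
})

test_that("detector equals the double-loop oracle on random junctions", {
    set.seed(13)
    g <- randomDna(4000)
    for (rep in 1:300) {
        donor <- sample(30:2000, 1)
        acceptor <- donor + sample(40:1500, 1)
        expect_equal(
            templateSwitchScore(c(g = g), "g", donor, acceptor)$best_match,
            templateSwitchScoreBrute(c(g = g), "g", donor, acceptor))
    }
})

test_that("score is symmetric under reverse-complementing genome and junction", {
    set.seed(14)
    for (rep in 1:50) {
        g <- randomDna(500)
        L <- nchar(g)
        donor <- sample(30:200, 1)
        acceptor <- donor + sample(40:200, 1)
        a <- templateSwitchScore(c(g = g), "g", donor, acceptor)$best_match
        b <- templateSwitchScore(c(g = revComp(g)), "g",
                                 L - acceptor + 1L, L - donor + 1L)$best_match
        expect_equal(a, b)
    }
})

test_that("triage flags follow the splice-signal criteria", {
    set.seed(15)
    intron <- paste0("GTATGT", randomDna(30), "ACTAAC", randomDna(4), "TAG")
    g <- paste0(randomDna(40), intron, randomDna(40))
    tr <- triageJunction(c(g = g), "g", 41L, 40L + nchar(intron))
    expect_true(tr$fivess_near)
    expect_true(tr$ctag_end)
    expect_true(tr$bp_near_3)

    # 5/6 match to GTGAGT
    intron2 <- paste0("GTGAGA", strrep("C", 30), "GGG")
    g2 <- paste0(strrep("A", 20), intron2, strrep("A", 20))
    tr <- triageJunction(c(g = g2), "g", 21L, 20L + nchar(intron2))
    expect_true(tr$fivess_near)
    expect_false(tr$ctag_end)     # ends GAG
    expect_false(tr$bp_near_3)

    # branch point present but not within the final 20 nt
    intron3 <- paste0("CCCCCC", "ACTAAC", strrep("G", 30))
    g3 <- paste0(strrep("A", 20), intron3, strrep("A", 20))
    tr <- triageJunction(c(g = g3), "g", 21L, 20L + nchar(intron3))
    expect_false(tr$bp_near_3)
})

test_that("partition is exhaustive, disjoint, and artifact takes precedence", {
    set.seed(16)
    tr <- simulateGenome(nContigs = 1, contigLen = 20000, nGenes = 4,
                         nIntrons = 4, seed = 16)
    sj <- simulateJunctions(tr, nReal = 30, nArtifact = 60,
                            repeatFidelity = 0.5, seed = 16)
    res <- filterJunctionCandidates(sj$genome, sj$junctions)
    tab <- res$table
    expect_equal(nrow(tab), 90L)
    expect_setequal(unique(tab$class), intersect(
        c("artifact", "rescued", "other"), unique(tab$class)))
    expect_equal(sum(tab$class == "artifact") + sum(tab$class == "rescued") +
                 sum(tab$class == "other"), nrow(tab))
    # artifact wins even when a splice signal is present
    both <- tab$ts_5of5 & (tab$fivess_near | tab$ctag_end | tab$bp_near_3)
    if (any(both)) expect_true(all(tab$class[both] == "artifact"))
    # summary fractions sum to at most 1
    expect_lte(res$summary$frac_perfect + res$summary$frac_nearmiss, 1)
    # fractions equal the independently derived labels
    expect_equal(res$summary$frac_perfect, mean(sj$junctions$label_best == 5))
    expect_equal(res$summary$frac_nearmiss,
                 mean(sj$junctions$label_best == 4))
})

test_that("an all-signals-false set yields no artifacts and no rescues", {
    g <- c(g = paste0(strrep("A", 30), strrep("C", 60), strrep("A", 30)))
    j <- data.frame(seq_id = "g", donor = 31L, acceptor = 90L)
    res <- filterJunctionCandidates(g, j)
    expect_equal(res$summary$n_rescued, 0L)
    expect_equal(res$table$class, "other")
})
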