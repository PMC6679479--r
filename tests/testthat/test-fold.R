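test_that("a unique GC hairpin folds as expected and constraints dominate", {
    s <- foldConstrained("GGGGAAAACCCC")
    expect_equal(dotBracket(s[[1]]), "((((....))))")
    expect_lt(structureEnergy(s[[1]]), 0)

    s <- foldConstrained("GGGGAAAACCCC", unpaired = 1:4)
    expect_equal(dotBracket(s[[1]]), "............")
    expect_equal(structureEnergy(s[[1]]), 0)

    # fully constrained sequence: single all-dot structure, energy 0
    s <- foldConstrained("GGGGAAAACCCC", unpaired = 1:12)
    expect_length(s, 1L)
    expect_equal(structureEnergy(s[[1]]), 0)
})

test_that("MFE equals the exhaustive-enumeration minimum on short RNAs", {
    set.seed(202)
    for (rep in 1:60) {
        n <- sample(10:18, 1)
        sq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
        unp <- if (rep %% 3 == 0) sample.int(n, 2) else integer(0)
        eng <- foldConstrained(sq, unpaired = unp, nBest = 1L)[[1]]
        expect_equal(structureEnergy(eng), foldExhaustive(sq, unp)$mfe,
                     tolerance = 1e-9)
        if (length(unp))
            expect_false(any(unp %in% as.vector(basePairs(eng))))
    }
})

test_that("constrained positions stay unpaired in every returned structure", {
    set.seed(9)
    for (rep in 1:10) {
        sq <- randomDna(60, gc = 0.6)
        unp <- sample.int(60, 8)
        structs <- foldConstrained(sq, unpaired = unp, nBest = 3L, band = 3)
        for (st in structs)
            expect_false(any(unp %in% as.vector(basePairs(st))))
    }
})

test_that("suboptimal structures are distinct, energy-sorted and self-consistent", {
    structs <- foldConstrained("GGGACGUCCCAAAGGGACGUCCC", nBest = 3L,
                               band = 5)
    dbs <- vapply(structs, dotBracket, character(1))
    expect_equal(anyDuplicated(dbs), 0L)
    en <- vapply(structs, structureEnergy, numeric(1))
    expect_true(!is.unsorted(en))
    # reported energies match independent loop-decomposition scoring
    for (st in structs)
        expect_equal(structureEnergy(st),
                     scoreStructure(st@seq, basePairs(st)), tolerance = 1e-9)
})

test_that("spatial distance excludes exactly the outer-pair spans", {
    expect_equal(spatialDistance(strrep(".", 63))$spatial_distance, 63L)

    # 63-nt intron with one 22-nt hairpin element -> 41 nt
    db <- paste0(strrep(".", 20), "((((((((......))))))))", strrep(".", 21))
    r <- spatialDistance(db)
    expect_equal(r$intron_length, 63L)
    expect_equal(r$spatial_distance, 41L)
    expect_equal(nrow(r$hairpins), 1L)
})

test_that("collapsing any hairpin recovers exactly its span", {
    set.seed(303)
    for (rep in 1:200) {
        nh <- sample(1:4, 1)
        spans <- sample(9:25, nh, replace = TRUE)
        gaps <- sample(0:10, nh + 1, replace = TRUE)
        db <- strrep(".", gaps[1])
        for (h in seq_len(nh)) {
            stem <- (spans[h] - 5) %/% 2
            loop <- spans[h] - 2 * stem
            db <- paste0(db, strrep("(", stem), strrep(".", loop),
                         strrep(")", stem), strrep(".", gaps[h + 1]))
        }
        full <- spatialDistance(db)
        hp <- full$hairpins
        expect_equal(nrow(hp), nh)
        expect_equal(full$spatial_distance,
                     nchar(db) - sum(hp[, 2] - hp[, 1] + 1L))
        # removing one hairpin increases the distance by exactly its span
        for (h in seq_len(nh)) {
            ch <- strsplit(db, "")[[1]]
            ch[hp[h, 1]:hp[h, 2]] <- "."
            expect_equal(spatialDistance(paste(ch, collapse = ""))$spatial_distance,
                         unname(full$spatial_distance + hp[h, 2] - hp[h, 1] + 1L))
        }
    }
})

test_that("raising temperature destabilizes helices monotonically", {
    # GC helix energy increases with temperature (entropic penalty)
    e21 <- structureEnergy(foldConstrained("GGGGAAAACCCC",
                                           temperature = 21)[[1]])
    e37 <- structureEnergy(foldConstrained("GGGGAAAACCCC",
                                           temperature = 37)[[1]])
    expect_lt(e21, e37)
    # a helix unstable at low temperature never becomes the MFE winner at
    # high temperature: the all-dot structure stays optimal
    weak <- "AUAAAAUA"   # at most 2 AU pairs, below stability
    for (tt in c(10, 37, 70)) {
        st <- foldConstrained(weak, temperature = tt, nBest = 1L)[[1]]
        expect_equal(structureEnergy(st), 0)
    }
})
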