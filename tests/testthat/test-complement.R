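test_that("domain filter retains complete candidates and tolerates one miss", {
    expect_true(domainFilter(c("A", "B"), c("A", "B"))$retain)

    r <- domainFilter("A", c("A", "B"), allowMissing = 0L)
    expect_false(r$retain)
    expect_equal(r$missing, "B")

    r <- domainFilter(c("A", "B"), c("A", "B", "C"), allowMissing = 1L)
    expect_true(r$retain)
    expect_true(r$flagged)
    expect_equal(r$missing, "C")

    # extra domains never hurt
    expect_true(domainFilter(c("A", "B", "Z"), c("A", "B"))$retain)
})

test_that("reciprocal rule: top-10 identity and the size branches", {
    hits <- function(rank) data.frame(
        subject = c(paste0("x", seq_len(rank - 1L)), "q"))

    expect_true(reciprocalCheck(hits(3), "q", 250, 295))
    expect_false(reciprocalCheck(hits(11), "q", 250, 250))
    expect_false(reciprocalCheck(hits(1)[0, , drop = FALSE], "q", 250, 250))

    # under-300 branch: +/- 50 aa inclusive
    expect_true(reciprocalCheck(hits(1), "q", 299, 349))
    expect_false(reciprocalCheck(hits(1), "q", 299, 350))
    # >= 300 branch: +/- 20 percent inclusive
    expect_true(reciprocalCheck(hits(1), "q", 300, 360))
    expect_false(reciprocalCheck(hits(1), "q", 300, 361))
    expect_false(reciprocalCheck(hits(1), "q", 400, 485))
    expect_true(reciprocalCheck(hits(1), "q", 400, 479))
    expect_true(reciprocalCheck(hits(1), "q", 400, 480))
    # alias map stands in for accession identity
    expect_true(reciprocalCheck(data.frame(subject = "syn1"), "q", 100, 100,
                                aliases = "syn1"))
})

test_that("nestedness extremes: containment 1 for subsets, 0 for disjoint", {
    m <- matrix(FALSE, 6, 2, dimnames = list(paste0("p", 1:6), c("A", "B")))
    m[1:3, "A"] <- TRUE
    m[1:5, "B"] <- TRUE
    r <- retentionAnalysis(m)
    expect_equal(r$containment$fraction[r$containment$from == "A" &
                                        r$containment$to == "B"], 1.0)

    m2 <- matrix(FALSE, 6, 2, dimnames = list(paste0("p", 1:6), c("A", "B")))
    m2[1:3, "A"] <- TRUE
    m2[4:6, "B"] <- TRUE
    r2 <- retentionAnalysis(
        m2, groupings = list(v = list(list(name = "A", organisms = "A"),
                                      list(name = "B", organisms = "B"))))
    expect_equal(r2$containment$fraction, c(0, 0))
    v <- r2$venn$v
    expect_equal(v$count[v$pattern == "11"], 0L)
})

test_that("Venn partitions match the set-algebra oracle on random matrices", {
    set.seed(41)
    orgs <- paste0("org", 1:6)
    for (rep in 1:15) {
        m <- matrix(runif(174 * 6) < runif(1, 0.2, 0.7), 174, 6,
                    dimnames = list(paste0("p", 1:174), orgs))
        pick <- sample(orgs, 3)
        r <- retentionAnalysis(m, groupings = list(
            g = lapply(pick, function(o) list(name = o, organisms = o))))
        v <- r$venn$g
        sets <- lapply(pick, function(o) rownames(m)[m[, o]])
        oracle <- vennOracle(sets)
        for (pat in v$pattern)
            expect_equal(v$count[v$pattern == pat], oracle[[pat]],
                         info = pat)
        expect_equal(sum(v$count), length(Reduce(union, sets)))
        expect_true(all(v$count >= 0))
    }
})

test_that("LSm/Sm proteins are counted as deduplicated families", {
    m <- matrix(FALSE, 5, 2, dimnames = list(
        c("lsm1a", "lsm1b", "lsm2", "smB", "prp8"), c("A", "B")))
    m[c("lsm1a", "lsm1b", "lsm2", "prp8"), "A"] <- TRUE
    m[c("lsm1a", "smB"), "B"] <- TRUE
    fam <- c(lsm1a = "LSm1", lsm1b = "LSm1", lsm2 = "LSm2", smB = "SmB")
    r <- retentionAnalysis(m, lsmFamily = fam)
    expect_equal(r$totals$n_lsm_families[r$totals$organism == "A"], 2L)
    expect_equal(r$totals$n_lsm_families[r$totals$organism == "B"], 2L)
})

test_that("census rules are pure: shuffling non-rank fields changes nothing", {
    df <- data.frame(subject = c("a", "b", "q"), evalue = c(1, 2, 3))
    expect_identical(reciprocalCheck(df, "q", 200, 200),
                     reciprocalCheck(df[, rev(names(df))], "q", 200, 200))
})
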