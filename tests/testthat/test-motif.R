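test_that("pattern compilation expands classes and bounded repeats", {
    p <- compilePattern("RCTAACAARHTAG")
    expect_equal(patternWidths(p), 13L)

    expect_equal(compilePattern("N")@expansions, "N")

    # AAC[T/C]{3,4}R: 3 or 4 pyrimidines between the fixed flanks
    p <- compilePattern("AAC[T/C]{3,4}R")
    expect_setequal(p@expansions, c("AACYYYR", "AACYYYYR"))
    expect_setequal(patternWidths(p), c(7L, 8L))

    p <- compilePattern("RAT{4,6}GR")
    expect_setequal(patternWidths(p), c(8L, 9L, 10L))

    expect_error(compilePattern("ACGX"), "X")
    expect_error(compilePattern("A{2,1}"), "repeat")
})

test_that("scanning finds consensus instances with exact coordinates", {
    h <- scanMotif("GCTAACAAACTAG", compilePattern("RCTAACAARHTAG"))
    expect_length(h, 1L)
    expect_equal(GenomicRanges::start(h), 1L)
    expect_equal(h$mismatches, 0L)

    h <- scanMotif("GTAAGTC", compilePattern("GTAAGTY"))
    expect_equal(h$matched, "GTAAGTC")

    # 'N' in the subject never satisfies a non-N pattern symbol
    expect_length(scanMotif("GTANGTC", compilePattern("GTAAGTY")), 0L)
    expect_length(scanMotif("NNNN", compilePattern("N"), strands = "+"), 4L)
})

test_that("scan agrees with the brute-force oracle on random sequences", {
    set.seed(101)
    pats <- pipelinePatterns(maxMismatches = 2L)
    for (rep in 1:150) {
        s <- randomDna(200)
        for (p in pats) {
            got <- scanMotif(s, p, strands = "+")
            want <- scanMotifBrute(s, p)
            expect_equal(GenomicRanges::start(got), want$start)
            expect_equal(GenomicRanges::end(got), want$end)
            expect_equal(got$mismatches, want$mismatches)
            # 0- and 1-mismatch scans are the corresponding subsets
            for (k in 0:1) {
                pk <- compilePattern(p@pattern, k)
                gk <- scanMotif(s, pk, strands = "+")
                expect_equal(grKey(gk), grKey(got[got$mismatches <= k]))
            }
        }
    }
})

test_that("minus-strand scanning equals scanning the reverse complement", {
    set.seed(55)
    p <- compilePattern("GTAAGTY", 1L)
    for (rep in 1:25) {
        s <- randomDna(300)
        L <- nchar(s)
        minus <- scanMotif(s, p, strands = "-")
        plus_rc <- scanMotif(revComp(s), p, strands = "+")
        expect_equal(sort(L - GenomicRanges::end(minus) + 1L),
                     sort(GenomicRanges::start(plus_rc)))
        expect_equal(sort(minus$mismatches), sort(plus_rc$mismatches))
    }
})

test_that("overlapping hits are all reported and output is sorted", {
    h <- scanMotif("AAAAAA", compilePattern("AAA"))
    expect_length(h, 4L)
    expect_true(!is.unsorted(GenomicRanges::start(h)))
})
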