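test_that("identical intron positions group together; adjacent codons flag sliding", {
    aln <- c(sp1 = "MKLV", sp2 = "MKLV")
    sites <- data.frame(species = c("sp1", "sp2"),
                        cds_upstream = c(3L, 3L))
    r <- callHomologousIntrons(aln, sites)
    expect_equal(length(unique(r$sites$group)), 1L)
    expect_equal(r$groups$n_species, 2L)
    expect_false(any(r$groups$possible_sliding))

    # one intron one codon downstream: two groups, sliding flagged
    sites2 <- data.frame(species = c("sp1", "sp2"),
                         cds_upstream = c(3L, 6L))
    r <- callHomologousIntrons(aln, sites2)
    expect_equal(length(unique(r$sites$group)), 2L)
    expect_true(all(r$groups$possible_sliding))

    # same column but different phase never groups
    sites3 <- data.frame(species = c("sp1", "sp2"),
                         cds_upstream = c(3L, 4L))
    r <- callHomologousIntrons(aln, sites3)
    expect_equal(length(unique(r$sites$group)), 2L)
})

test_that("sites beyond the CDS raise an error naming the species", {
    aln <- c(spA = "MKLV", spB = "MKLV")
    sites <- data.frame(species = "spB", cds_upstream = 15L)
    expect_error(callHomologousIntrons(aln, sites), "spB")
})

test_that("column mapping matches the cumulative non-gap oracle with indels", {
    set.seed(31)
    for (rep in 1:30) {
        fam <- simulateOrthologFamily(nSpecies = 10, cdsLenAa = 120,
                                      subRate = 0.05, indelRate = 0.04,
                                      lossProb = 0.3, seed = 31 + rep)
        if (!nrow(fam$sites)) next
        r <- callHomologousIntrons(fam$alignment, fam$sites)
        for (k in seq_len(nrow(r$sites))) {
            sp <- r$sites$species[k]
            expect_equal(r$sites$aln_column[k],
                         columnOracle(fam$alignment[[sp]],
                                      r$sites$codon_index[k]))
        }
        # recovered groups equal the planted truth
        tg <- fam$sites$truth_group
        expect_true(all(tapply(r$sites$group, tg,
                               function(x) length(unique(x)) == 1L)))
        expect_equal(length(unique(r$sites$group)), length(unique(tg)))
    }
})

test_that("grouping is invariant to species input order", {
    fam <- simulateOrthologFamily(nSpecies = 8, indelRate = 0.03,
                                  lossProb = 0.1, seed = 77)
    r1 <- callHomologousIntrons(fam$alignment, fam$sites)
    perm <- sample(nrow(fam$sites))
    r2 <- callHomologousIntrons(fam$alignment, fam$sites[perm, ])
    k1 <- paste(r1$sites$aln_column, r1$sites$phase)
    k2 <- paste(r2$sites$aln_column, r2$sites$phase)[order(perm)]
    expect_equal(k1, k2)
    expect_equal(r1$groups[c("aln_column", "phase", "n_species")],
                 r2$groups[c("aln_column", "phase", "n_species")])
})

test_that("proto-splice-site matches count the (A/C)AG|G consensus", {
    expect_equal(protoSpliceCheck("CAG", "G")$matches, 4L)
    expect_equal(protoSpliceCheck("ATG", "G")$matches, 3L)
    expect_equal(protoSpliceCheck("TTT", "T")$matches, 0L)
    expect_equal(protoSpliceCheck("AAG", "G")$matches, 4L)  # M is A or C
    r <- protoSpliceCheck("AG", "G")
    expect_true(r$truncated)
    expect_equal(r$n_scored, 3L)
})

test_that("clade summaries tally numerators over denominators", {
    cl <- c(s1 = "X", s2 = "X", s3 = "X", s4 = "Y")
    r <- cladePresenceSummary(c("s1", "s2"), cl)
    expect_equal(r$n_with_intron[r$clade == "X"], 2L)
    expect_equal(r$n_sampled[r$clade == "X"], 3L)

    # gene-not-found species leave the denominator only
    r <- cladePresenceSummary(c("s1"), cl, geneNotFound = "s3")
    expect_equal(r$n_sampled[r$clade == "X"], 2L)

    expect_error(cladePresenceSummary("zz", cl), "zz")

    # numerators sum to the homology-group size over random assignments
    set.seed(32)
    for (rep in 1:20) {
        sp <- paste0("s", 1:12)
        clades <- setNames(sample(LETTERS[1:4], 12, TRUE), sp)
        withIntron <- sample(sp, sample(0:12, 1))
        r <- cladePresenceSummary(withIntron, clades)
        expect_equal(sum(r$n_with_intron), length(withIntron))
        expect_equal(sum(r$n_sampled), 12L)
    }
})
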