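#' Template-switch direct-repeat score of a spliced junction
#'
#' Reverse-transcriptase template switching during cDNA synthesis creates
#' apparent splice junctions between loci sharing a short direct repeat. The
#' score compares a k-mer anchored at the intron's first nucleotide (the
#' donor) with the k-mer anchored at the first exonic nucleotide after the
#' intron, at the same offset applied to both boundaries ("in-frame"), and
#' reports the best identity count over offsets in \code{[-window, window]}.
#' A perfect repeat therefore scores \code{k}. Both boundary-pair geometries
#' of the direct-repeat model are evaluated (repeat shared by intron start
#' and downstream exon, or by upstream exon and intron end) and the maximum
#' is reported, which makes the score strand-symmetric.
#'
#' The source data do not state whether the comparison windows include the
#' junction base itself; the default anchoring (\code{anchor = "boundary"})
#' starts the windows at the boundary bases (donor and acceptor+1), the
#' alternative (\code{anchor = "adjacent"}) one base 3' of each.
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param seqId contig of the junction.
#' @param donor 1-based position of the first intronic nucleotide.
#' @param acceptor 1-based position of the last intronic nucleotide.
#' @param k repeat length compared (default 5).
#' @param window offset half-width (default 5).
#' @param anchor \code{"boundary"} or \code{"adjacent"}.
#' @return list \code{best_match} (integer in \code{[0, k]}),
#'   \code{best_offset}, \code{truncated_flank} (\code{TRUE} when some
#'   offsets fell outside the contig and were skipped).
#' @export
templateSwitchScore <- function(genome, seqId, donor, acceptor,
                                k = 5L, window = 5L,
                                anchor = c("boundary", "adjacent")) {
    anchor <- match.arg(anchor)
    seqs <- asSeqVector(genome)
    if (!seqId %in% names(seqs)) stop("unknown contig: ", seqId)
    s <- seqs[[seqId]]
    L <- nchar(s)
    if (donor >= acceptor) stop("donor must precede acceptor")
    shift <- if (anchor == "boundary") 0L else 1L
    # two boundary-pair geometries of the direct-repeat model: the repeat at
    # (intron start, exon after) and at (exon before, intron end); taking the
    # max over both makes the score symmetric under reverse-complementation
    anchors <- list(c(donor + shift, acceptor + 1L + shift),
                    c(donor - k + shift, acceptor - k + 1L + shift))
    best <- -1L; bestOff <- NA_integer_; truncated <- FALSE
    for (a in anchors) for (d in seq.int(-window, window)) {
        s1 <- a[1] + d; s2 <- a[2] + d
        if (s1 < 1L || s2 < 1L || s1 + k - 1L > L || s2 + k - 1L > L) {
            truncated <- TRUE
            next
        }
        k1 <- chars(substr(s, s1, s1 + k - 1L))
        k2 <- chars(substr(s, s2, s2 + k - 1L))
        m <- sum(k1 == k2 & k1 != "N")
        if (m > best) { best <- m; bestOff <- d }
    }
    if (best < 0L) stop("no offset with sufficient flank for junction at ",
                        seqId, ":", donor, "-", acceptor)
    list(best_match = as.integer(best), best_offset = bestOff,
         truncated_flank = truncated)
}

#' Brute-force reference template-switch scorer
#'
#' Independent double-loop reference used to validate
#' [templateSwitchScore()]: explicit loops over every offset and every
#' position within the k-mers.
#'
#' @inheritParams templateSwitchScore
#' @return integer best match count.
#' @export
templateSwitchScoreBrute <- function(genome, seqId, donor, acceptor,
                                     k = 5L, window = 5L) {
    s <- asSeqVector(genome)[[seqId]]
    sc <- chars(s)
    best <- 0L
    starts1 <- c(donor, donor - k)
    starts2 <- c(acceptor + 1L, acceptor - k + 1L)
    for (fam in 1:2) for (d in seq.int(-window, window)) {
        s1 <- starts1[fam] + d; s2 <- starts2[fam] + d
        if (s1 < 1L || s2 < 1L || s1 + k - 1L > length(sc) ||
            s2 + k - 1L > length(sc)) next
        m <- 0L
        for (p in 0:(k - 1L))
            if (sc[s1 + p] == sc[s2 + p] && sc[s1 + p] != "N") m <- m + 1L
        if (m > best) best <- m
    }
    best
}

#' Splice-signal triage of junction candidates
#'
#' Computes the three splice-signal criteria used to rescue junction
#' candidates for manual study: (i) \code{fivess_near} - the first 6
#' intronic nt match \code{GTATGT} or \code{GTGAGT} with at least 5 of 6
#' identities; (ii) \code{ctag_end} - the last 3 intronic nt are \code{CAG}
#' or \code{TAG}; (iii) \code{bp_near_3} - a candidate branch point
#' \code{ACT[AG]AC} occurs with its last base within the final 20 intronic
#' nt. Minus-strand junctions are evaluated on the intron-sense sequence.
#'
#' @inheritParams templateSwitchScore
#' @param strand \code{"+"} or \code{"-"}.
#' @return list of logicals \code{fivess_near}, \code{ctag_end},
#'   \code{bp_near_3}.
#' @export
triageJunction <- function(genome, seqId, donor, acceptor, strand = "+") {
    seqs <- asSeqVector(genome)
    intron <- substr(seqs[[seqId]], donor, acceptor)
    if (strand == "-") intron <- revComp(intron)
    n <- nchar(intron)
    fivess <- FALSE
    if (n >= 6L) {
        first6 <- chars(substr(intron, 1, 6))
        fivess <- any(vapply(c("GTATGT", "GTGAGT"), function(p)
            sum(first6 == chars(p)) >= 5L, logical(1)))
    }
    ctag <- n >= 3L && substr(intron, n - 2L, n) %in% c("CAG", "TAG")
    bp <- FALSE
    if (n >= 6L) {
        hits <- scanMotifBrute(intron, compilePattern("ACT[A/G]AC"))
        bp <- nrow(hits) > 0 && any(hits$end >= n - 19L)
    }
    list(fivess_near = fivess, ctag_end = ctag, bp_near_3 = bp)
}

#' Score, flag and partition junction candidates
#'
#' Applies [templateSwitchScore()] and [triageJunction()] to a junction
#' table and partitions it into template-switch \code{artifacts} (perfect
#' k/k direct repeat), \code{rescued} candidates (any splice-signal
#' criterion met, among non-artifacts; artifact classification takes
#' precedence) and \code{other}. The summary reports the fraction of all
#' candidates with a perfect repeat and the fraction with a k-1 repeat.
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param junctions data.frame with columns \code{seq_id, donor, acceptor}
#'   and optionally \code{strand} (as from [readJunctions()]).
#' @param k,window,anchor passed to [templateSwitchScore()].
#' @return list with \code{table} (the input plus \code{best_match},
#'   \code{ts_5of5}, \code{ts_4of5}, \code{fivess_near}, \code{ctag_end},
#'   \code{bp_near_3}, \code{class}), and \code{summary} (list
#'   \code{n}, \code{frac_perfect}, \code{frac_nearmiss},
#'   \code{n_artifact}, \code{n_rescued}, \code{n_other}).
#' @export
filterJunctionCandidates <- function(genome, junctions, k = 5L, window = 5L,
                                     anchor = "boundary") {
    stopifnot(all(c("seq_id", "donor", "acceptor") %in% names(junctions)))
    n <- nrow(junctions)
    if (is.null(junctions$strand)) junctions$strand <- "+"
    best <- integer(n)
    f5 <- ce <- bp <- logical(n)
    for (i in seq_len(n)) {
        ts <- templateSwitchScore(genome, junctions$seq_id[i],
                                  junctions$donor[i], junctions$acceptor[i],
                                  k = k, window = window, anchor = anchor)
        best[i] <- ts$best_match
        tr <- triageJunction(genome, junctions$seq_id[i], junctions$donor[i],
                             junctions$acceptor[i], junctions$strand[i])
        f5[i] <- tr$fivess_near; ce[i] <- tr$ctag_end; bp[i] <- tr$bp_near_3
    }
    cls <- ifelse(best == k, "artifact",
                  ifelse(f5 | ce | bp, "rescued", "other"))
    tab <- cbind(junctions,
                 data.frame(best_match = best,
                            ts_5of5 = best == k, ts_4of5 = best == k - 1L,
                            fivess_near = f5, ctag_end = ce, bp_near_3 = bp,
                            class = cls))
    list(table = tab,
         summary = list(n = n,
                        frac_perfect = if (n) mean(best == k) else 0,
                        frac_nearmiss = if (n) mean(best == k - 1L) else 0,
                        n_artifact = sum(cls == "artifact"),
                        n_rescued = sum(cls == "rescued"),
                        n_other = sum(cls == "other")))
}
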