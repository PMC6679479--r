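#' Mismatches of a candidate loop against the U5 loop-I consensus
#'
#' Standalone predicate used both by the U5 search and by its
#' re-validation: position-wise IUPAC mismatch count of an 11-nt window
#' against the conserved U5 loop-I consensus \code{UGCCUUUUACY}.
#'
#' @param loopSeq 11-nt window (DNA or RNA alphabet).
#' @param consensus the loop consensus (DNA spelling by default).
#' @return integer mismatch count.
#' @export
u5LoopMismatches <- function(loopSeq, consensus = "TGCCTTTTACY") {
    s <- gsub("U", "T", toupper(loopSeq), fixed = TRUE)
    if (nchar(s) != nchar(consensus)) return(nchar(consensus))
    sc <- chars(s); pc <- chars(consensus)
    mis <- 0L
    for (j in seq_along(pc)) {
        ok <- if (sc[j] == "N") pc[j] == "N" else sc[j] %in% IUPAC_CLASSES[[pc[j]]]
        if (!ok) mis <- mis + 1L
    }
    mis
}

#' Consecutive closing stem pairs flanking a loop
#'
#' Standalone predicate: the number of consecutive base pairs (Watson-Crick
#' plus G:U wobble) formed by the nucleotides immediately flanking a loop,
#' pairing outward (last base before the loop with first base after it, and
#' so on).
#'
#' @param upstream bases 5' of the loop (closest to the loop last).
#' @param downstream bases 3' of the loop (closest to the loop first).
#' @return integer count of consecutive closing pairs.
#' @export
closingStemPairs <- function(upstream, downstream) {
    up <- chars(gsub("U", "T", toupper(upstream), fixed = TRUE))
    dn <- chars(gsub("U", "T", toupper(downstream), fixed = TRUE))
    m <- min(length(up), length(dn))
    cnt <- 0L
    for (j in seq_len(m)) {
        if (canPairDNA(up[length(up) - j + 1L], dn[j])) cnt <- cnt + 1L
        else break
    }
    cnt
}

#' Sm binding-site hits
#'
#' Standalone predicate: occurrences of the canonical single-stranded Sm
#' protein binding site \code{RAU(4-6)GR} on the sense strand.
#'
#' @param seq sequence (DNA or RNA alphabet).
#' @return data.frame \code{start, end} (1-based), possibly empty.
#' @export
smSiteHits <- function(seq) {
    s <- gsub("U", "T", toupper(seq), fixed = TRUE)
    h <- scanMotifBrute(s, compilePattern("RAT{4,6}GR"))
    h[c("start", "end")]
}

# count helix segments and internal loops along the stem enclosing `pos`
# in a pair matrix: walk the enclosing pairs from innermost outward,
# grouping directly-stacked pairs into helices; a gap on either side
# between consecutive enclosing pairs is an internal loop (or bulge).
stemArchitecture <- function(pairs, pos) {
    if (!nrow(pairs)) return(list(n_helix = 0L, n_internal = 0L,
                                  outer = c(NA_integer_, NA_integer_)))
    enc <- pairs[pairs[, 1] < pos & pairs[, 2] > pos, , drop = FALSE]
    if (!nrow(enc)) return(list(n_helix = 0L, n_internal = 0L,
                                outer = c(NA_integer_, NA_integer_)))
    enc <- enc[order(enc[, 1], decreasing = TRUE), , drop = FALSE]  # innermost first
    nHelix <- 1L; nInternal <- 0L
    if (nrow(enc) > 1) for (r in 2:nrow(enc)) {
        g1 <- enc[r - 1, 1] - enc[r, 1] - 1L
        g2 <- enc[r, 2] - enc[r - 1, 2] - 1L
        if (g1 > 0L || g2 > 0L) {
            nHelix <- nHelix + 1L
            nInternal <- nInternal + 1L
        }
    }
    list(n_helix = nHelix, n_internal = nInternal,
         outer = c(enc[nrow(enc), 1], enc[nrow(enc), 2]))
}

#' Search a genome for U5 snRNA-like loci
#'
#' Three-stage structured-motif search for U5 snRNA candidates. Stage 1:
#' occurrences of the conserved loop-I sequence \code{UGCCUUUUACY} with at
#' most \code{maxLoopMismatches} substitutions whose immediate flanks (6 nt
#' each side) can form at least \code{minStemPairs} consecutive closing base
#' pairs (G:U wobble allowed). Stage 2: a constrained fold of the hit plus
#' \code{flank} nt of context (loop positions forced single-stranded) must
#' place the loop inside an extended stem-loop with at least 3 helix
#' segments separated by at least 2 internal loops (the canonical 1a/1b/1c
#' helices with internal loops IL1 and IL2). Stage 3: a canonical Sm site
#' must occur downstream of the stem-loop within the flank. Candidates
#' passing stage 1 but failing stage 2 or 3 are retained flagged
#' \code{partial}. Both strands are searched.
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param flank context examined on each side of the loop hit (nt).
#' @param maxLoopMismatches loop-I mismatch allowance (default 2).
#' @param minStemPairs consecutive closing pairs required at stage 1.
#' @param temperature folding temperature for stage 2.
#' @return data.frame with one row per candidate: \code{seq_id, start, end,
#'   strand} (loop-I span, plus-strand coordinates), \code{loop_mismatches,
#'   stem_pairs, n_helix, n_internal, sm_start, sm_end} (relative to the
#'   folded window), \code{full} (passed all three stages), \code{partial},
#'   and \code{window_seq}/\code{window_db} (folded context and its
#'   structure).
#' @export
findU5Candidates <- function(genome, flank = 100L, maxLoopMismatches = 2L,
                             minStemPairs = 6L, temperature = 37) {
    seqs <- asSeqVector(genome)
    loopPat <- compilePattern("TGCCTTTTACY", maxLoopMismatches)
    out <- list()
    for (id in names(seqs)) {
        fwd <- seqs[[id]]
        L <- nchar(fwd)
        for (strand in c("+", "-")) {
            s <- if (strand == "+") fwd else revComp(fwd)
            hits <- scanMotif(stats::setNames(s, id), loopPat, strands = "+")
            if (!length(hits)) next
            for (h in seq_along(hits)) {
                hs <- GenomicRanges::start(hits)[h]
                he <- GenomicRanges::end(hits)[h]
                if (hs < 7L || he + 6L > nchar(s)) next
                stem <- closingStemPairs(substr(s, hs - 6L, hs - 1L),
                                         substr(s, he + 1L, he + 6L))
                if (stem < minStemPairs) next
                ws <- max(1L, hs - flank)
                we <- min(nchar(s), he + flank)
                win <- substr(s, ws, we)
                loopIdx <- (hs - ws + 1L):(he - ws + 1L)
                fold <- foldConstrained(win, unpaired = loopIdx,
                                        temperature = temperature,
                                        nBest = 1L)[[1]]
                arch <- stemArchitecture(fold@pairs,
                                         loopIdx[ceiling(length(loopIdx) / 2)])
                stage2 <- arch$n_helix >= 3L && arch$n_internal >= 2L
                # Sm site downstream of the stem-loop: past the closing stem
                # on the 3' side of the loop (the MFE stem may be extended by
                # context pairing, so anchor on the loop, not the outer pair)
                smFrom <- max(loopIdx) + minStemPairs + 1L
                sm <- smSiteHits(substr(win, smFrom, nchar(win)))
                stage3 <- nrow(sm) > 0
                smStart <- if (stage3) sm$start[1] + smFrom - 1L else NA_integer_
                smEnd <- if (stage3) sm$end[1] + smFrom - 1L else NA_integer_
                st <- hs; en <- he
                if (strand == "-") { st <- L - he + 1L; en <- L - hs + 1L }
                out[[length(out) + 1L]] <- data.frame(
                    seq_id = id, start = st, end = en, strand = strand,
                    loop_mismatches = hits$mismatches[h],
                    stem_pairs = stem,
                    n_helix = arch$n_helix, n_internal = arch$n_internal,
                    sm_start = smStart, sm_end = smEnd,
                    full = stage2 && stage3,
                    partial = !(stage2 && stage3),
                    window_seq = win,
                    window_db = fold@dotbracket)
            }
        }
    }
    if (!length(out))
        return(data.frame(seq_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          loop_mismatches = integer(0), stem_pairs = integer(0),
                          n_helix = integer(0), n_internal = integer(0),
                          sm_start = integer(0), sm_end = integer(0),
                          full = logical(0), partial = logical(0),
                          window_seq = character(0), window_db = character(0)))
    df <- do.call(rbind, out)
    df[order(df$seq_id, df$start), , drop = FALSE]
}

#' U2 snRNA feature annotation
#'
#' Annotates a candidate U2 snRNA sequence with the features expected of a
#' functional U2: (i) \code{bp_interaction} - some window of the candidate
#' can base-pair (Watson-Crick plus G:U) with the intron branch-point region
#' leaving exactly the branch adenosine unpaired (bulged); (ii) presence and
#' positions of the conserved \code{GCU} and \code{GAUC} sequences that form
#' U2-U6 intermolecular helix I; (iii) a canonical Sm site.
#'
#' @param candidateSeq candidate sequence, RNA sense (DNA spelling accepted).
#' @param bpRegion intron branch-point region, RNA sense 5'->3' (default
#'   \code{"UACUAAC"}).
#' @param branchA 1-based position of the branch adenosine within
#'   \code{bpRegion} (default: the adenosine directly 5' of the final C).
#' @return list \code{bp_interaction} (logical),
#'   \code{bp_window} (candidate window pairing the BP region, or NA),
#'   \code{bulge_unique} (the bulged position is unique), \code{helix1_motifs}
#'   (data.frame motif/position, possibly empty), \code{sm_site} (data.frame).
#' @export
checkU2Features <- function(candidateSeq, bpRegion = "UACUAAC",
                            branchA = NULL) {
    cand <- gsub("U", "T", toupper(candidateSeq), fixed = TRUE)
    bp <- gsub("U", "T", toupper(bpRegion), fixed = TRUE)
    nb <- nchar(bp)
    if (is.null(branchA)) {
        # adenosine directly 5' of the last C of the ACUAAC-like core
        lastC <- max(gregexpr("C", bp)[[1]])
        branchA <- lastC - 1L
    }
    if (substr(bp, branchA, branchA) != "A")
        stop("branchA position is not an adenosine in bpRegion")
    bpCh <- chars(bp)
    # candidate window pairs antiparallel with bpRegion minus the bulged base
    pairsWithBulge <- function(win, bulgeAt) {
        red <- bpCh[-bulgeAt]
        w <- chars(win)
        if (length(w) != length(red)) return(FALSE)
        all(vapply(seq_along(red), function(t)
            canPairDNA(red[t], w[length(w) - t + 1L]), logical(1)))
    }
    wlen <- nb - 1L
    bpOk <- FALSE; bpWin <- NA_character_; unique_bulge <- NA
    if (nchar(cand) >= wlen) {
        for (i in seq_len(nchar(cand) - wlen + 1L)) {
            win <- substr(cand, i, i + wlen - 1L)
            if (pairsWithBulge(win, branchA)) {
                bpOk <- TRUE
                bpWin <- win
                # adjacent adenosines give an identical reduced duplex, so
                # uniqueness is assessed against non-adjacent alternatives
                others <- setdiff(which(bpCh == "A"),
                                  (branchA - 1L):(branchA + 1L))
                unique_bulge <- !any(vapply(others, function(b)
                    pairsWithBulge(win, b), logical(1)))
                break
            }
        }
    }
    h1 <- list()
    for (m in c("GCT", "GATC")) {
        g <- gregexpr(m, cand, fixed = TRUE)[[1]]
        g <- g[g > 0]
        if (length(g))
            h1[[length(h1) + 1L]] <- data.frame(
                motif = gsub("T", "U", m), position = g)
    }
    helix1 <- if (length(h1)) do.call(rbind, h1) else
        data.frame(motif = character(0), position = integer(0))
    list(bp_interaction = bpOk,
         bp_window = gsub("T", "U", bpWin),
         bulge_unique = unique_bulge,
         helix1_motifs = helix1,
         sm_site = smSiteHits(cand))
}
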