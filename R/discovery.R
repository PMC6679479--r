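#' Translate a nucleotide sequence
#'
#' Frame-aware translation under either the standard genetic code or the
#' ciliate code (NCBI translation table 6, which also covers diplomonads):
#' TAA and TAG encode glutamine and TGA is the sole stop codon. The trailing
#' partial codon is dropped.
#'
#' @param seq nucleotide string.
#' @param frame 0, 1 or 2 (nucleotides skipped before the first codon).
#' @param code \code{"ciliate"} or \code{"standard"}.
#' @return amino-acid string; stops are \code{"*"}.
#' @examples
#' translateSeq("TAATAGTGA", 0, "ciliate")   # "QQ*"
#' @export
translateSeq <- function(seq, frame = 0L, code = c("ciliate", "standard")) {
    code <- match.arg(code)
    stopifnot(frame %in% 0:2)
    s <- toupper(seq)
    s <- substr(s, frame + 1L, nchar(s))
    s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
    if (!nchar(s)) return("")
    gc <- Biostrings::getGeneticCode(if (code == "ciliate") "6" else "1")
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = gc))
}

#' Genome-wide intron candidate discovery
#'
#' Scans contigs for the fused branch-point + 3' splice-site consensus and,
#' for every anchor, searches the upstream region for donor-site hits that
#' yield an intron length within bounds. The intron 3' end is the final
#' position of the anchor match (the terminal \code{AG}); the 5' end is the
#' first position of the donor match (the \code{GT}). When several donor
#' hits precede one anchor all are emitted, ranked by proximity to the
#' anchor (\code{rank} 1 is the closest). Candidates are deduplicated by
#' (contig, start, end, strand). Both strands are scanned; minus-strand
#' candidates are reported in plus-strand coordinates.
#'
#' An optional displaced-acceptor mode additionally searches for candidates
#' whose branch-point motif is not fused to the acceptor: a branch-point
#' core hit followed by \code{YAG} within \code{maxDisplacement} nt is
#' emitted flagged \code{displaced_3ss}, for folding follow-up.
#'
#' @param genome named \code{DNAStringSet} (or named character vector).
#' @param fiveSS donor consensus pattern (default \code{"GTAAGTY"}).
#' @param bp3SS fused branch-point + acceptor pattern (default
#'   \code{"RCTAACAARHTAG"}; the \code{Y}-variant \code{"RCTAACAARYTAG"} is
#'   also accepted by the consensus).
#' @param mismatches mismatch allowance applied to both patterns.
#' @param minLen,maxLen intron length bounds in nt (defaults 40-120).
#' @param branchOffset 1-based offset of the branch adenosine within the
#'   \code{bp3SS} motif (default 5, the adenosine directly 5' of the last C
#'   of the ACTAAC-like core).
#' @param displaced if \code{TRUE}, also emit displaced-acceptor candidates.
#' @param maxDisplacement maximum nt between branch-point motif end and the
#'   \code{YAG} acceptor in displaced mode (default 20).
#' @param bpCore branch-point core pattern used only in displaced mode.
#' @return a \code{GRanges} of intron candidates with metadata columns
#'   \code{five_ss}, \code{bp_3ss}, \code{branch_a_offset} (1-based offset of
#'   the branch adenosine within the intron), \code{rank},
#'   \code{displaced_3ss}, and \code{intron_seq} (intron-strand sequence).
#' @export
scanGenomeForIntrons <- function(genome,
                                 fiveSS = "GTAAGTY",
                                 bp3SS = "RCTAACAARHTAG",
                                 mismatches = 0L,
                                 minLen = 40L, maxLen = 120L,
                                 branchOffset = 5L,
                                 displaced = FALSE,
                                 maxDisplacement = 20L,
                                 bpCore = "RCTAACAAR") {
    if (minLen > maxLen) stop("minLen exceeds maxLen")
    if (minLen < 15L) stop("minLen must be >= 15")
    seqs <- asSeqVector(genome)
    p5 <- compilePattern(fiveSS, mismatches)
    pA <- compilePattern(bp3SS, mismatches)
    out <- list()
    emit <- function(id, strand, sseq, start5, matched5,
                     aStart, aEnd, matchedA, disp, bOff) {
        # coordinates on the scanned (intron-sense) strand
        len <- aEnd - start5 + 1L
        if (len < minLen || len > maxLen) return(NULL)
        data.frame(seq_id = id, s = start5, e = aEnd, strand = strand,
                   five_ss = matched5, bp_3ss = matchedA,
                   branch_a = aStart - start5 + bOff,
                   displaced_3ss = disp,
                   intron_seq = substr(sseq, start5, aEnd))
    }
    for (id in names(seqs)) {
        fwd <- seqs[[id]]
        L <- nchar(fwd)
        for (strand in c("+", "-")) {
            s <- if (strand == "+") fwd else revComp(fwd)
            a5 <- scanMotif(stats::setNames(s, id), p5, strands = "+")
            anch <- scanMotif(stats::setNames(s, id), pA, strands = "+")
            rows <- list()
            addFrom <- function(anchorStart, anchorEnd, anchorTxt, disp,
                                bOff) {
                if (!length(a5)) return(NULL)
                st5 <- GenomicRanges::start(a5)
                keep <- which(st5 <= anchorEnd - minLen + 1L &
                              st5 >= anchorEnd - maxLen + 1L &
                              st5 < anchorStart)
                if (!length(keep)) return(NULL)
                keep <- keep[order(anchorStart - st5[keep])]  # closest first
                for (r in seq_along(keep)) {
                    k <- keep[r]
                    rec <- emit(id, strand, s, st5[k], a5$matched[k],
                                anchorStart, anchorEnd, anchorTxt, disp, bOff)
                    if (!is.null(rec)) {
                        rec$rank <- r
                        rows[[length(rows) + 1L]] <<- rec
                    }
                }
            }
            if (length(anch))
                for (a in seq_along(anch))
                    addFrom(GenomicRanges::start(anch)[a],
                            GenomicRanges::end(anch)[a],
                            anch$matched[a], FALSE, branchOffset)
            if (displaced) {
                pC <- compilePattern(bpCore, mismatches)
                cores <- scanMotif(stats::setNames(s, id), pC, strands = "+")
                if (length(cores)) for (a in seq_along(cores)) {
                    ce <- GenomicRanges::end(cores)[a]
                    dn <- substr(s, ce + 1L, min(L, ce + maxDisplacement + 3L))
                    m <- gregexpr("[CT]AG", dn)[[1]]
                    m <- m[m > 0]
                    for (pos in m) {
                        gap <- pos - 1L   # nt between core end and YAG
                        if (gap > maxDisplacement) next
                        addFrom(GenomicRanges::start(cores)[a],
                                ce + pos + 2L,
                                paste0(cores$matched[a],
                                       substr(dn, pos, pos + 2L)),
                                TRUE, branchOffset)
                    }
                }
            }
            if (!length(rows)) next
            df <- do.call(rbind, rows)
            if (strand == "-") {
                s2 <- L - df$e + 1L; e2 <- L - df$s + 1L
                df$s <- s2; df$e <- e2
            }
            out[[length(out) + 1L]] <- df
        }
    }
    if (!length(out))
        return(GenomicRanges::GRanges(
            five_ss = character(0), bp_3ss = character(0),
            branch_a_offset = integer(0), rank = integer(0),
            displaced_3ss = logical(0), intron_seq = character(0)))
    df <- do.call(rbind, out)
    df <- df[!duplicated(df[c("seq_id", "s", "e", "strand")]), , drop = FALSE]
    df <- df[order(df$seq_id, df$s, df$e), , drop = FALSE]
    GenomicRanges::GRanges(
        seqnames = df$seq_id,
        ranges = IRanges::IRanges(df$s, df$e),
        strand = df$strand,
        five_ss = df$five_ss, bp_3ss = df$bp_3ss,
        branch_a_offset = as.integer(df$branch_a),
        rank = as.integer(df$rank),
        displaced_3ss = df$displaced_3ss,
        intron_seq = df$intron_seq)
}

#' Assess open-reading-frame disruption by an unspliced intron
#'
#' Whether retention of the intron in the transcript would truncate the
#' protein: \code{in_frame_stop} is \code{TRUE} when a stop codon of the
#' chosen genetic code (under the ciliate code only \code{TGA} is a stop)
#' lies entirely within the intron in the upstream reading frame;
#' \code{frameshift} is \code{TRUE} exactly when the intron length is not a
#' multiple of 3.
#'
#' @param geneSeq gene-region nucleotide string containing the intron.
#' @param intronStart,intronEnd 1-based inclusive intron span within
#'   \code{geneSeq}.
#' @param cdsFrame reading-frame phase at the intron 5' boundary: the number
#'   of coding nucleotides of the interrupted codon already read (0, 1, 2).
#' @param code genetic code, as in [translateSeq()].
#' @return list \code{in_frame_stop}, \code{frameshift},
#'   \code{stop_codons} (0-length or the in-frame stop codons found).
#' @export
assessOrfDisruption <- function(geneSeq, intronStart, intronEnd,
                                cdsFrame = 0L,
                                code = c("ciliate", "standard")) {
    code <- match.arg(code)
    n <- nchar(geneSeq)
    if (intronStart < 1L || intronEnd > n || intronStart >= intronEnd)
        stop("intron span outside the gene sequence")
    len <- intronEnd - intronStart + 1L
    stops <- if (code == "ciliate") "TGA" else c("TAA", "TAG", "TGA")
    # first in-frame codon start at or after the intron 5' boundary
    first <- intronStart + ((3L - cdsFrame) %% 3L)
    found <- character(0)
    k <- first
    while (k + 2L <= intronEnd) {
        cod <- substr(geneSeq, k, k + 2L)
        if (cod %in% stops) found <- c(found, cod)
        k <- k + 3L
    }
    list(in_frame_stop = length(found) > 0L,
         frameshift = (len %% 3L) != 0L,
         stop_codons = found)
}

#' Annotate an intron candidate with conserved motifs and phase
#'
#' Computes the accessory annotations of a discovered intron: whether its
#' first 11 nt match the extended donor consensus \code{GTARGTYTAAA};
#' pyrimidine-motif (\code{AAC[T/C]{3,4}R}) hits whose 3' end directly abuts
#' the branch-point motif start; the intron phase; and whether it is a
#' start-codon intron (phase 0 with exactly 3 coding nt upstream).
#'
#' @param intronSeq intron-strand intron sequence.
#' @param bpMotifStart 1-based start of the branch-point + acceptor motif
#'   within the intron (needed for the abutting test; \code{NA} skips it).
#' @param cdsUpstream number of coding nucleotides upstream of the intron
#'   (\code{NA} when no CDS context is known).
#' @return list \code{extended_5ss}, \code{pyrimidine_hits} (integer starts
#'   of abutting hits), \code{all_pyrimidine_hits}, \code{phase} (0/1/2 or
#'   \code{NA}), \code{start_codon_intron}.
#' @export
annotateIntron <- function(intronSeq, bpMotifStart = NA_integer_,
                           cdsUpstream = NA_integer_) {
    s <- toupper(intronSeq)
    ext <- nchar(s) >= 11L &&
        nrow(scanMotifBrute(substr(s, 1, 11), compilePattern("GTARGTYTAAA"))) > 0
    py <- scanMotif(s, compilePattern("AAC[T/C]{3,4}R"), strands = "+")
    allHits <- GenomicRanges::start(py)
    # "abutting" admits a shared base: the motif's terminal purine may be the
    # branch motif's leading purine (as in the Rps15 'AACTTTGCTAACAA' context)
    abutting <- if (!is.na(bpMotifStart) && length(py))
        allHits[GenomicRanges::end(py) %in% c(bpMotifStart - 1L, bpMotifStart)]
    else integer(0)
    phase <- if (is.na(cdsUpstream)) NA_integer_ else cdsUpstream %% 3L
    list(extended_5ss = ext,
         pyrimidine_hits = abutting,
         all_pyrimidine_hits = allHits,
         phase = phase,
         start_codon_intron = !is.na(cdsUpstream) &&
             phase == 0L && cdsUpstream == 3L)
}
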