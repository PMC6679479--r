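#' Compile a degenerate IUPAC pattern
#'
#' Compiles a degenerate nucleotide pattern into fixed-length IUPAC
#' expansions. The syntax accepts single IUPAC codes, explicit base classes
#' written \code{"[X/Y]"} (e.g. \code{"[T/C]"}, which maps onto the IUPAC
#' code for that class), and bounded repeats \code{"{m,n}"} or \code{"{m}"}
#' applied to the preceding token. Bounded repeats are expanded into one
#' fixed-length alternative per repeat count, so \code{"RAT{4,6}GR"} yields
#' three expansions of widths 8, 9 and 10.
#'
#' The splice-signal consensus patterns used throughout the pipeline (donor
#' \code{"GTAAGTY"}, fused branch-point + acceptor \code{"RCTAACAARHTAG"} or
#' its \code{"RCTAACAARYTAG"} variant, extended donor \code{"GTARGTYTAAA"},
#' pyrimidine motif \code{"AAC[T/C]{3,4}R"}, Sm site \code{"RAT{4,6}GR"}) all
#' compile with this syntax. The fused branch-point motif is reported with an
#' \code{H} at position 10 in one part of the source literature and a
#' \code{Y} in another; both compile, and [defaultPatterns()] carries the
#' broader \code{H} form as the default with the \code{Y} form available.
#'
#' @param pattern the degenerate pattern string.
#' @param maxMismatches non-negative mismatch allowance used by [scanMotif()].
#' @return a [CompiledPattern-class] object.
#' @examples
#' compilePattern("RCTAACAARHTAG")
#' compilePattern("AAC[T/C]{3,4}R", maxMismatches = 0)
#' @export
compilePattern <- function(pattern, maxMismatches = 0L) {
    stopifnot(length(pattern) == 1L, maxMismatches >= 0)
    up <- toupper(pattern)
    i <- 1L
    n <- nchar(up)
    tokens <- list()   # each: character vector of IUPAC codes (one per count)
    while (i <= n) {
        ch <- substr(up, i, i)
        if (ch == "[") {
            close <- regexpr("]", substr(up, i, n), fixed = TRUE)
            if (close < 0) stop("unterminated '[' in pattern at position ", i)
            body <- substr(up, i + 1L, i + close - 2L)
            bases <- unlist(strsplit(body, "/", fixed = TRUE))
            if (!all(bases %in% c("A", "C", "G", "T")))
                stop("invalid base class '[", body, "]' in pattern")
            code <- iupacCodeFor(bases)
            i <- i + close
        } else if (ch == "{") {
            stop("'{' must follow a pattern token, at position ", i)
        } else {
            if (!ch %in% names(IUPAC_CLASSES))
                stop("invalid IUPAC code '", ch, "' in pattern at position ", i)
            code <- ch
            i <- i + 1L
        }
        reps <- 1L
        if (i <= n && substr(up, i, i) == "{") {
            close <- regexpr("}", substr(up, i, n), fixed = TRUE)
            if (close < 0) stop("unterminated '{' in pattern at position ", i)
            body <- substr(up, i + 1L, i + close - 2L)
            mn <- suppressWarnings(as.integer(strsplit(body, ",")[[1]]))
            if (anyNA(mn) || !length(mn) %in% 1:2 ||
                (length(mn) == 2L && mn[1] > mn[2]) || any(mn < 0))
                stop("invalid bounded repeat '{", body, "}'")
            reps <- if (length(mn) == 1L) mn else mn[1]:mn[2]
            i <- i + close
        }
        tokens[[length(tokens) + 1L]] <- vapply(
            reps, function(r) paste(rep(code, r), collapse = ""), character(1))
    }
    expansions <- Reduce(function(acc, tok)
        as.vector(outer(acc, tok, paste0)), tokens, accumulate = FALSE,
        init = "")
    methods::new("CompiledPattern", pattern = pattern,
                 maxMismatches = as.integer(maxMismatches),
                 expansions = unname(expansions))
}

# scan one plus-strand character sequence with one fixed-length IUPAC
# expansion; returns data.frame(start, end, mismatches) in 1-based
# inclusive coordinates. Vectorized over offsets per pattern position.
scanExpansion <- function(seqChars, codes, pat, maxMismatches) {
    m <- nchar(pat)
    L <- length(seqChars)
    if (L < m) return(data.frame(start = integer(0), end = integer(0),
                                 mismatches = integer(0)))
    pch <- chars(pat)
    nW <- L - m + 1L
    mis <- integer(nW)
    for (j in seq_len(m)) {
        ok <- iupacAcceptMatrix[pch[j], codes[j:(j + nW - 1L)]]
        mis <- mis + !ok
    }
    hit <- which(mis <= maxMismatches)
    data.frame(start = hit, end = hit + m - 1L, mismatches = mis[hit])
}

#' Scan sequences for a compiled pattern
#'
#' Scans every record for matches of a [CompiledPattern-class] within its
#' mismatch allowance, on one or both strands. A position matches when the
#' subject base belongs to the pattern symbol's IUPAC class; each
#' non-matching position costs one mismatch; indels are not allowed. A
#' subject \code{N} never satisfies a pattern symbol other than \code{N}.
#' Minus-strand hits are reported in plus-strand coordinates with
#' \code{strand == "-"}; overlapping hits are all reported.
#'
#' @param genome a named \code{DNAStringSet}, named character vector, or a
#'   single sequence string.
#' @param compiled a [CompiledPattern-class] (or a pattern string, compiled
#'   with zero mismatches).
#' @param strands \code{"+"}, \code{"-"} or \code{"both"}.
#' @return a \code{GRanges} sorted by (seqname, start), with metadata columns
#'   \code{mismatches} and \code{matched} (the matched plus-strand text for
#'   \code{+} hits; the minus-strand motif text for \code{-} hits).
#' @examples
#' scanMotif("GCTAACAAACTAG", compilePattern("RCTAACAARHTAG"))
#' @export
scanMotif <- function(genome, compiled, strands = c("both", "+", "-")) {
    strands <- match.arg(strands)
    if (is.character(compiled) && length(compiled) == 1L &&
        !methods::is(compiled, "CompiledPattern"))
        compiled <- compilePattern(compiled)
    seqs <- asSeqVector(genome)
    res <- list()
    for (id in names(seqs)) {
        sc <- chars(seqs[[id]])
        codes <- match(sc, SUBJECT_ALPHABET)
        if (anyNA(codes))
            stop("sequence '", id, "' contains characters outside {A,C,G,T,N}")
        L <- length(sc)
        doStrand <- function(st) {
            if (st == "-") {
                rcc <- rev(unname(COMPLEMENT[sc]))
                cod <- match(rcc, SUBJECT_ALPHABET)
            } else cod <- codes
            hits <- do.call(rbind, lapply(compiled@expansions, function(p)
                scanExpansion(if (st == "-") rcc else sc, cod, p,
                              compiled@maxMismatches)))
            if (is.null(hits) || !nrow(hits)) return(NULL)
            if (st == "-") {
                txt <- substring(paste(rcc, collapse = ""), hits$start, hits$end)
                s <- L - hits$end + 1L
                e <- L - hits$start + 1L
                hits$start <- s; hits$end <- e
            } else {
                txt <- substring(seqs[[id]], hits$start, hits$end)
            }
            hits$matched <- txt
            hits$strand <- st
            hits
        }
        hits <- switch(strands,
            "+" = doStrand("+"),
            "-" = doStrand("-"),
            both = rbind(doStrand("+"), doStrand("-")))
        if (is.null(hits) || !nrow(hits)) next
        # dedup identical (start,end,strand) keeping min mismatches
        key <- paste(hits$start, hits$end, hits$strand)
        hits <- hits[order(key, hits$mismatches), ]
        hits <- hits[!duplicated(paste(hits$start, hits$end, hits$strand)), ]
        res[[id]] <- GenomicRanges::GRanges(
            seqnames = id,
            ranges = IRanges::IRanges(hits$start, hits$end),
            strand = hits$strand,
            mismatches = hits$mismatches,
            matched = hits$matched)
    }
    if (!length(res))
        return(GenomicRanges::GRanges(mismatches = integer(0),
                                      matched = character(0)))
    out <- suppressWarnings(do.call(c, unname(res)))
    out[order(as.character(GenomicRanges::seqnames(out)),
              GenomicRanges::start(out), GenomicRanges::end(out),
              as.character(GenomicRanges::strand(out)))]
}

#' Brute-force reference scanner
#'
#' Independent per-offset reference implementation used to validate
#' [scanMotif()]: every offset of every expansion is tested position by
#' position against the expanded character classes. Plus strand only (strand
#' handling is validated separately through the reverse-complement
#' symmetry property). Intentionally simple and slow.
#'
#' @param seq a single plus-strand sequence string.
#' @param compiled a [CompiledPattern-class].
#' @return data.frame \code{start, end, mismatches} (1-based inclusive),
#'   sorted by (start, end).
#' @export
scanMotifBrute <- function(seq, compiled) {
    sc <- chars(toupper(seq))
    out <- list()
    kmax <- compiled@maxMismatches
    for (pat in compiled@expansions) {
        pch <- chars(pat)
        cls <- IUPAC_CLASSES[pch]
        m <- length(pch)
        if (length(sc) < m) next
        for (i in seq_len(length(sc) - m + 1L)) {
            mis <- 0L
            for (j in seq_len(m)) {
                b <- sc[i + j - 1L]
                classOk <- if (b == "N") pch[j] == "N" else b %in% cls[[j]]
                if (!classOk) {
                    mis <- mis + 1L
                    if (mis > kmax) break
                }
            }
            if (mis <= kmax)
                out[[length(out) + 1L]] <- c(i, i + m - 1L, mis)
        }
    }
    if (!length(out))
        return(data.frame(start = integer(0), end = integer(0),
                          mismatches = integer(0)))
    df <- as.data.frame(do.call(rbind, out))
    names(df) <- c("start", "end", "mismatches")
    df <- df[order(df$start, df$end, df$mismatches), ]
    df <- df[!duplicated(df[c("start", "end")]), ]
    rownames(df) <- NULL
    df
}

#' Default consensus patterns of the pipeline
#'
#' The degenerate splice-signal and snRNA motifs used by the discovery,
#' triage and snRNA stages, with their default mismatch allowances. The
#' fused branch-point + acceptor consensus exists in two published variants
#' (\code{H} vs \code{Y} at position 10); the broader \code{H} form is the
#' default and the \code{Y} form is included as \code{bp3ss_y}.
#'
#' @return a named list of pattern strings.
#' @export
defaultPatterns <- function() {
    list(
        five_ss = "GTAAGTY",
        bp3ss = "RCTAACAARHTAG",
        bp3ss_y = "RCTAACAARYTAG",
        extended_five_ss = "GTARGTYTAAA",
        pyrimidine = "AAC[T/C]{3,4}R",
        sm_site = "RAT{4,6}GR",
        u5_loop1 = "TGCCTTTTACY",
        triage_five_a = "GTATGT",
        triage_five_b = "GTGAGT",
        triage_bp = "ACT[A/G]AC"
    )
}
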