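# IUPAC degenerate nucleotide classes over {A,C,G,T}. A pattern symbol
# matches a subject base iff the base belongs to the symbol's class; an 'N'
# in the subject never satisfies a pattern symbol other than 'N'.
IUPAC_CLASSES <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
)

# subject alphabet used by the scanner
SUBJECT_ALPHABET <- c("A", "C", "G", "T", "N")

# 15 x 5 logical: does pattern code (row) accept subject base (column)?
# Subject 'N' is accepted only by pattern 'N'.
iupacAcceptMatrix <- local({
    m <- matrix(FALSE, nrow = length(IUPAC_CLASSES), ncol = 5,
                dimnames = list(names(IUPAC_CLASSES), SUBJECT_ALPHABET))
    for (code in names(IUPAC_CLASSES))
        m[code, IUPAC_CLASSES[[code]]] <- TRUE
    m["N", "N"] <- TRUE
    m
})

# map a set of bases to the IUPAC code with exactly that class
iupacCodeFor <- function(bases) {
    bases <- sort(unique(bases))
    for (code in names(IUPAC_CLASSES))
        if (identical(sort(IUPAC_CLASSES[[code]]), bases)) return(code)
    stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper (IUPAC codes supported).
#'
#' @param x a single DNA string.
#' @return the reverse complement as a character string.
#' @export
revComp <- function(x) {
    ch <- strsplit(toupper(x), "")[[1]]
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
}

# split a single string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# coerce a genome argument (DNAStringSet / named character / single string)
# to a named character vector of uppercase sequences
asSeqVector <- function(genome) {
    if (methods::is(genome, "DNAStringSet")) {
        stats::setNames(as.character(genome), names(genome))
    } else if (methods::is(genome, "DNAString")) {
        stats::setNames(as.character(genome), "seq")
    } else if (is.character(genome)) {
        nm <- names(genome)
        if (is.null(nm)) nm <- if (length(genome) == 1L) "seq" else
            paste0("seq", seq_along(genome))
        stats::setNames(toupper(genome), nm)
    } else {
        stop("unsupported genome representation: ", class(genome)[1])
    }
}

# Watson-Crick + wobble pairing on the DNA alphabet (T == U)
canPairDNA <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Write a TSV report with provenance comments
#'
#' All human-readable reports share one dialect: '#'-prefixed provenance
#' comment lines, then a header line, then tab-separated rows. Coordinates in
#' reports are 1-based inclusive.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param comments character vector of provenance lines (without the '#').
#' @return the path, invisibly.
#' @export
writeReport <- function(df, path, comments = character()) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("# ", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
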