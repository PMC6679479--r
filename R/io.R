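#' Read genome/contig sequences from FASTA
#'
#' Reads a FASTA file into a named \code{DNAStringSet}. Sequences are
#' uppercased, \code{U} is converted to \code{T} (with a note), and any
#' character outside \code{A,C,G,T,N} (after uppercasing; IUPAC ambiguity
#' codes other than N are not part of the genome alphabet contract) raises an
#' error naming the record and offending position. Soft-masking (lowercase)
#' is ignored by the uppercasing step.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a named \code{DNAStringSet}, records in file order. An empty file
#'   yields an empty set with a warning.
#' @seealso [writeGenome()]
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty FASTA file: ", path)
        return(Biostrings::DNAStringSet())
    }
    if (!startsWith(lines[1], ">"))
        stop("not FASTA: first non-empty line does not start with '>'")
    hdr <- startsWith(lines, ">")
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
    # records with no sequence lines get empty strings
    all <- stats::setNames(rep("", length(ids)), as.character(seq_along(ids)))
    all[names(seqs)] <- seqs
    seqs <- toupper(all)
    if (any(grepl("U", seqs, fixed = TRUE))) {
        message("note: 'U' converted to 'T' on load")
        seqs <- gsub("U", "T", seqs, fixed = TRUE)
    }
    for (k in seq_along(seqs)) {
        bad <- regexpr("[^ACGTN]", seqs[[k]])
        if (bad > 0)
            stop("non-IUPAC genome character '",
                 substr(seqs[[k]], bad, bad), "' in record '", ids[k],
                 "' at position ", bad)
    }
    if (anyDuplicated(ids))
        stop("duplicate record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    stats::setNames(Biostrings::DNAStringSet(unname(seqs)), ids)
}

#' Write sequences to FASTA
#'
#' @param x a named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @param width line-wrap width (nt).
#' @return the path, invisibly.
#' @export
writeGenome <- function(x, path, width = 70L) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Parse tabular BLAST output (outfmt 6 style)
#'
#' Reads a 12+ column tab-separated hit table. Rows keep file order, which
#' carries the ranking semantics used by the census "top 10" rule.
#'
#' @param path path to the tabular file.
#' @return a data.frame with columns \code{query, subject, identity, aln_len,
#'   mismatches, gap_opens, q_start, q_end, s_start, s_end, evalue, bitscore}
#'   plus \code{q_len, s_len} when 14 columns are present.
#' @export
readBlastTab <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    base <- c("query", "subject", "identity", "aln_len", "mismatches",
              "gap_opens", "q_start", "q_end", "s_start", "s_end",
              "evalue", "bitscore")
    if (!length(lines)) {
        warning("no data rows in ", path)
        out <- as.data.frame(stats::setNames(
            rep(list(character(0)), length(base)), base))
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 12L))
        stop("malformed BLAST tabular line ", which(ncols < 12L)[1],
             ": expected >= 12 columns, found ", ncols[ncols < 12L][1])
    n <- min(ncols)
    mat <- t(vapply(fields, function(f) f[seq_len(n)], character(n)))
    cols <- base
    if (n >= 14L) cols <- c(cols, "q_len", "s_len")
    df <- as.data.frame(mat[, seq_along(cols), drop = FALSE],
                        stringsAsFactors = FALSE)
    names(df) <- cols
    num <- setdiff(cols, c("query", "subject"))
    suppressWarnings(df[num] <- lapply(df[num], as.numeric))
    badnum <- which(vapply(seq_len(nrow(df)),
                           function(i) anyNA(unlist(df[i, num])), logical(1)))
    if (length(badnum))
        stop("malformed numeric field at line ", badnum[1])
    df
}

#' Parse an HMMER per-domain table (domtblout)
#'
#' Whitespace-separated per-domain table with '#' comment lines; one row per
#' domain hit.
#'
#' @param path path to the table.
#' @return a data.frame with columns \code{target, target_len, domain_name,
#'   ievalue, ali_from, ali_to}. No data rows yields an empty table with a
#'   warning.
#' @export
readDomainTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    cols <- c("target", "target_len", "domain_name", "ievalue",
              "ali_from", "ali_to")
    if (!length(lines)) {
        warning("no domain hits in ", path)
        return(as.data.frame(stats::setNames(
            rep(list(character(0)), length(cols)), cols)))
    }
    fields <- strsplit(trimws(lines), "\\s+")
    ncols <- lengths(fields)
    if (any(ncols < 23L))
        stop("malformed domain-table line ", which(ncols < 23L)[1],
             ": expected >= 23 columns (HMMER domtblout), found ",
             ncols[ncols < 23L][1])
    # domtblout columns: 1 target, 3 tlen, 4 query(domain) name,
    # 13 i-Evalue, 18/19 ali coords
    df <- data.frame(
        target = vapply(fields, `[`, character(1), 1L),
        target_len = as.numeric(vapply(fields, `[`, character(1), 3L)),
        domain_name = vapply(fields, `[`, character(1), 4L),
        ievalue = as.numeric(vapply(fields, `[`, character(1), 13L)),
        ali_from = as.integer(vapply(fields, `[`, character(1), 18L)),
        ali_to = as.integer(vapply(fields, `[`, character(1), 19L)),
        stringsAsFactors = FALSE
    )
    df
}

#' Read spliced-junction candidates
#'
#' Accepts two dialects: 6-column BED (intron span; 0-based half-open start
#' as BED requires) and a 4-column splice-site table \code{chrom, donor,
#' acceptor, strand} as written by a spliced aligner's novel-splice-site
#' output (0-based positions of the first and last intronic nucleotide).
#' Both are converted to 1-based inclusive coordinates.
#'
#' @param path path to the junction file.
#' @param dialect \code{"auto"} (by column count), \code{"bed6"} or
#'   \code{"sites"}.
#' @return a data.frame with columns \code{seq_id, donor, acceptor, strand,
#'   read_support}; \code{donor}/\code{acceptor} are the 1-based positions of
#'   the first and last intronic nucleotide.
#' @export
readJunctions <- function(path, dialect = c("auto", "bed6", "sites")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines)) {
        warning("no junctions in ", path)
        return(data.frame(seq_id = character(0), donor = integer(0),
                          acceptor = integer(0), strand = character(0),
                          read_support = integer(0)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(fields)
    if (dialect == "auto")
        dialect <- if (all(n >= 6L)) "bed6" else "sites"
    if (dialect == "bed6") {
        if (any(n < 6L)) stop("BED6 line ", which(n < 6L)[1], " has ",
                              n[n < 6L][1], " columns")
        data.frame(
            seq_id = vapply(fields, `[`, character(1), 1L),
            donor = as.integer(vapply(fields, `[`, character(1), 2L)) + 1L,
            acceptor = as.integer(vapply(fields, `[`, character(1), 3L)),
            strand = vapply(fields, `[`, character(1), 6L),
            read_support = suppressWarnings(
                as.integer(vapply(fields, `[`, character(1), 5L))),
            stringsAsFactors = FALSE)
    } else {
        if (any(n < 4L)) stop("splice-site line ", which(n < 4L)[1], " has ",
                              n[n < 4L][1], " columns")
        data.frame(
            seq_id = vapply(fields, `[`, character(1), 1L),
            donor = as.integer(vapply(fields, `[`, character(1), 2L)) + 1L,
            acceptor = as.integer(vapply(fields, `[`, character(1), 3L)) + 1L,
            strand = vapply(fields, `[`, character(1), 4L),
            read_support = NA_integer_,
            stringsAsFactors = FALSE)
    }
}

#' Read features from GFF3
#'
#' Thin wrapper over \code{rtracklayer::import.gff3}; returns the features
#' as a \code{GRanges} with attribute columns (including \code{ID} /
#' \code{Parent}) as metadata.
#'
#' @param path path to a GFF3 file.
#' @return a \code{GRanges}.
#' @export
readFeaturesGff3 <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    rtracklayer::import.gff3(path)
}

#' Export features to GFF3
#'
#' Thin wrapper over \code{rtracklayer::export.gff3}; feature \code{GRanges}
#' carry their annotations as metadata columns.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return the path, invisibly.
#' @export
writeFeaturesGff3 <- function(gr, path, source = "intronoscope") {
    mc <- S4Vectors::mcols(gr)
    mc$source <- source
    if (is.null(mc$type)) mc$type <- "intron"
    if (is.null(mc$ID)) mc$ID <- paste0("feat", seq_along(gr))
    S4Vectors::mcols(gr) <- mc
    rtracklayer::export.gff3(gr, path)
    invisible(path)
}
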