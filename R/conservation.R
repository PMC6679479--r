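#' Call positionally homologous introns across orthologs
#'
#' Maps every intron to the protein-alignment column of the codon it
#' interrupts and groups introns that share (column, phase): only introns at
#' the same relative coding position and phase are considered homologous.
#' Introns whose groups sit in adjacent alignment columns at the same phase
#' are cross-flagged \code{possible_sliding} (reported, never merged).
#'
#' @param proteinAlignment named character vector of aligned amino-acid
#'   sequences (gap \code{"-"}), one per species, equal lengths.
#' @param intronSites data.frame with columns \code{species}, \code{gene}
#'   (optional), \code{cds_upstream} - the number of coding nucleotides
#'   upstream of the intron in that species' CDS.
#' @return list with \code{sites} (the input plus \code{phase},
#'   \code{codon_index}, \code{aln_column}, \code{group},
#'   \code{possible_sliding}) and \code{groups} (data.frame \code{group},
#'   \code{aln_column}, \code{phase}, \code{n_species}, \code{species}).
#' @export
callHomologousIntrons <- function(proteinAlignment, intronSites) {
    stopifnot(is.character(proteinAlignment), !is.null(names(proteinAlignment)))
    if (length(unique(nchar(proteinAlignment))) != 1L)
        stop("aligned sequences have unequal lengths")
    need <- c("species", "cds_upstream")
    stopifnot(all(need %in% names(intronSites)))
    sites <- intronSites
    n <- nrow(sites)
    sites$phase <- sites$cds_upstream %% 3L
    # codon interrupted by the intron (phase 0: the codon following the site)
    sites$codon_index <- sites$cds_upstream %/% 3L + 1L
    sites$aln_column <- NA_integer_
    for (r in seq_len(n)) {
        sp <- sites$species[r]
        if (!sp %in% names(proteinAlignment))
            stop("species '", sp, "' absent from the alignment")
        aa <- chars(proteinAlignment[[sp]])
        nongap <- which(aa != "-")
        if (sites$codon_index[r] > length(nongap))
            stop("intron site beyond CDS length for species '", sp, "'")
        sites$aln_column[r] <- nongap[sites$codon_index[r]]
    }
    key <- paste(sites$aln_column, sites$phase, sep = "/")
    ukey <- sort(unique(key))
    sites$group <- match(key, ukey)
    grp <- do.call(rbind, lapply(seq_along(ukey), function(g) {
        idx <- which(sites$group == g)
        data.frame(group = g,
                   aln_column = sites$aln_column[idx[1]],
                   phase = sites$phase[idx[1]],
                   n_species = length(unique(sites$species[idx])),
                   species = paste(sort(unique(sites$species[idx])),
                                   collapse = ","))
    }))
    sliding <- vapply(seq_len(nrow(grp)), function(g)
        any(abs(grp$aln_column[-g] - grp$aln_column[g]) == 1L &
            grp$phase[-g] == grp$phase[g]), logical(1))
    grp$possible_sliding <- sliding
    sites$possible_sliding <- grp$possible_sliding[sites$group]
    list(sites = sites, groups = grp)
}

#' Proto-splice-site conformance of exonic flanks
#'
#' Counts agreement of the exonic sequence around an intron insertion site
#' with the proto-splice-site consensus \code{(A/C)AG|G}: three exonic
#' nucleotides before the site (M, A, G) and one after (G).
#'
#' @param exonic5 exonic flank 5' of the intron (its last 3 nt are scored).
#' @param exonic3 exonic flank 3' of the intron (its first nt is scored).
#' @return list \code{matches} (integer 0-4), \code{n_scored},
#'   \code{truncated} (\code{TRUE} when fewer than 4 positions were
#'   available).
#' @examples
#' protoSpliceCheck("CAG", "G")$matches   # 4
#' @export
protoSpliceCheck <- function(exonic5, exonic3) {
    u5 <- chars(toupper(exonic5))
    u3 <- chars(toupper(exonic3))
    last3 <- utils::tail(u5, 3)
    scored <- 0L; matches <- 0L
    cons5 <- c("M", "A", "G")
    offset <- 3L - length(last3)
    for (j in seq_along(last3)) {
        scored <- scored + 1L
        if (last3[j] %in% IUPAC_CLASSES[[cons5[j + offset]]])
            matches <- matches + 1L
    }
    if (length(u3) >= 1L) {
        scored <- scored + 1L
        if (u3[1] == "G") matches <- matches + 1L
    }
    list(matches = matches, n_scored = scored, truncated = scored < 4L)
}

#' Per-clade intron presence summary
#'
#' For a homology group, tallies per clade the number of species carrying
#' the intron (numerator) against the number of species sampled
#' (denominator). Species whose gene could not be found are excluded from
#' the denominator only when listed in \code{geneNotFound}. Clades with no
#' sampled species are omitted.
#'
#' @param speciesWithIntron character vector of species carrying the intron.
#' @param speciesClade named character vector mapping every sampled species
#'   to its clade.
#' @param geneNotFound species excluded from denominators.
#' @return data.frame \code{clade}, \code{n_with_intron}, \code{n_sampled}.
#' @export
cladePresenceSummary <- function(speciesWithIntron, speciesClade,
                                 geneNotFound = character(0)) {
    unmapped <- setdiff(speciesWithIntron, names(speciesClade))
    if (length(unmapped))
        stop("species without clade assignment: ",
             paste(unmapped, collapse = ", "))
    sampled <- setdiff(names(speciesClade), geneNotFound)
    clades <- unique(unname(speciesClade[sampled]))
    out <- do.call(rbind, lapply(clades, function(cl) {
        sp <- sampled[speciesClade[sampled] == cl]
        data.frame(clade = cl,
                   n_with_intron = sum(sp %in% speciesWithIntron),
                   n_sampled = length(sp))
    }))
    out[out$n_sampled > 0L, , drop = FALSE]
}
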