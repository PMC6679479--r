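#' Conserved-domain filter for protein candidates
#'
#' A candidate spliceosomal protein is retained only when it carries all of
#' the expected conserved domains, or all but one when
#' \code{allowMissing = 1} (retained with a flag).
#'
#' @param domainsFound character vector of domain names found on the
#'   candidate.
#' @param requiredDomains non-empty character vector of expected domains.
#' @param allowMissing 0 or 1 missing domains tolerated.
#' @return list \code{retain} (logical), \code{missing} (character vector),
#'   \code{flagged} (retained despite a missing domain).
#' @export
domainFilter <- function(domainsFound, requiredDomains, allowMissing = 0L) {
    stopifnot(length(requiredDomains) > 0L, allowMissing %in% 0:1)
    missing <- setdiff(requiredDomains, domainsFound)
    retain <- length(missing) <= allowMissing
    list(retain = retain, missing = missing,
         flagged = retain && length(missing) > 0L)
}

#' Reciprocal-hit acceptance rule
#'
#' A candidate is "reciprocal" when one of the top 10 hits of its BLASTp
#' search against the reference proteome matches the original query and the
#' candidate is of similar size: within +/- 50 aa for queries under 300 aa,
#' or within +/- 20 percent for queries of 300 aa and larger (tolerances
#' inclusive; the under-300 branch applies to lengths up to 299).
#'
#' @param hits data.frame of BLASTp rows in file (rank) order, with a
#'   \code{subject} column (as from [readBlastTab()]).
#' @param queryId identifier of the original PSSM-forming query; an optional
#'   \code{aliases} vector extends the identity test.
#' @param queryLen,candidateLen protein lengths in aa.
#' @param aliases additional accepted subject identifiers.
#' @return logical.
#' @export
reciprocalCheck <- function(hits, queryId, queryLen, candidateLen,
                            aliases = character(0)) {
    if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
    top <- utils::head(hits$subject, 10L)
    if (!any(top %in% c(queryId, aliases))) return(FALSE)
    tol <- if (queryLen < 300) 50 else 0.20 * queryLen
    abs(candidateLen - queryLen) <= tol
}

#' Retention-pattern analysis of a presence matrix
#'
#' Summaries of which spliceosomal proteins are retained where: per-organism
#' totals (with LSm/Sm-family proteins optionally counted as a deduplicated
#' block), pairwise containment fractions
#' \eqn{|present(A) \cap present(B)| / |present(A)|} for every ordered
#' organism pair (the nestedness statistic), and Venn partition counts for
#' declared groupings of 2 or 3 sets, where each set is an organism or the
#' union/intersection of several.
#'
#' @param presence logical matrix, proteins x organisms (rownames are
#'   protein identifiers, colnames organisms), complete (no NA).
#' @param groupings optional named list of Venn groupings; each grouping is
#'   a list of 2 or 3 sets, each set a list with \code{name},
#'   \code{organisms} (character), and \code{mode} (\code{"union"} or
#'   \code{"intersection"}, default union).
#' @param lsmFamily optional named character vector mapping LSm/Sm-block
#'   protein rownames to family identifiers; per organism the block
#'   contributes the number of distinct families present.
#' @return list with \code{totals} (data.frame organism/n_present and, with
#'   \code{lsmFamily}, \code{n_lsm_families}), \code{containment}
#'   (data.frame from/to/fraction), and \code{venn} (named list of
#'   data.frames region/count).
#' @export
retentionAnalysis <- function(presence, groupings = NULL, lsmFamily = NULL) {
    stopifnot(is.matrix(presence), !anyNA(presence),
              !is.null(colnames(presence)), !is.null(rownames(presence)))
    mode(presence) <- "logical"
    orgs <- colnames(presence)
    sets <- lapply(orgs, function(o) rownames(presence)[presence[, o]])
    names(sets) <- orgs
    totals <- data.frame(organism = orgs,
                         n_present = vapply(sets, length, integer(1)))
    if (!is.null(lsmFamily)) {
        totals$n_lsm_families <- vapply(orgs, function(o) {
            p <- intersect(sets[[o]], names(lsmFamily))
            length(unique(lsmFamily[p]))
        }, integer(1))
    }
    cont <- do.call(rbind, lapply(orgs, function(a) do.call(rbind, lapply(
        setdiff(orgs, a), function(b) data.frame(
            from = a, to = b,
            fraction = if (length(sets[[a]]))
                length(intersect(sets[[a]], sets[[b]])) / length(sets[[a]])
            else NA_real_)))))
    venn <- NULL
    if (!is.null(groupings)) {
        resolveSet <- function(st) {
            if (is.character(st)) st <- list(organisms = st)
            md <- if (is.null(st$mode)) "union" else st$mode
            miss <- setdiff(st$organisms, orgs)
            if (length(miss)) stop("organism absent from matrix: ",
                                   paste(miss, collapse = ", "))
            members <- sets[st$organisms]
            if (md == "union") Reduce(union, members)
            else Reduce(intersect, members)
        }
        venn <- lapply(groupings, function(gr) {
            ss <- lapply(gr, resolveSet)
            nm <- vapply(seq_along(gr), function(i) {
                g <- gr[[i]]
                if (is.character(g)) paste(g, collapse = "+")
                else if (!is.null(g$name)) g$name
                else paste(g$organisms, collapse = "+")
            }, character(1))
            ns <- length(ss)
            stopifnot(ns %in% 2:3)
            uni <- Reduce(union, ss)
            member <- vapply(ss, function(x) uni %in% x,
                             logical(length(uni)))
            if (length(uni) == 1L) member <- matrix(member, nrow = 1)
            patterns <- apply(member, 1, function(b)
                paste(ifelse(b, "1", "0"), collapse = ""))
            allPat <- apply(expand.grid(rep(list(c("0", "1")), ns)), 1,
                            paste, collapse = "")
            allPat <- setdiff(allPat, paste(rep("0", ns), collapse = ""))
            counts <- vapply(allPat, function(p) sum(patterns == p),
                             integer(1))
            region <- vapply(allPat, function(p) {
                b <- chars(p) == "1"
                paste0(paste(nm[b], collapse = "&"),
                       if (any(!b)) paste0(" only") else "")
            }, character(1))
            data.frame(pattern = allPat, region = region,
                       count = unname(counts))
        })
    }
    list(totals = totals, containment = cont, venn = venn)
}
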