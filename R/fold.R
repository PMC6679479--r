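#' @useDynLib intronoscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

FOLD_INF <- 1e8          # anything above this is "no structure"
FOLD_EPS <- 1e-6
MIN_HAIRPIN <- 3L
MAX_INTERNAL <- 30L

# Watson-Crick nearest-neighbor stack parameters (dG37 / dH, kcal/mol),
# indexed by (outer pair, inner pair). Stacks containing a G:U wobble use a
# single simplified value class (see vignette). dS is derived as
# (dH - dG37)/310.15 and dG(T) = dH - (T + 273.15) * dS.
PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

wcStackTable <- local({
    # entries as 5'-XY-3'/3'-X'Y'-5': outer pair X:X', inner pair Y:Y'
    raw <- list(
        c("AU", "AU", -0.93, -6.82),
        c("AU", "UA", -1.10, -9.38),
        c("UA", "AU", -1.33, -7.69),
        c("CG", "UA", -2.08, -10.48),
        c("CG", "AU", -2.11, -10.44),
        c("GC", "UA", -2.24, -11.40),
        c("GC", "AU", -2.35, -12.44),
        c("CG", "GC", -2.36, -10.64),
        c("GC", "GC", -3.26, -13.39),
        c("GC", "CG", -3.42, -14.88)
    )
    g <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
    h <- g
    rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    for (e in raw) {
        g[e[1], e[2]] <- as.numeric(e[3]); h[e[1], e[2]] <- as.numeric(e[4])
        g[rev2(e[2]), rev2(e[1])] <- as.numeric(e[3])
        h[rev2(e[2]), rev2(e[1])] <- as.numeric(e[4])
    }
    wob <- grepl("GU|UG", PAIR_TYPES)
    for (p1 in PAIR_TYPES) for (p2 in PAIR_TYPES) {
        nw <- (p1 %in% c("GU", "UG")) + (p2 %in% c("GU", "UG"))
        if (nw == 1L) { g[p1, p2] <- -1.00; h[p1, p2] <- -7.00 }
        if (nw == 2L) { g[p1, p2] <- -0.50; h[p1, p2] <- -6.00 }
    }
    list(dG37 = g, dH = h)
})

#' Energy-model parameters at a folding temperature
#'
#' Resolves the package's nearest-neighbor parameter table at a temperature:
#' stack free energies via \eqn{\Delta G(T) = \Delta H - T_K \Delta S}, and
#' purely entropic linear loop penalties (hairpin, bulge, internal,
#' multiloop) scaled by \eqn{T_K / 310.15}.
#'
#' @param temperature folding temperature in degrees Celsius (0-100).
#' @param maxLen longest loop size for which penalties are tabulated.
#' @return a list with \code{stackG} (7x7 matrix indexed by pair type, row
#'   and column 1 unused), \code{hairpinG}, \code{bulgeG}, \code{internalG}
#'   (penalty by loop size, index = size + 1 so index 1 is size 0),
#'   \code{multiA}, \code{multiB}, \code{multiC}.
#' @export
energyParams <- function(temperature = 37, maxLen = 400L) {
    stopifnot(temperature >= 0, temperature <= 100)
    tk <- temperature + 273.15
    scale <- tk / 310.15
    dS <- (wcStackTable$dH - wcStackTable$dG37) / 310.15
    g <- wcStackTable$dH - tk * dS
    stackG <- matrix(FOLD_INF * 10, 7, 7)
    stackG[2:7, 2:7] <- g
    sizes <- 0:maxLen
    hairpinG <- ifelse(sizes >= MIN_HAIRPIN,
                       (5.0 + 0.15 * (sizes - 3)) * scale, FOLD_INF * 10)
    bulgeG <- ifelse(sizes >= 1, (3.5 + 0.30 * sizes) * scale, FOLD_INF * 10)
    internalG <- ifelse(sizes >= 2, (2.0 + 0.25 * sizes) * scale,
                        FOLD_INF * 10)
    list(stackG = stackG, hairpinG = hairpinG, bulgeG = bulgeG,
         internalG = internalG,
         multiA = 3.4 * scale, multiB = 0.4 * scale, multiC = 0.1 * scale,
         temperature = temperature)
}

# encode a DNA/RNA string as integers A=1 C=2 G=3 U/T=4 N=0
encodeRna <- function(seq) {
    ch <- chars(toupper(seq))
    ch[ch == "T"] <- "U"
    code <- match(ch, c("A", "C", "G", "U"))
    code[is.na(code)] <- 0L
    code
}

pairTypeOf <- function(a, b) {
    match(paste0(a, b), PAIR_TYPES, nomatch = 0L)
}

#' Fold a sequence under single-strandedness constraints
#'
#' Minimum-free-energy pseudoknot-free secondary structure prediction under
#' the package's nearest-neighbor model, with selected positions forced
#' single-stranded (the splice-site masking used for intron folding) and
#' deterministic enumeration of near-optimal structures. The first returned
#' structure attains the MFE; up to \code{nBest} distinct structures within
#' \code{band} kcal/mol of the MFE are returned, sorted by energy with ties
#' broken by lexicographically smallest dot-bracket.
#'
#' Pairs are restricted to AU/UA/GC/CG/GU/UG, hairpin loops have at least 3
#' unpaired nucleotides, interior loops are capped at 30 unpaired
#' nucleotides total, and there are no dangle or coaxial terms. \code{T} is
#' treated as \code{U}. If every position is constrained (or nothing can
#' pair) the single all-dot structure with energy 0 is returned.
#'
#' @param seq a single DNA or RNA sequence string.
#' @param unpaired integer vector of 1-based positions forced
#'   single-stranded.
#' @param temperature folding temperature in degrees Celsius.
#' @param nBest maximum number of structures to return.
#' @param band suboptimal energy band in kcal/mol.
#' @param maxStructures cap on enumerated structures before deduplication.
#' @return a list of [SecondaryStructure-class] objects, energy-sorted.
#' @examples
#' foldConstrained("GGGGAAAACCCC")[[1]]
#' @export
foldConstrained <- function(seq, unpaired = integer(0), temperature = 37,
                            nBest = 3L, band = 2.0, maxStructures = 400L) {
    n <- nchar(seq)
    stopifnot(n >= 1L)
    if (length(unpaired)) {
        unpaired <- as.integer(sort(unique(unpaired)))
        if (any(unpaired < 1L) || any(unpaired > n))
            stop("constraint position outside the sequence")
    }
    par <- energyParams(temperature, maxLen = max(n, 40L))
    s <- encodeRna(seq)
    force <- rep(FALSE, n); force[unpaired] <- TRUE
    mats <- .foldFill(s, force, par$stackG, par$hairpinG, par$bulgeG,
                      par$internalG, par$multiA, par$multiB, par$multiC,
                      MIN_HAIRPIN, MAX_INTERNAL)
    res <- if (nBest == 1L)       # MFE only: fast greedy traceback
        list(tracebackMFE(s, mats, par))
    else enumerateSubopt(s, mats, par, band = band,
                         maxStructures = maxStructures)
    rna <- paste(c("N", "A", "C", "G", "U")[s + 1L], collapse = "")
    db <- vapply(res, function(r) pairsToDotBracket(r$pairs, n), character(1))
    keep <- !duplicated(db)
    res <- res[keep]; db <- db[keep]
    en <- vapply(res, `[[`, numeric(1), "energy")
    o <- order(round(en, 6), db)
    res <- res[o][seq_len(min(nBest, length(res)))]
    db <- db[o][seq_len(length(res))]
    lapply(seq_along(res), function(k) {
        pr <- res[[k]]$pairs
        methods::new("SecondaryStructure", seq = rna, dotbracket = db[k],
                     energy = res[[k]]$energy,
                     pairs = if (is.null(pr)) matrix(integer(0), 0, 2) else pr,
                     unpaired = unpaired, temperature = temperature)
    })
}

# greedy traceback of one MFE structure: first choice meeting the bound
tracebackMFE <- function(s, mats, par) {
    n <- length(s)
    V <- mats$V; WM <- mats$WM; W <- mats$W
    A <- par$multiA; B <- par$multiB; C <- par$multiC
    bases <- c("A", "C", "G", "U")
    pairs <- list()
    goals <- list(list(t = "W", j = n))
    while (length(goals)) {
        g <- goals[[1]]; goals <- goals[-1]
        if (g$t == "W") {
            j <- g$j
            while (j > 0L) {
                if (abs(W[j + 1L] - W[j]) < FOLD_EPS) { j <- j - 1L; next }
                found <- FALSE
                for (i in seq_len(j)) {
                    if (V[i + 1L, j + 1L] < FOLD_INF &&
                        abs(W[i] + V[i + 1L, j + 1L] - W[j + 1L]) < FOLD_EPS) {
                        pairs[[length(pairs) + 1L]] <- c(i, j)
                        goals <- c(list(list(t = "V", i = i, j = j)), goals)
                        j <- i - 1L
                        found <- TRUE
                        break
                    }
                }
                if (!found) stop("traceback failed at W(", j, ")")
            }
        } else if (g$t == "V") {
            i <- g$i; j <- g$j
            Bv <- V[i + 1L, j + 1L]
            L <- j - i - 1L
            if (L >= MIN_HAIRPIN && abs(par$hairpinG[L + 1L] - Bv) < FOLD_EPS)
                next
            pt <- pairTypeOf(bases[s[i]], bases[s[j]])
            done <- FALSE
            for (p in (i + 1L):(j - 1L)) {
                l1 <- p - i - 1L
                if (l1 > MAX_INTERNAL || p + 1L > j - 1L) break
                for (q in (j - 1L):(p + 1L)) {
                    l2 <- j - q - 1L
                    if (l1 + l2 > MAX_INTERNAL) break
                    if (V[p + 1L, q + 1L] >= FOLD_INF) next
                    pt2 <- pairTypeOf(bases[s[p]], bases[s[q]])
                    cost <- if (l1 == 0L && l2 == 0L)
                        par$stackG[pt + 1L, pt2 + 1L]
                    else if (l1 == 0L || l2 == 0L) par$bulgeG[l1 + l2 + 1L]
                    else par$internalG[l1 + l2 + 1L]
                    if (abs(cost + V[p + 1L, q + 1L] - Bv) < FOLD_EPS) {
                        pairs[[length(pairs) + 1L]] <- c(p, q)
                        goals <- c(list(list(t = "V", i = p, j = q)), goals)
                        done <- TRUE; break
                    }
                }
                if (done) break
            }
            if (done) next
            # multiloop split
            for (k in (i + 2L):(j - 3L)) {
                if (k < i + 2L || k > j - 3L) break
                if (WM[i + 2L, k + 1L] >= FOLD_INF ||
                    WM[k + 2L, j] >= FOLD_INF) next
                if (abs(A + B + WM[i + 2L, k + 1L] + WM[k + 2L, j] - Bv) <
                    FOLD_EPS) {
                    goals <- c(list(list(t = "M", i = i + 1L, j = k),
                                    list(t = "M", i = k + 1L, j = j - 1L)),
                               goals)
                    done <- TRUE; break
                }
            }
            if (!done) stop("traceback failed at V(", i, ",", j, ")")
        } else {
            i <- g$i; j <- g$j
            Bm <- WM[i + 1L, j + 1L]
            if (j - 1L >= i && WM[i + 1L, j] < FOLD_INF &&
                abs(WM[i + 1L, j] + C - Bm) < FOLD_EPS) {
                goals <- c(list(list(t = "M", i = i, j = j - 1L)), goals)
                next
            }
            done <- FALSE
            for (p in i:(j - 1L)) {
                if (V[p + 1L, j + 1L] >= FOLD_INF) next
                if (abs(V[p + 1L, j + 1L] + B + C * (p - i) - Bm) < FOLD_EPS) {
                    pairs[[length(pairs) + 1L]] <- c(p, j)
                    goals <- c(list(list(t = "V", i = p, j = j)), goals)
                    done <- TRUE; break
                }
                if (p - 1L >= i && WM[i + 1L, p] < FOLD_INF &&
                    abs(V[p + 1L, j + 1L] + B + WM[i + 1L, p] - Bm) <
                    FOLD_EPS) {
                    pairs[[length(pairs) + 1L]] <- c(p, j)
                    goals <- c(list(list(t = "V", i = p, j = j),
                                    list(t = "M", i = i, j = p - 1L)), goals)
                    done <- TRUE; break
                }
            }
            if (!done) stop("traceback failed at WM(", i, ",", j, ")")
        }
    }
    pr <- if (length(pairs)) do.call(rbind, pairs) else
        matrix(integer(0), 0, 2)
    if (nrow(pr)) {
        pr <- pr[order(pr[, 1]), , drop = FALSE]
        storage.mode(pr) <- "integer"
    }
    list(pairs = pr, energy = mats$W[n + 1L])
}

# bounded best-first/greedy DFS over the DP recurrences; returns
# list of list(pairs = matrix, energy = numeric) within `band` of the MFE
enumerateSubopt <- function(s, mats, par, band, maxStructures) {
    n <- length(s)
    Vm <- function(i, j) mats$V[i + 1L, j + 1L]
    WMm <- function(i, j) mats$WM[i + 1L, j + 1L]
    Wv <- function(j) mats$W[j + 1L]
    A <- par$multiA; B <- par$multiB; C <- par$multiC
    collector <- new.env(parent = emptyenv())
    collector$out <- vector("list", 0L)
    goalBound <- function(g)
        switch(g$t, W = Wv(g$j), V = Vm(g$i, g$j), M = WMm(g$i, g$j))

    rec <- function(goals, pairs, fixed, slack) {
        if (length(collector$out) >= maxStructures) return(invisible())
        if (!length(goals)) {
            collector$out[[length(collector$out) + 1L]] <-
                list(pairs = pairs, energy = fixed)
            return(invisible())
        }
        g <- goals[[1]]; rest <- goals[-1]
        Bg <- goalBound(g)
        ch <- list()   # each: list(delta, cost, children, newPairs)
        add <- function(cost, children, newPairs = NULL) {
            cb <- sum(vapply(children, goalBound, numeric(1)))
            delta <- cost + cb - Bg
            if (delta <= slack + FOLD_EPS)
                ch[[length(ch) + 1L]] <<- list(delta = delta, cost = cost,
                                               children = children,
                                               newPairs = newPairs)
        }
        if (g$t == "W") {
            j <- g$j
            if (j == 0L) { rec(rest, pairs, fixed, slack); return(invisible()) }
            add(0, list(list(t = "W", j = j - 1L)))
            for (i in seq_len(j))
                if (Vm(i, j) < FOLD_INF)
                    add(0, list(list(t = "W", j = i - 1L),
                                list(t = "V", i = i, j = j)), c(i, j))
        } else if (g$t == "V") {
            i <- g$i; j <- g$j; L <- j - i - 1L
            if (L >= MIN_HAIRPIN) add(par$hairpinG[L + 1L], list())
            pt <- pairTypeOf(c("A","C","G","U")[s[i]], c("A","C","G","U")[s[j]])
            for (p in (i + 1L):(j - 1L)) {
                l1 <- p - i - 1L
                if (l1 > MAX_INTERNAL) break
                if (p + 1L > j - 1L) break
                for (q in (j - 1L):(p + 1L)) {
                    l2 <- j - q - 1L
                    if (l1 + l2 > MAX_INTERNAL) break
                    if (Vm(p, q) >= FOLD_INF) next
                    pt2 <- pairTypeOf(c("A","C","G","U")[s[p]],
                                      c("A","C","G","U")[s[q]])
                    cost <- if (l1 == 0L && l2 == 0L)
                        par$stackG[pt + 1L, pt2 + 1L]
                    else if (l1 == 0L || l2 == 0L) par$bulgeG[l1 + l2 + 1L]
                    else par$internalG[l1 + l2 + 1L]
                    add(cost, list(list(t = "V", i = p, j = q)), c(p, q))
                }
            }
            if (j - 1L > i + 1L)
                for (q in (j - 1L):(i + 3L)) {
                    trail <- C * (j - 1L - q)
                    for (p in (i + 2L):(q - 1L)) {
                        if (Vm(p, q) >= FOLD_INF) next
                        if (WMm(i + 1L, p - 1L) >= FOLD_INF) next
                        add(A + 2 * B + trail,
                            list(list(t = "V", i = p, j = q),
                                 list(t = "M", i = i + 1L, j = p - 1L)),
                            c(p, q))
                    }
                }
        } else {                                   # WM
            i <- g$i; j <- g$j
            if (j - 1L >= i && WMm(i, j - 1L) < FOLD_INF)
                add(C, list(list(t = "M", i = i, j = j - 1L)))
            for (p in i:(j - 1L)) {
                if (Vm(p, j) >= FOLD_INF) next
                add(B + C * (p - i), list(list(t = "V", i = p, j = j)),
                    c(p, j))
                if (p - 1L >= i && WMm(i, p - 1L) < FOLD_INF)
                    add(B, list(list(t = "V", i = p, j = j),
                                list(t = "M", i = i, j = p - 1L)), c(p, j))
            }
        }
        if (!length(ch)) return(invisible())
        deltas <- vapply(ch, `[[`, numeric(1), "delta")
        for (k in order(deltas)) {
            cc <- ch[[k]]
            np <- if (is.null(cc$newPairs)) pairs else
                rbind(pairs, cc$newPairs)
            rec(c(cc$children, rest), np, fixed + cc$cost, slack - cc$delta)
            if (length(collector$out) >= maxStructures) return(invisible())
        }
        invisible()
    }
    rec(list(list(t = "W", j = n)), matrix(integer(0), 0, 2), 0, band)
    lapply(collector$out, function(r) {
        pr <- r$pairs
        if (nrow(pr)) {
            pr <- pr[order(pr[, 1]), , drop = FALSE]
            storage.mode(pr) <- "integer"
        }
        list(pairs = pr, energy = r$energy)
    })
}

# dot-bracket string from a pair matrix
pairsToDotBracket <- function(pairs, n) {
    db <- rep(".", n)
    if (!is.null(pairs) && nrow(pairs)) {
        db[pairs[, 1]] <- "("
        db[pairs[, 2]] <- ")"
    }
    paste(db, collapse = "")
}

#' Parse a dot-bracket string into a pair matrix
#'
#' @param db dot-bracket string over \code{". ( )"}.
#' @return integer matrix with columns \code{i}, \code{j} (1-based, i < j),
#'   sorted by \code{i}.
#' @export
dotBracketPairs <- function(db) {
    ch <- chars(db)
    stack <- integer(0)
    out <- list()
    for (k in seq_along(ch)) {
        if (ch[k] == "(") stack <- c(stack, k)
        else if (ch[k] == ")") {
            if (!length(stack)) stop("unbalanced ')' at position ", k)
            out[[length(out) + 1L]] <- c(stack[length(stack)], k)
            stack <- stack[-length(stack)]
        } else if (ch[k] != ".") stop("invalid character '", ch[k], "'")
    }
    if (length(stack)) stop("unbalanced '(' at position ", stack[1])
    if (!length(out)) return(matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("i", "j"))))
    m <- do.call(rbind, out)
    m <- m[order(m[, 1]), , drop = FALSE]
    dimnames(m) <- list(NULL, c("i", "j"))
    storage.mode(m) <- "integer"
    m
}

#' Score a structure by loop decomposition
#'
#' Free energy of an explicit pseudoknot-free structure under exactly the
#' parameter table used by [foldConstrained()]: the structure is decomposed
#' into its loops (stacks, hairpins, bulges, internal loops, multiloops;
#' external bases are free) and each is scored. This is the scoring function
#' the exhaustive reference folder uses.
#'
#' @param seq the sequence (DNA or RNA).
#' @param pairs two-column pair matrix (1-based) or a dot-bracket string.
#' @param temperature degrees Celsius.
#' @return energy in kcal/mol.
#' @export
scoreStructure <- function(seq, pairs, temperature = 37) {
    if (is.character(pairs)) pairs <- dotBracketPairs(pairs)
    n <- nchar(seq)
    par <- energyParams(temperature, maxLen = max(n, 40L))
    if (is.null(pairs) || nrow(pairs) == 0) return(0)
    s <- encodeRna(seq)
    bases <- c("A", "C", "G", "U")
    partner <- integer(n)
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    total <- 0
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (s[i] == 0L || s[j] == 0L || pairTypeOf(bases[s[i]], bases[s[j]]) == 0L)
            stop("non-canonical pair ", i, "-", j)
        # children: directly enclosed pairs
        children <- list()
        k <- i + 1L
        unpairedIn <- 0L
        while (k < j) {
            if (partner[k] > k && partner[k] < j) {
                children[[length(children) + 1L]] <- c(k, partner[k])
                k <- partner[k] + 1L
            } else if (partner[k] != 0L && (partner[k] < i || partner[k] > j)) {
                stop("pseudoknotted pair at ", k)
            } else {
                unpairedIn <- unpairedIn + 1L
                k <- k + 1L
            }
        }
        nc <- length(children)
        if (nc == 0L) {
            L <- j - i - 1L
            if (L < MIN_HAIRPIN) stop("hairpin loop shorter than ",
                                      MIN_HAIRPIN, " nt at pair ", i, "-", j)
            total <- total + par$hairpinG[L + 1L]
        } else if (nc == 1L) {
            p <- children[[1]][1]; q <- children[[1]][2]
            l1 <- p - i - 1L; l2 <- j - q - 1L
            pt <- pairTypeOf(bases[s[i]], bases[s[j]])
            pt2 <- pairTypeOf(bases[s[p]], bases[s[q]])
            total <- total + if (l1 == 0L && l2 == 0L)
                par$stackG[pt + 1L, pt2 + 1L]
            else if (l1 == 0L || l2 == 0L) par$bulgeG[l1 + l2 + 1L]
            else par$internalG[l1 + l2 + 1L]
        } else {
            total <- total + par$multiA + par$multiB * (nc + 1L) +
                par$multiC * unpairedIn
        }
    }
    total
}

#' Exhaustive reference folder
#'
#' Enumerates every pseudoknot-free structure of a short sequence (respecting
#' pairing rules, the minimum hairpin loop and single-strandedness
#' constraints), scores each with [scoreStructure()], and returns the
#' minimum. Independent of the dynamic-programming engine; intended for
#' validating [foldConstrained()] on sequences of up to ~18 nt.
#'
#' @inheritParams foldConstrained
#' @return list with \code{mfe} (numeric), \code{pairs} (pair matrix of one
#'   optimal structure), and \code{nStructures} (count enumerated).
#' @export
foldExhaustive <- function(seq, unpaired = integer(0), temperature = 37) {
    n <- nchar(seq)
    s <- encodeRna(seq)
    bases <- c("A", "C", "G", "U")
    force <- rep(FALSE, n); force[unpaired] <- TRUE
    canP <- function(i, j) {
        !force[i] && !force[j] && s[i] != 0L && s[j] != 0L &&
            pairTypeOf(bases[s[i]], bases[s[j]]) != 0L &&
            j - i - 1L >= MIN_HAIRPIN
    }
    # all pair-lists for interval [i, j]
    enum <- function(i, j) {
        if (i >= j) return(list(list()))
        out <- lapply(enum(i + 1L, j), identity)       # i unpaired
        for (k in (i + 1L):j) {
            if (!canP(i, k)) next
            inner <- enum(i + 1L, k - 1L)
            outer <- enum(k + 1L, j)
            for (a in inner) for (b in outer)
                out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
        }
        out
    }
    structs <- enum(1L, n)
    best <- 0; bestPairs <- matrix(integer(0), 0, 2)
    for (st in structs) {
        pr <- if (length(st)) do.call(rbind, st) else matrix(integer(0), 0, 2)
        e <- scoreStructure(seq, pr, temperature)
        if (e < best - FOLD_EPS) { best <- e; bestPairs <- pr }
    }
    list(mfe = best, pairs = bestPairs, nStructures = length(structs))
}

#' Splice-site spatial distance of a folded intron
#'
#' The donor-to-acceptor path length after excluding every nucleotide
#' sequestered in a stem-loop element: hairpin elements are the maximal
#' structural elements closed by an outermost (top-level) base pair, and
#' every nucleotide enclosed by (and including) such a pair is removed from
#' the path. With no pairing the spatial distance equals the intron length.
#'
#' @param structure a [SecondaryStructure-class] or a dot-bracket string.
#' @return list with \code{intron_length}, \code{spatial_distance}, and
#'   \code{hairpins} (two-column matrix of outermost pair coordinates).
#' @export
spatialDistance <- function(structure) {
    db <- if (methods::is(structure, "SecondaryStructure"))
        structure@dotbracket else structure
    n <- nchar(db)
    pairs <- dotBracketPairs(db)
    hairpins <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    if (nrow(pairs)) {
        # top-level pairs: not enclosed by any other pair
        top <- vapply(seq_len(nrow(pairs)), function(r) {
            i <- pairs[r, 1]; j <- pairs[r, 2]
            !any(pairs[, 1] < i & pairs[, 2] > j)
        }, logical(1))
        hairpins <- pairs[top, , drop = FALSE]
    }
    span <- if (nrow(hairpins)) sum(hairpins[, 2] - hairpins[, 1] + 1L) else 0L
    list(intron_length = n, spatial_distance = n - span, hairpins = hairpins)
}
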