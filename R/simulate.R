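# sample a degenerate IUPAC string into a concrete sequence, each degenerate
# position uniform over its class
sampleFromPattern <- function(pattern) {
    paste(vapply(chars(pattern), function(code) {
        cls <- IUPAC_CLASSES[[code]]
        if (length(cls) == 1L) cls else sample(cls, 1L)
    }, character(1)), collapse = "")
}

randomSeq <- function(n, gc = 0.45) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# random stop-free ORF under the chosen code: ATG + codons + stop
randomOrf <- function(nCodons, code = "ciliate") {
    stops <- if (code == "ciliate") "TGA" else c("TAA", "TAG", "TGA")
    all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
    ok <- setdiff(all3, stops)
    paste0("ATG", paste(sample(ok, nCodons - 2L, replace = TRUE),
                        collapse = ""), sample(stops, 1L))
}

# build one intron: consensus-sampled donor and fused BP+acceptor, random
# interior; guarantees ORF disruption (frameshift or in-frame TGA) and,
# when structured, an interior inverted repeat placing the folded spatial
# distance in the target band
buildIntron <- function(len, phase, structured, band, fivePat, bpPat,
                        temperature, gc, maxTries = 40L) {
    d <- sampleFromPattern(fivePat)
    a <- sampleFromPattern(bpPat)
    nd <- nchar(d); na <- nchar(a)
    interiorLen <- len - nd - na
    stopifnot(interiorLen >= 8L)
    for (try in seq_len(maxTries)) {
        if (structured) {
            spanTarget <- len - round(mean(band))
            loopLen <- if (spanTarget %% 2L == 0L) 4L else 5L
            sPairs <- (spanTarget - loopLen) %/% 2L
            if (sPairs < 4L || spanTarget + 2L > interiorLen) stop(
                "intron length ", len,
                " too short for the requested spatial-distance band")
            side <- sample(c("G", "C", "A", "T"), sPairs, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1))
            hp <- paste0(paste(side, collapse = ""),
                         randomSeq(loopLen, gc = 0.2),
                         paste(rev(unname(COMPLEMENT[side])), collapse = ""))
            pad <- interiorLen - nchar(hp)
            left <- sample.int(pad + 1L, 1L) - 1L
            interior <- paste0(randomSeq(left, gc), hp,
                               randomSeq(pad - left, gc))
        } else {
            interior <- randomSeq(interiorLen, gc)
        }
        intron <- paste0(d, interior, a)
        # disruption guarantee
        if (len %% 3L == 0L) {
            f <- (3L - phase) %% 3L
            slots <- seq.int(1L + f, len - 2L, by = 3L)
            slots <- slots[slots > nd & slots + 2L <= len - na]
            if (!length(slots)) next
            codons <- vapply(slots, function(k) substr(intron, k, k + 2L),
                             character(1))
            if (!any(codons == "TGA")) {
                k <- sample(slots, 1L)
                substr(intron, k, k + 2L) <- "TGA"
            }
        }
        if (structured) {
            mask <- c(seq_len(nd), (len - na + 1L):len)
            st <- foldConstrained(intron, unpaired = mask,
                                  temperature = temperature, nBest = 1L)[[1]]
            sd <- spatialDistance(st)$spatial_distance
            if (sd < band[1] || sd > band[2]) next
        }
        return(intron)
    }
    stop("could not build a conforming intron in ", maxTries, " attempts")
}

#' Simulate a genome with planted introns
#'
#' Seeded generator of synthetic contigs: i.i.d. background of configurable
#' GC content, stop-free protein-coding genes under the ciliate (or
#' standard) genetic code, and planted introns conforming to the donor and
#' fused branch-point + acceptor consensus (degenerate positions sampled
#' uniformly within their IUPAC class). Every planted intron is guaranteed
#' to disrupt the reading frame (length not a multiple of 3) or to carry an
#' in-frame stop codon. With probability \code{structuredFraction} an
#' interior inverted repeat is planted so that the constrained fold's
#' splice-site spatial distance falls within \code{structuredBand}
#' (generation is verified by folding and resampled if needed). Genes are
#' placed on a random strand.
#'
#' @param nContigs number of contigs.
#' @param contigLen contig length (nt).
#' @param gc background GC content (default 0.45).
#' @param nGenes genes per contig.
#' @param nIntrons introns per contig (at most one per gene).
#' @param intronLenRange intron length bounds, default \code{c(40, 120)}.
#' @param structuredFraction fraction of introns with a planted stem-loop.
#' @param structuredBand target spatial-distance band for structured
#'   introns (default \code{c(35, 45)}).
#' @param geneCodons gene length in codons (including start and stop).
#' @param code \code{"ciliate"} or \code{"standard"}.
#' @param temperature folding temperature used for structure verification.
#' @param fiveSS,bp3SS consensus patterns to sample splice sites from.
#' @param seed integer seed; identical seeds give identical output.
#' @return a [TruthSet-class].
#' @export
simulateGenome <- function(nContigs = 1L, contigLen = 10000L, gc = 0.45,
                           nGenes = 5L, nIntrons = 5L,
                           intronLenRange = c(40L, 120L),
                           structuredFraction = 0,
                           structuredBand = c(35, 45),
                           geneCodons = 120L,
                           code = c("ciliate", "standard"),
                           temperature = 37,
                           fiveSS = "GTAAGTY", bp3SS = "RCTAACAARHTAG",
                           seed = 1L) {
    code <- match.arg(code)
    stopifnot(nIntrons <= nGenes, intronLenRange[1] >= 28L,
              intronLenRange[1] <= intronLenRange[2])
    set.seed(seed)
    geneLen <- 3L * geneCodons
    maxIntron <- intronLenRange[2]
    if (contigLen < nGenes * (geneLen + maxIntron + 40L))
        stop("contigLen too small for the requested genes")
    contigs <- character(nContigs)
    names(contigs) <- sprintf("contig%02d", seq_len(nContigs))
    geneRows <- list(); intronRows <- list()
    minStructured <- round(mean(structuredBand)) + 13L + 28L
    for (ci in seq_len(nContigs)) {
        id <- names(contigs)[ci]
        slot <- contigLen %/% nGenes
        withIntron <- sample(seq_len(nGenes), nIntrons)
        pieces <- character(0)
        cursor <- 0L
        for (g in seq_len(nGenes)) {
            orf <- randomOrf(geneCodons, code)
            strand <- sample(c("+", "-"), 1L)
            hasIntron <- g %in% withIntron
            intron <- NULL
            if (hasIntron) {
                structured <- stats::runif(1) < structuredFraction
                len <- if (structured)
                    sample(seq.int(max(intronLenRange[1], minStructured),
                                   intronLenRange[2]), 1L)
                else sample(seq.int(intronLenRange[1], intronLenRange[2]), 1L)
                cdsUp <- sample(seq.int(3L, geneLen - 30L), 1L)
                phase <- cdsUp %% 3L
                intron <- buildIntron(len, phase, structured, structuredBand,
                                      fiveSS, bp3SS, temperature, gc)
                geneSeq <- paste0(substr(orf, 1L, cdsUp), intron,
                                  substr(orf, cdsUp + 1L, geneLen))
            } else geneSeq <- orf
            placed <- if (strand == "-") revComp(geneSeq) else geneSeq
            # gene at a random offset within its slot
            slotStart <- (g - 1L) * slot + 1L
            maxOff <- slot - nchar(placed) - 10L
            off <- sample.int(max(1L, maxOff), 1L)
            gStart <- slotStart + off - 1L
            pieces <- c(pieces,
                        randomSeq(gStart - cursor - 1L, gc), placed)
            cursor <- gStart + nchar(placed) - 1L
            geneRows[[length(geneRows) + 1L]] <- data.frame(
                seq_id = id, start = gStart, end = cursor, strand = strand,
                gene_id = sprintf("%s_g%02d", id, g))
            if (hasIntron) {
                iu <- cdsUp + 1L            # intron start on the gene strand
                iv <- cdsUp + nchar(intron)
                if (strand == "+") {
                    is <- gStart + iu - 1L; ie <- gStart + iv - 1L
                } else {
                    is <- cursor - iv + 1L; ie <- cursor - iu + 1L
                }
                intronRows[[length(intronRows) + 1L]] <- data.frame(
                    seq_id = id, start = is, end = ie, strand = strand,
                    gene_id = sprintf("%s_g%02d", id, g),
                    intron_seq = intron,
                    length = nchar(intron),
                    phase = phase,
                    cds_upstream = cdsUp,
                    structured = structured,
                    branch_a_offset = nchar(intron) - 13L + 5L)
            }
        }
        pieces <- c(pieces, randomSeq(contigLen - cursor, gc))
        contigs[ci] <- paste(pieces, collapse = "")
    }
    toGR <- function(rows, extra) {
        if (!length(rows)) return(GenomicRanges::GRanges())
        df <- do.call(rbind, rows)
        gr <- GenomicRanges::GRanges(df$seq_id,
                                     IRanges::IRanges(df$start, df$end),
                                     strand = df$strand)
        S4Vectors::mcols(gr) <- df[setdiff(names(df),
                                           c("seq_id", "start", "end",
                                             "strand"))]
        gr
    }
    methods::new("TruthSet",
                 genome = Biostrings::DNAStringSet(contigs),
                 genes = toGR(geneRows),
                 introns = toGR(intronRows),
                 snrnas = GenomicRanges::GRanges(),
                 params = list(nContigs = nContigs, contigLen = contigLen,
                               gc = gc, nGenes = nGenes, nIntrons = nIntrons,
                               intronLenRange = intronLenRange,
                               structuredFraction = structuredFraction,
                               structuredBand = structuredBand,
                               geneCodons = geneCodons, code = code,
                               temperature = temperature, fiveSS = fiveSS,
                               bp3SS = bp3SS, seed = seed))
}

#' Simulate junction candidates with template-switch artifacts
#'
#' Seeded generator of spliced-alignment junction candidates over a
#' simulated genome: real junctions coincide with planted introns; artifact
#' junctions are built by planting a k-mer direct repeat at matched offsets
#' around two intergenic loci (a perfect copy with probability
#' \code{repeatFidelity}, otherwise one substitution for a k-1 match),
#' emulating reverse-transcriptase template switching. The realized
#' best-match label of every junction is computed with the brute-force
#' scorer and returned, so detector output can be compared against
#' independently derived labels.
#'
#' @param truth a [TruthSet-class] from [simulateGenome()].
#' @param nReal number of real junctions (sampled from planted introns,
#'   with replacement if needed).
#' @param nArtifact number of artifact junctions.
#' @param repeatFidelity probability an artifact repeat is planted perfect.
#' @param k,window repeat length and offset half-width.
#' @param seed integer seed.
#' @return list with \code{genome} (the genome with planted repeats),
#'   \code{junctions} (data.frame \code{seq_id, donor, acceptor, strand,
#'   is_artifact, intended_perfect, label_best}).
#' @export
simulateJunctions <- function(truth, nReal = 500L, nArtifact = 500L,
                              repeatFidelity = 0.5, k = 5L, window = 5L,
                              seed = 1L) {
    set.seed(seed)
    seqs <- asSeqVector(genomeSeqs(truth))
    genes <- plantedGenes(truth)
    rows <- list()
    if (nReal > 0L) {
        introns <- plantedIntrons(truth)
        if (!length(introns)) stop("no planted introns for real junctions")
        pick <- sample(seq_along(introns), nReal,
                       replace = nReal > length(introns))
        for (i in pick)
            rows[[length(rows) + 1L]] <- data.frame(
                seq_id = as.character(GenomicRanges::seqnames(introns)[i]),
                donor = GenomicRanges::start(introns)[i],
                acceptor = GenomicRanges::end(introns)[i],
                strand = as.character(GenomicRanges::strand(introns)[i]),
                is_artifact = FALSE, intended_perfect = NA)
    }
    if (nArtifact > 0L) {
        # free = intergenic with clearance; updated as repeats are planted so
        # two artifacts never overwrite each other's flanks
        freeMask <- lapply(seqs, function(s) {
            L <- nchar(s)
            free <- rep(TRUE, L)
            free[seq_len(k + window + 1L)] <- FALSE
            free[(L - k - window - 1L):L] <- FALSE
            free
        })
        for (gi in seq_along(genes)) {
            id <- as.character(GenomicRanges::seqnames(genes))[gi]
            L <- nchar(seqs[[id]])
            a <- max(1L, GenomicRanges::start(genes)[gi] - 2L * window - k)
            b <- min(L, GenomicRanges::end(genes)[gi] + 2L * window + k)
            freeMask[[id]][a:b] <- FALSE
        }
        clear <- k + 2L * window
        for (i in seq_len(nArtifact)) {
            id <- sample(names(seqs), 1L)
            L <- nchar(seqs[[id]])
            free <- freeMask[[id]]
            cand <- which(free)
            repeat {
                donor <- sample(cand, 1L)
                acceptor <- donor + sample(seq.int(60L, 2000L), 1L)
                if (acceptor + clear <= L &&
                    all(free[max(1L, donor - clear):(donor + clear)]) &&
                    all(free[(acceptor - clear):(acceptor + 1L + clear)]))
                    break
            }
            freeMask[[id]][max(1L, donor - clear):(donor + clear)] <- FALSE
            freeMask[[id]][(acceptor - clear):(acceptor + 1L + clear)] <- FALSE
            off <- sample(seq.int(-min(window, 3L), min(window, 3L)), 1L)
            rep5 <- randomSeq(k, gc = 0.5)
            copy <- rep5
            perfect <- stats::runif(1) < repeatFidelity
            if (!perfect) {
                # interior substitution: an edge substitution could complete
                # back to k/k at a shifted offset via a flanking match
                p <- sample(seq.int(2L, k - 1L), 1L)
                b <- chars(copy)[p]
                substr(copy, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     b), 1L)
            }
            substr(seqs[[id]], donor + off, donor + off + k - 1L) <- rep5
            substr(seqs[[id]], acceptor + 1L + off,
                   acceptor + off + k) <- copy
            # break boundary extension so a shifted window cannot regain a
            # full match through identical bases adjacent to the repeat
            fixNe <- function(ref, tgt) {
                if (substr(seqs[[id]], ref, ref) ==
                    substr(seqs[[id]], tgt, tgt))
                    substr(seqs[[id]], tgt, tgt) <<- sample(
                        setdiff(c("A", "C", "G", "T"),
                                substr(seqs[[id]], ref, ref)), 1L)
            }
            fixNe(donor + off - 1L, acceptor + off)
            fixNe(donor + off + k, acceptor + 1L + off + k)
            rows[[length(rows) + 1L]] <- data.frame(
                seq_id = id, donor = donor, acceptor = acceptor,
                strand = "+", is_artifact = TRUE,
                intended_perfect = perfect)
        }
    }
    junctions <- do.call(rbind, rows)
    genome <- Biostrings::DNAStringSet(seqs)
    junctions$label_best <- vapply(seq_len(nrow(junctions)), function(i)
        templateSwitchScoreBrute(seqs, junctions$seq_id[i],
                                 junctions$donor[i], junctions$acceptor[i],
                                 k = k, window = window), integer(1))
    list(genome = genome, junctions = junctions)
}

#' Simulate a U5 snRNA-like locus
#'
#' Designs one U5-like locus: an extended stem-loop with three GC-rich
#' helices (1a/1b/1c) separated by two internal loops, the conserved loop-I
#' sequence at the apex, and a downstream Sm site; verified against the
#' structural predicates (closing stem, fold architecture, Sm presence) and
#' resampled if the verification fails.
#'
#' @param temperature folding temperature used for verification.
#' @return the locus sequence (character).
#' @keywords internal
buildU5Locus <- function(temperature = 37, maxTries = 25L) {
    loop <- "TGCCTTTTACT"
    for (try in seq_len(maxTries)) {
        h1a <- paste(sample(c("G", "C"), 7L, TRUE), collapse = "")
        h1b <- paste(sample(c("G", "C"), 5L, TRUE), collapse = "")
        h1c <- paste(sample(c("G", "C"), 6L, TRUE), collapse = "")
        il1 <- randomSeq(3L, 0.1); il1b <- randomSeq(2L, 0.1)
        il2 <- randomSeq(2L, 0.1); il2b <- randomSeq(3L, 0.1)
        locus <- paste0(h1a, il1, h1b, il2, h1c, loop,
                        revComp(h1c), il2b, revComp(h1b), il1b, revComp(h1a),
                        randomSeq(6L, 0.3), "AATTTTGG")
        loopStart <- nchar(h1a) + 3L + nchar(h1b) + 2L + nchar(h1c) + 1L
        stem <- closingStemPairs(substr(locus, loopStart - 6L, loopStart - 1L),
                                 substr(locus, loopStart + 11L,
                                        loopStart + 16L))
        if (stem < 6L) next
        loopIdx <- loopStart:(loopStart + 10L)
        fold <- foldConstrained(locus, unpaired = loopIdx,
                                temperature = temperature, nBest = 1L)[[1]]
        arch <- stemArchitecture(fold@pairs, loopIdx[6])
        if (arch$n_helix < 3L || arch$n_internal < 2L) next
        if (!nrow(smSiteHits(substr(locus, loopStart + 11L + 6L,
                                    nchar(locus))))) next
        return(locus)
    }
    stop("could not design a verifiable U5-like locus")
}

#' Simulate genomes with planted U5-like loci
#'
#' @param nGenomes number of genomes.
#' @param genomeLen background length (nt).
#' @param gc background GC content.
#' @param temperature folding temperature for locus verification.
#' @param seed integer seed.
#' @return list of [TruthSet-class] objects, one per genome, each with a
#'   single planted U5-like locus recorded in \code{plantedSnrnas()}.
#' @export
simulateU5Genomes <- function(nGenomes = 20L, genomeLen = 50000L, gc = 0.45,
                              temperature = 37, seed = 1L) {
    set.seed(seed)
    lapply(seq_len(nGenomes), function(gi) {
        bg0 <- randomSeq(genomeLen, gc)
        # plant and verify in genomic context: the fold at stage 2 sees the
        # locus plus flanking background, so acceptance is checked on the
        # planted window itself and the locus resampled on failure
        for (attempt in 1:25) {
            bg <- bg0
            locus <- buildU5Locus(temperature)
            pos <- sample(seq.int(200L, genomeLen - nchar(locus) - 200L), 1L)
            strand <- sample(c("+", "-"), 1L)
            ins <- if (strand == "-") revComp(locus) else locus
            substr(bg, pos, pos + nchar(ins) - 1L) <- ins
            wFrom <- pos - 150L
            win <- substr(bg, wFrom, pos + nchar(ins) - 1L + 150L)
            chk <- findU5Candidates(stats::setNames(win, "w"),
                                    temperature = temperature)
            hit <- nrow(chk) > 0 && any(
                chk$full & chk$strand == strand &
                chk$start + wFrom - 1L >= pos &
                chk$end + wFrom - 1L <= pos + nchar(ins) - 1L)
            if (hit) break
        }
        if (!hit) stop("could not plant a detectable U5-like locus")
        id <- sprintf("genome%02d", gi)
        gr <- GenomicRanges::GRanges(id,
                                     IRanges::IRanges(pos,
                                                      pos + nchar(ins) - 1L),
                                     strand = strand, kind = "U5",
                                     locus_seq = locus)
        methods::new("TruthSet",
                     genome = stats::setNames(Biostrings::DNAStringSet(bg), id),
                     genes = GenomicRanges::GRanges(),
                     introns = GenomicRanges::GRanges(),
                     snrnas = gr,
                     params = list(genomeLen = genomeLen, gc = gc,
                                   temperature = temperature, seed = seed,
                                   index = gi))
    })
}

#' Simulate an ortholog family with planted homologous introns
#'
#' Seeded generator of a protein family: an ancestral protein diverged per
#' species by substitutions and single-residue indels (the true alignment
#' is tracked, so species insertions open gap columns), with intron sites
#' defined at ancestral codons and retained per species with probability
#' \code{1 - lossProb} (an intron is also lost when its codon is deleted).
#'
#' @param nSpecies number of species.
#' @param cdsLenAa ancestral protein length (aa).
#' @param subRate per-residue substitution probability.
#' @param indelRate per-residue indel probability (split between single
#'   residue insertion and deletion).
#' @param intronSites data.frame \code{codon_index}, \code{phase} of planted
#'   ancestral intron sites.
#' @param lossProb per-species intron loss probability.
#' @param seed integer seed.
#' @return list with \code{alignment} (named character vector),
#'   \code{sites} (data.frame \code{species, cds_upstream, truth_group}),
#'   and \code{truth} (data.frame \code{truth_group, codon_index, phase}).
#' @export
simulateOrthologFamily <- function(nSpecies = 10L, cdsLenAa = 200L,
                                   subRate = 0.02, indelRate = 0.01,
                                   intronSites = data.frame(
                                       codon_index = c(10L, 120L),
                                       phase = c(0L, 1L)),
                                   lossProb = 0.2, seed = 1L) {
    set.seed(seed)
    stopifnot(all(intronSites$codon_index <= cdsLenAa),
              all(intronSites$phase %in% 0:2))
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    anc <- sample(aas, cdsLenAa, replace = TRUE)
    species <- sprintf("sp%02d", seq_len(nSpecies))
    del <- matrix(stats::runif(nSpecies * cdsLenAa) < indelRate / 2,
                  nSpecies, cdsLenAa)
    ins <- matrix(ifelse(stats::runif(nSpecies * cdsLenAa) < indelRate / 2,
                         sample(aas, nSpecies * cdsLenAa, replace = TRUE),
                         NA_character_), nSpecies, cdsLenAa)
    res <- matrix(rep(anc, each = nSpecies), nSpecies, cdsLenAa)
    sub <- matrix(stats::runif(nSpecies * cdsLenAa) < subRate,
                  nSpecies, cdsLenAa)
    res[sub] <- sample(aas, sum(sub), replace = TRUE)
    res[del] <- "-"
    # assemble the alignment: ancestor columns, with species-specific
    # insertion columns after each
    cols <- list(); ancCol <- integer(0)
    for (c in seq_len(cdsLenAa)) {
        cols[[length(cols) + 1L]] <- res[, c]
        ancCol <- c(ancCol, c)
        for (s in seq_len(nSpecies)) if (!is.na(ins[s, c])) {
            v <- rep("-", nSpecies); v[s] <- ins[s, c]
            cols[[length(cols) + 1L]] <- v
            ancCol <- c(ancCol, NA_integer_)
        }
    }
    mat <- do.call(cbind, cols)
    alignment <- stats::setNames(apply(mat, 1, paste, collapse = ""), species)
    siteRows <- list()
    for (g in seq_len(nrow(intronSites))) {
        c0 <- intronSites$codon_index[g]
        ph <- intronSites$phase[g]
        col <- which(ancCol == c0)
        for (s in seq_len(nSpecies)) {
            if (del[s, c0]) next
            if (stats::runif(1) < lossProb) next
            upstream <- sum(mat[s, seq_len(col - 1L)] != "-")
            siteRows[[length(siteRows) + 1L]] <- data.frame(
                species = species[s],
                cds_upstream = 3L * upstream + ph,
                truth_group = g)
        }
    }
    sites <- if (length(siteRows)) do.call(rbind, siteRows) else
        data.frame(species = character(0), cds_upstream = integer(0),
                   truth_group = integer(0))
    list(alignment = alignment, sites = sites,
         truth = data.frame(truth_group = seq_len(nrow(intronSites)),
                            codon_index = intronSites$codon_index,
                            phase = intronSites$phase))
}
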