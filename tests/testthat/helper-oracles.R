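# shared fixtures and independent oracles used across test files

randomDna <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# independent column-mapping oracle: alignment column of the k-th residue by
# cumulative non-gap counting, character by character
columnOracle <- function(alignedSeq, k) {
    cnt <- 0L
    ch <- strsplit(alignedSeq, "")[[1]]
    for (pos in seq_along(ch)) {
        if (ch[pos] != "-") cnt <- cnt + 1L
        if (cnt == k) return(pos)
    }
    NA_integer_
}

# exhaustive set-algebra oracle for Venn partitions over explicit sets
vennOracle <- function(sets) {
    uni <- Reduce(union, sets)
    ns <- length(sets)
    pats <- apply(expand.grid(rep(list(c(FALSE, TRUE)), ns)), 1, identity)
    out <- list()
    for (r in seq_len(2^ns)) {
        b <- as.logical(pats[, r])
        if (!any(b)) next
        members <- uni
        for (i in seq_len(ns))
            members <- if (b[i]) intersect(members, sets[[i]])
                       else setdiff(members, sets[[i]])
        out[[paste(ifelse(b, "1", "0"), collapse = "")]] <- length(members)
    }
    out
}

grKey <- function(gr) paste(GenomicRanges::seqnames(gr),
                            GenomicRanges::start(gr),
                            GenomicRanges::end(gr),
                            GenomicRanges::strand(gr))

# every degenerate pattern the pipeline uses, as compiled objects
pipelinePatterns <- function(maxMismatches = 2L) {
    lapply(defaultPatterns(), compilePattern, maxMismatches = maxMismatches)
}
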