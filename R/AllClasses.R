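#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand width
NULL

#' Compiled degenerate nucleotide pattern
#'
#' A degenerate IUPAC pattern (optionally with bounded repeats such as
#' \code{"RAT{4,6}GR"} or explicit classes such as \code{"[T/C]"}) compiled
#' into one or more fixed-length IUPAC expansions, together with the mismatch
#' allowance used when scanning.
#'
#' @slot pattern the pattern string as supplied.
#' @slot maxMismatches maximum number of mismatching positions tolerated.
#' @slot expansions character vector of fixed-length IUPAC strings; bounded
#'   repeats contribute one expansion per repeat count.
#'
#' @seealso [compilePattern()], [scanMotif()]
#' @export
setClass("CompiledPattern",
    representation(
        pattern = "character",
        maxMismatches = "integer",
        expansions = "character"
    )
)

setValidity("CompiledPattern", function(object) {
    msg <- character()
    if (length(object@pattern) != 1L) msg <- c(msg, "'pattern' must be length 1")
    if (object@maxMismatches < 0L) msg <- c(msg, "'maxMismatches' must be >= 0")
    bad <- setdiff(unique(strsplit(paste(object@expansions, collapse = ""), "")[[1]]),
                   names(IUPAC_CLASSES))
    if (length(bad))
        msg <- c(msg, paste0("invalid IUPAC code(s) in expansions: ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @describeIn CompiledPattern lengths of the fixed-length expansions (nt).
#' @param x a \code{CompiledPattern}.
#' @export
patternWidths <- function(x) unique(nchar(x@expansions))

setMethod("show", "CompiledPattern", function(object) {
    cat("CompiledPattern: ", object@pattern,
        "  (", length(object@expansions), " expansion",
        if (length(object@expansions) > 1L) "s", ", width ",
        paste(patternWidths(object), collapse = "/"),
        ", <= ", object@maxMismatches, " mismatch",
        if (object@maxMismatches != 1L) "es", ")\n", sep = "")
})

#' RNA secondary structure with energy and constraints
#'
#' A pseudoknot-free secondary structure in dot-bracket notation, with its
#' free energy (kcal/mol) under the package's nearest-neighbor model, the
#' base-pair list, the folding temperature, and the set of positions forced
#' single-stranded during prediction.
#'
#' @slot seq the folded sequence (RNA alphabet, as folded).
#' @slot dotbracket structure string over \code{". ( )"}.
#' @slot energy free energy in kcal/mol.
#' @slot pairs two-column integer matrix of base pairs (i < j, 1-based).
#' @slot unpaired integer vector of positions constrained single-stranded.
#' @slot temperature folding temperature in degrees Celsius.
#'
#' @seealso [foldConstrained()], [spatialDistance()]
#' @export
setClass("SecondaryStructure",
    representation(
        seq = "character",
        dotbracket = "character",
        energy = "numeric",
        pairs = "matrix",
        unpaired = "integer",
        temperature = "numeric"
    )
)

setValidity("SecondaryStructure", function(object) {
    msg <- character()
    n <- nchar(object@seq)
    if (nchar(object@dotbracket) != n)
        msg <- c(msg, "dot-bracket length differs from sequence length")
    ch <- strsplit(object@dotbracket, "")[[1]]
    if (sum(ch == "(") != sum(ch == ")"))
        msg <- c(msg, "unbalanced brackets")
    if (nrow(object@pairs) > 0) {
        if (any(object@pairs[, 1] >= object@pairs[, 2]))
            msg <- c(msg, "pairs must satisfy i < j")
        if (any(object@pairs < 1) || any(object@pairs > n))
            msg <- c(msg, "pair index out of range")
        if (any(object@unpaired %in% as.vector(object@pairs)))
            msg <- c(msg, "constrained position is paired")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SecondaryStructure", function(object) {
    cat("SecondaryStructure (", nchar(object@seq), " nt, ",
        sprintf("%.2f", object@energy), " kcal/mol at ",
        object@temperature, " C)\n", sep = "")
    cat(" ", object@seq, "\n ", object@dotbracket, "\n", sep = "")
})

#' @describeIn SecondaryStructure free energy (kcal/mol).
#' @param x a \code{SecondaryStructure}.
#' @export
structureEnergy <- function(x) x@energy

#' @describeIn SecondaryStructure dot-bracket string.
#' @export
dotBracket <- function(x) x@dotbracket

#' @describeIn SecondaryStructure base-pair matrix (columns i, j; 1-based).
#' @export
basePairs <- function(x) x@pairs

#' Synthetic data set with planted ground truth
#'
#' Container returned by the synthetic-data generators: the simulated contigs
#' plus the planted features (genes, introns, snRNA loci) and the full
#' generator configuration including the seed, so any run is reproducible.
#'
#' @slot genome named \code{DNAStringSet} of simulated contigs.
#' @slot genes planted protein-coding genes (\code{GRanges}).
#' @slot introns planted introns (\code{GRanges}; metadata columns carry the
#'   sampled splice-site texts, phase and structure information).
#' @slot snrnas planted snRNA-like loci (\code{GRanges}).
#' @slot params generator configuration, including the seed.
#'
#' @seealso [simulateGenome()], [simulateJunctions()]
#' @export
setClass("TruthSet",
    representation(
        genome = "DNAStringSet",
        genes = "GRanges",
        introns = "GRanges",
        snrnas = "GRanges",
        params = "list"
    )
)

setValidity("TruthSet", function(object) {
    msg <- character()
    lens <- stats::setNames(Biostrings::width(object@genome), names(object@genome))
    for (gr in list(object@genes, object@introns, object@snrnas)) {
        if (length(gr) == 0) next
        sid <- as.character(GenomicRanges::seqnames(gr))
        if (!all(sid %in% names(lens))) {
            msg <- c(msg, "feature on unknown contig")
            next
        }
        if (any(GenomicRanges::start(gr) < 1) ||
            any(GenomicRanges::end(gr) > lens[sid]))
            msg <- c(msg, "planted feature outside its contig")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet: ", length(object@genome), " contig(s), ",
        sum(Biostrings::width(object@genome)), " nt total\n",
        "  planted: ", length(object@genes), " gene(s), ",
        length(object@introns), " intron(s), ",
        length(object@snrnas), " snRNA locus/loci\n",
        "  seed: ", object@params$seed, "\n", sep = "")
})

#' @describeIn TruthSet simulated contigs as a \code{DNAStringSet}.
#' @param x a \code{TruthSet}.
#' @export
genomeSeqs <- function(x) x@genome

#' @describeIn TruthSet planted introns (\code{GRanges}).
#' @export
plantedIntrons <- function(x) x@introns

#' @describeIn TruthSet planted genes (\code{GRanges}).
#' @export
plantedGenes <- function(x) x@genes

#' @describeIn TruthSet planted snRNA-like loci (\code{GRanges}).
#' @export
plantedSnrnas <- function(x) x@snrnas

#' @describeIn TruthSet full generator configuration (list, includes seed).
#' @export
truthParams <- function(x) x@params
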