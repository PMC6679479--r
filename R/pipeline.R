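#' Build and validate a pipeline configuration
#'
#' Central configuration for [runPipeline()], validated up front so no stage
#' runs on a malformed configuration. Defaults are the study conditions of
#' the source analyses: zero-mismatch consensus scanning with the donor
#' \code{GTAAGTY} and fused branch-point + acceptor \code{RCTAACAARHTAG},
#' intron length bounds 40-120 nt, splice-site masks of 7 nt (donor) and
#' 13 nt (branch-point + acceptor) during folding, folding temperature 21 or
#' 37 degrees Celsius depending on the organism's growth temperature
#' (default 37), and a 5-nt template-switch repeat within a 5-nt offset
#' window.
#'
#' @param fiveSS,bp3SS consensus patterns.
#' @param mismatches mismatch allowance for the discovery scan.
#' @param minLen,maxLen intron length bounds (nt).
#' @param displaced also search displaced-acceptor candidates.
#' @param temperature folding temperature (degrees Celsius, 0-100).
#' @param mask5ss,maskBp3ss numbers of 5'- and 3'-terminal intron positions
#'   forced single-stranded during folding.
#' @param foldMinLen only introns at least this long are folded.
#' @param tsK,tsWindow template-switch repeat length and offset window.
#' @param tsAnchor \code{"boundary"} or \code{"adjacent"}.
#' @param seed integer seed recorded in provenance output.
#' @return a validated configuration list of class \code{"intronoscopeConfig"}.
#' @export
pipelineConfig <- function(fiveSS = "GTAAGTY", bp3SS = "RCTAACAARHTAG",
                           mismatches = 0L, minLen = 40L, maxLen = 120L,
                           displaced = FALSE, temperature = 37,
                           mask5ss = 7L, maskBp3ss = 13L, foldMinLen = 50L,
                           tsK = 5L, tsWindow = 5L, tsAnchor = "boundary",
                           seed = 1L) {
    cfg <- list(fiveSS = fiveSS, bp3SS = bp3SS,
                mismatches = as.integer(mismatches),
                minLen = as.integer(minLen), maxLen = as.integer(maxLen),
                displaced = isTRUE(displaced),
                temperature = as.numeric(temperature),
                mask5ss = as.integer(mask5ss),
                maskBp3ss = as.integer(maskBp3ss),
                foldMinLen = as.integer(foldMinLen),
                tsK = as.integer(tsK), tsWindow = as.integer(tsWindow),
                tsAnchor = match.arg(tsAnchor, c("boundary", "adjacent")),
                seed = as.integer(seed))
    # schema validation before any stage is allowed to run
    compilePattern(cfg$fiveSS)
    compilePattern(cfg$bp3SS)
    if (cfg$mismatches < 0L) stop("mismatches must be >= 0")
    if (cfg$minLen < 15L) stop("minLen must be >= 15")
    if (cfg$minLen > cfg$maxLen) stop("minLen exceeds maxLen")
    if (cfg$temperature < 0 || cfg$temperature > 100)
        stop("temperature must be in [0, 100]")
    if (cfg$tsK < 1L || cfg$tsWindow < 0L)
        stop("invalid template-switch parameters")
    class(cfg) <- "intronoscopeConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipelineConfig()] arguments.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    bad <- setdiff(names(vals), names(formals(pipelineConfig)))
    if (length(bad)) stop("unknown configuration key(s): ",
                          paste(bad, collapse = ", "))
    do.call(pipelineConfig, vals)
}

configComments <- function(cfg) {
    c("intronoscope provenance",
      vapply(names(unclass(cfg)), function(k)
          paste0(k, " = ", paste(format(cfg[[k]]), collapse = ",")),
          character(1)))
}

#' Run the discovery pipeline end to end
#'
#' Stages, in order: intron candidate discovery on the genome; motif/phase
#' annotation of every candidate; constrained folding and spatial-distance
#' computation for candidates of at least \code{foldMinLen} nt; junction
#' triage and template-switch filtering when a junction table is supplied.
#' Reports (candidate GFF3, annotation TSV, junction TSV, summary TSV) are
#' written under \code{outDir} with the resolved configuration echoed into
#' every report's provenance header; given identical inputs, configuration
#' and seed the outputs are byte-identical.
#'
#' @param genome a named \code{DNAStringSet} or path to a FASTA file.
#' @param junctions optional junction data.frame (see [readJunctions()]) or
#'   path to a junction file.
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   all file output.
#' @return invisibly, a list with \code{candidates} (GRanges),
#'   \code{annotation} (data.frame), \code{junctions} (filter result or
#'   NULL), and \code{summary} (data.frame of per-stage counts).
#' @export
runPipeline <- function(genome, junctions = NULL,
                        config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "intronoscopeConfig"))
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readGenome(genome)
    else if (is.character(genome) && length(genome) == 1L &&
             grepl("[./]", genome))
        stop("genome file not found: ", genome)
    if (is.character(junctions)) {
        if (!file.exists(junctions))
            stop("junction file not found: ", junctions)
        junctions <- readJunctions(junctions)
    }
    cand <- scanGenomeForIntrons(genome,
                                 fiveSS = config$fiveSS,
                                 bp3SS = config$bp3SS,
                                 mismatches = config$mismatches,
                                 minLen = config$minLen,
                                 maxLen = config$maxLen,
                                 displaced = config$displaced)
    ann <- NULL
    if (length(cand)) {
        rows <- lapply(seq_along(cand), function(i) {
            iseq <- cand$intron_seq[i]
            len <- nchar(iseq)
            bpStart <- len - nchar(cand$bp_3ss[i]) + 1L
            a <- annotateIntron(iseq, bpMotifStart = bpStart)
            sd <- NA_integer_; db <- NA_character_; en <- NA_real_
            if (len >= config$foldMinLen) {
                mask <- c(seq_len(min(config$mask5ss, len)),
                          seq.int(max(1L, len - config$maskBp3ss + 1L), len))
                st <- foldConstrained(iseq, unpaired = unique(mask),
                                      temperature = config$temperature,
                                      nBest = 1L)[[1]]
                sd <- spatialDistance(st)$spatial_distance
                db <- st@dotbracket
                en <- st@energy
            }
            data.frame(seq_id = as.character(
                           GenomicRanges::seqnames(cand)[i]),
                       start = GenomicRanges::start(cand)[i],
                       end = GenomicRanges::end(cand)[i],
                       strand = as.character(GenomicRanges::strand(cand)[i]),
                       length = len,
                       five_ss = cand$five_ss[i], bp_3ss = cand$bp_3ss[i],
                       extended_5ss = a$extended_5ss,
                       n_pyrimidine_abutting = length(a$pyrimidine_hits),
                       displaced_3ss = cand$displaced_3ss[i],
                       spatial_distance = sd, energy = en, structure = db)
        })
        ann <- do.call(rbind, rows)
    }
    jres <- NULL
    if (!is.null(junctions) && nrow(junctions))
        jres <- filterJunctionCandidates(genome, junctions, k = config$tsK,
                                         window = config$tsWindow,
                                         anchor = config$tsAnchor)
    summary <- data.frame(
        stage = c("discover", "fold", "junctions_artifact",
                  "junctions_rescued", "junctions_other"),
        count = c(length(cand),
                  if (is.null(ann)) 0L else sum(!is.na(ann$spatial_distance)),
                  if (is.null(jres)) NA_integer_ else jres$summary$n_artifact,
                  if (is.null(jres)) NA_integer_ else jres$summary$n_rescued,
                  if (is.null(jres)) NA_integer_ else jres$summary$n_other))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        cm <- configComments(config)
        if (length(cand)) {
            gr <- cand
            S4Vectors::mcols(gr)$type <- "intron"
            writeFeaturesGff3(gr, file.path(outDir, "candidates.gff3"))
            writeReport(ann, file.path(outDir, "candidates.tsv"), cm)
        }
        if (!is.null(jres))
            writeReport(jres$table, file.path(outDir, "junctions.tsv"), cm)
        writeReport(summary, file.path(outDir, "summary.tsv"), cm)
    }
    invisible(list(candidates = cand, annotation = ann, junctions = jres,
                   summary = summary))
}
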