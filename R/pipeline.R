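#' Run the full analysis pipeline on one library
#'
#' Preprocess (quality filter, adapter trim, reverse complement, collapse),
#' align and classify 3' ends, and summarize into the reporting tables.
#'
#' @param reads A \code{QualityScaledDNAStringSet} or a FASTQ path.
#' @param models Named list of \code{TRNAGeneModel} or
#'   \code{PrecursorReference}.
#' @param libraryId Library label (default \code{"library1"}).
#' @param adapter,qThreshold,qualityMethod,minOverlap,maxMismatchFrac,minLength
#'   Preprocessing parameters (see \code{\link{preprocessReads}}).
#' @param scoring An \code{AlignmentScoring}.
#' @param addedFirst Boundary policy (see \code{\link{callThreePrime}}).
#' @param intronMinOverlap Minimum intron overlap for the intron flag.
#' @param intronFilter Restrict end-processed shares to intron-overlapping
#'   reads (default \code{TRUE}).
#' @param mappingExpectation Mapping-rate warning threshold (default 0.96).
#' @return A list with \code{unique_reads}, \code{calls}, \code{summary}
#'   (see \code{\link{summarizeLibrary}}), \code{qc}
#'   (see \code{\link{mappingQC}}) and \code{stats} (read accounting across
#'   all stages).
#' @examples
#' fix <- makeFixtureGenes(seed = 42)
#' cfg <- simulationConfig(names(fix$models), nReads = 200, seed = 7)
#' lib <- simulateLibrary(cfg, fix$models)
#' res <- runPipeline(lib$reads, fix$models, libraryId = "demo")
#' res$summary$percentages
#' @export
runPipeline <- function(reads, models, libraryId = "library1",
                        adapter = DEFAULT_ADAPTER, qThreshold = 30,
                        qualityMethod = "mean", minOverlap = 4L,
                        maxMismatchFrac = 0.1, minLength = 15L,
                        scoring = alignmentScoring(), addedFirst = FALSE,
                        intronMinOverlap = 6L, intronFilter = TRUE,
                        mappingExpectation = 0.96) {
    if (is.character(reads)) reads <- readFastqReads(reads)
    refs <- lapply(models, function(m)
        if (is(m, "PrecursorReference")) m else buildPrecursorReference(m))
    pre <- preprocessReads(reads, adapter, qThreshold, qualityMethod,
                           minOverlap, maxMismatchFrac, minLength)
    cls <- classifyReads(pre$unique_reads, refs, scoring, addedFirst,
                         intronMinOverlap)
    summ <- summarizeLibrary(cls$calls, libraryId, intronFilter)
    qc <- mappingQC(cls$stats$n_reads_total, cls$stats$n_reads_assigned,
                    cls$stats$n_reads_ambiguous, mappingExpectation)
    list(unique_reads = pre$unique_reads,
         calls = cls$calls,
         summary = summ,
         qc = qc,
         stats = c(pre$stats, cls$stats,
                   list(gene_ambiguity = cls$gene_ambiguity)))
}
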