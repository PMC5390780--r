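#' Accessors for gene models and precursor references
#'
#' @param x A \code{TRNAGeneModel} or \code{PrecursorReference}.
#' @return \code{geneId} the gene identifier; \code{geneSeq} the sense gene
#'   sequence (\code{DNAString}); \code{geneStrand} \code{"+"} or \code{"-"};
#'   \code{intronRanges} intron interval(s) (\code{IRanges}, gene-relative for
#'   models, reference coordinates for references); \code{leaderFlank} /
#'   \code{trailerFlank} the flanking sequences; \code{refSeq} the full
#'   precursor sequence; \code{geneRange} the position of the gene inside the
#'   precursor reference.
#' @name accessors
#' @rdname accessors
#' @examples
#' m <- exampleGeneModel()
#' geneId(m); geneSeq(m); intronRanges(m)
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("geneSeq", function(x) standardGeneric("geneSeq"))
#' @rdname accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))
#' @rdname accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname accessors
#' @export
setGeneric("leaderFlank", function(x) standardGeneric("leaderFlank"))
#' @rdname accessors
#' @export
setGeneric("trailerFlank", function(x) standardGeneric("trailerFlank"))
#' @rdname accessors
#' @export
setGeneric("refSeq", function(x) standardGeneric("refSeq"))
#' @rdname accessors
#' @export
setGeneric("geneRange", function(x) standardGeneric("geneRange"))

#' @rdname accessors
setMethod("geneId", "TRNAGeneModel", function(x) x@gene_id)
#' @rdname accessors
setMethod("geneSeq", "TRNAGeneModel", function(x) x@gene_seq)
#' @rdname accessors
setMethod("geneStrand", "TRNAGeneModel", function(x) x@strand)
#' @rdname accessors
setMethod("intronRanges", "TRNAGeneModel", function(x) x@intron_intervals)
#' @rdname accessors
setMethod("leaderFlank", "TRNAGeneModel", function(x) x@leader_flank)
#' @rdname accessors
setMethod("trailerFlank", "TRNAGeneModel", function(x) x@trailer_flank)

#' @rdname accessors
setMethod("geneId", "PrecursorReference", function(x) x@gene_id)
#' @rdname accessors
setMethod("refSeq", "PrecursorReference", function(x) x@seq)
#' @rdname accessors
setMethod("intronRanges", "PrecursorReference", function(x) x@intron_offsets)
#' @rdname accessors
setMethod("geneRange", "PrecursorReference",
          function(x) IRanges(x@gene_start, x@gene_last))

setMethod("show", "TRNAGeneModel", function(object) {
    cat(sprintf("TRNAGeneModel %s (%s) %s:%d-%d(%s)\n",
                object@gene_id, object@isotype, object@chrom,
                start(object@gene_interval), end(object@gene_interval),
                object@strand))
    cat(sprintf("  gene: %d nt, %d intron(s); leader %d nt, trailer %d nt\n",
                length(object@gene_seq), length(object@intron_intervals),
                length(object@leader_flank), length(object@trailer_flank)))
})

setMethod("show", "PrecursorReference", function(object) {
    cat(sprintf("PrecursorReference %s: %d nt, gene at %d-%d\n",
                object@gene_id, length(object@seq),
                object@gene_start, object@gene_last))
})

setMethod("show", "AlignmentScoring", function(object) {
    cat(sprintf(paste0("AlignmentScoring: match +%d, mismatch -%d, ",
                       "gap %d+%dk, word %d, min score %d\n"),
                object@match_reward, object@mismatch_penalty,
                object@gap_open, object@gap_extend,
                object@word_size, object@min_score))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d reads over %d gene(s), ",
                       "read length %d, substitution error %g, seed %d\n"),
                object@n_reads, length(object@gene_mixture),
                object@read_length, object@substitution_error, object@seed))
})
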