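#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement pairwiseAlignment nucleotideSubstitutionMatrix score
#'   pattern subject alignedPattern alignedSubject quality PhredQuality
#'   QualityScaledDNAStringSet readQualityScaledDNAStringSet
#' @importFrom IRanges IRanges start end width findOverlaps overlapsAny
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

## Category labels for 3'-end calls, in fixed reporting order.
## TRAILER        read 3' end lies in the genomic trailer (unprocessed)
## OLIGO_A        >=1 non-templated terminal adenosine (surveillance mark)
## PLUS_C/CC/CCA  partial or full CCA added at the exact gene end
## PROCESSED_EXACT  3' end at the last gene base, nothing added
## TRIMMED        3' end inside the gene body
## OTHER          anything else (unexplained suffixes, N-containing, etc.)
END_CATEGORIES <- c("TRAILER", "OLIGO_A", "PLUS_C", "PLUS_CC", "PLUS_CCA",
                    "PROCESSED_EXACT", "TRIMMED", "OTHER")

## Categories the simulator can generate (OTHER only arises from errors).
SIM_CATEGORIES <- setdiff(END_CATEGORIES, "OTHER")

## Categories counted as "3' end processed" (the Fig.-2-style denominator).
END_PROCESSED_CATEGORIES <- c("PROCESSED_EXACT", "PLUS_C", "PLUS_CC", "PLUS_CCA")

## 5' adapter seen at the start of every raw read: the reverse complement of
## the 3' RNA adapter ligated during library prep.
DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGGC"

#' A tRNA gene model with precursor flanks
#'
#' Holds one tRNA gene in sense orientation: the gene body (introns retained),
#' the genomic leader immediately 5' of the gene and the genomic trailer
#' immediately 3' of it. Nuclear tRNA genes do not encode the CCA end; the
#' trailer is plain genomic sequence, removed during 3' maturation.
#'
#' All internal coordinates are 1-based and closed (IRanges convention);
#' the on-disk annotation format uses 0-based half-open intervals (BED-like)
#' and is converted on load/write.
#'
#' @slot gene_id Gene identifier, e.g. \code{"tL(CAA)S1"}.
#' @slot isotype Amino-acid + anticodon label parsed from the id, e.g.
#'   \code{"L(CAA)"}.
#' @slot chrom Chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot gene_interval \code{IRanges} of length 1: genomic gene interval.
#' @slot intron_intervals \code{IRanges}: gene-relative intron interval(s),
#'   1-based closed, relative to the sense gene start.
#' @slot gene_seq \code{DNAString}, sense strand, introns included.
#' @slot leader_flank \code{DNAString}, sense, immediately 5' of the gene.
#' @slot trailer_flank \code{DNAString}, sense, immediately 3' of the gene.
#' @exportClass TRNAGeneModel
setClass("TRNAGeneModel",
    representation(
        gene_id = "character",
        isotype = "character",
        chrom = "character",
        strand = "character",
        gene_interval = "IRanges",
        intron_intervals = "IRanges",
        gene_seq = "DNAString",
        leader_flank = "DNAString",
        trailer_flank = "DNAString"
    )
)

.validTRNAGeneModel <- function(object) {
    msg <- character(0)
    if (length(object@gene_id) != 1L || !nzchar(object@gene_id))
        msg <- c(msg, "gene_id must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(object@gene_interval) != 1L)
        msg <- c(msg, "gene_interval must have length 1")
    else if (width(object@gene_interval) != length(object@gene_seq))
        msg <- c(msg, "gene_seq length must equal gene_interval width")
    gl <- length(object@gene_seq)
    ir <- object@intron_intervals
    if (length(ir) > 0L) {
        if (any(start(ir) < 1L) || any(end(ir) > gl) || any(width(ir) < 1L))
            msg <- c(msg, "intron intervals must lie strictly inside the gene")
        if (length(ir) > 1L) {
            o <- order(start(ir))
            if (any(o != seq_along(ir)) ||
                any(start(ir)[o][-1L] <= end(ir)[o][-length(ir)]))
                msg <- c(msg, "intron intervals must be sorted and disjoint")
        }
    }
    for (sl in c("gene_seq", "leader_flank", "trailer_flank")) {
        s <- as.character(slot(object, sl))
        if (nzchar(s) && grepl("[^ACGTN]", s))
            msg <- c(msg, sprintf("%s contains characters outside {A,C,G,T,N}", sl))
    }
    if (length(msg)) msg else TRUE
}
setValidity("TRNAGeneModel", .validTRNAGeneModel)

#' A precursor reference sequence
#'
#' Concatenation \code{leader_flank + gene_seq + trailer_flank} in sense
#' orientation, with the gene located at
#' \code{seq[gene_start..gene_last]}. \code{gene_last} is the coordinate
#' against which all 3'-end offsets are measured: a read whose last templated
#' base sits at \code{gene_last} has \code{end_offset == 0}.
#'
#' @slot gene_id Gene identifier.
#' @slot seq \code{DNAString}: full precursor reference.
#' @slot gene_start Integer: position of the first gene base (1-based).
#' @slot gene_last Integer: position of the last gene base (1-based).
#' @slot intron_offsets \code{IRanges}: intron interval(s) lifted into
#'   reference coordinates.
#' @exportClass PrecursorReference
setClass("PrecursorReference",
    representation(
        gene_id = "character",
        seq = "DNAString",
        gene_start = "integer",
        gene_last = "integer",
        intron_offsets = "IRanges"
    )
)

setValidity("PrecursorReference", function(object) {
    msg <- character(0)
    if (object@gene_start < 1L || object@gene_last > length(object@seq) ||
        object@gene_start > object@gene_last)
        msg <- c(msg, "gene interval must lie inside seq")
    ir <- object@intron_offsets
    if (length(ir) && (any(start(ir) < object@gene_start) ||
                       any(end(ir) > object@gene_last)))
        msg <- c(msg, "intron offsets must lie inside the gene interval")
    if (length(msg)) msg else TRUE
})

#' Local alignment scoring parameters
#'
#' blastn-style scoring for local (Smith-Waterman, affine-gap) alignment of
#' reads against precursor references: match +1, mismatch -3, gap of length
#' k costs \code{gap_open + k * gap_extend}. The E-value cutoff of the
#' original BLAST-based analysis is replaced by a raw score threshold
#' \code{min_score}; \code{word_size} is retained for provenance but the
#' implementation always computes the optimal local alignment.
#'
#' @slot match_reward Integer, score for a match (default 1).
#' @slot mismatch_penalty Integer, positive as stored (default 3).
#' @slot gap_open Integer, cost to open a gap (default 2).
#' @slot gap_extend Integer, cost per gap base (default 1).
#' @slot word_size Integer, seed length of the original tool (default 8).
#' @slot min_score Integer, minimum score for a read to count as mapped
#'   (default 20, roughly 20 matched bases).
#' @exportClass AlignmentScoring
setClass("AlignmentScoring",
    representation(
        match_reward = "integer",
        mismatch_penalty = "integer",
        gap_open = "integer",
        gap_extend = "integer",
        word_size = "integer",
        min_score = "integer"
    )
)

setValidity("AlignmentScoring", function(object) {
    msg <- character(0)
    if (object@mismatch_penalty <= 0L || object@gap_open < 0L ||
        object@gap_extend <= 0L)
        msg <- c(msg, "penalties must be positive as stored")
    if (object@word_size < 4L)
        msg <- c(msg, "word_size must be >= 4")
    if (length(msg)) msg else TRUE
})

#' Construct alignment scoring parameters
#'
#' @param match Match reward (default 1).
#' @param mismatch Mismatch penalty, positive (default 3).
#' @param gapOpen Gap opening cost (default 2).
#' @param gapExtend Gap extension cost per base (default 1).
#' @param wordSize Seed word size (default 8; informational).
#' @param minScore Minimum alignment score to call a read mapped (default 20).
#' @return An \code{AlignmentScoring} object.
#' @examples
#' alignmentScoring()
#' @export
alignmentScoring <- function(match = 1L, mismatch = 3L, gapOpen = 2L,
                             gapExtend = 1L, wordSize = 8L, minScore = 20L) {
    new("AlignmentScoring",
        match_reward = as.integer(match),
        mismatch_penalty = as.integer(mismatch),
        gap_open = as.integer(gapOpen),
        gap_extend = as.integer(gapExtend),
        word_size = as.integer(wordSize),
        min_score = as.integer(minScore))
}

#' Simulation configuration for synthetic pre-tRNA libraries
#'
#' Describes the ground-truth mixture and error model used by
#' \code{\link{simulateLibrary}}. Reads emulate the targeted library design:
#' an RNA fragment starting inside the intron and ending at the (possibly
#' modified) 3' terminus is reverse-transcribed, so the sequenced read is
#' the 5' adapter followed by the reverse complement of the fragment,
#' truncated (or padded with templated upstream sequence) to
#' \code{read_length}.
#'
#' @slot gene_mixture Named numeric: per-gene read share, sums to 1.
#' @slot category_mixture Numeric matrix (genes x categories over
#'   \code{SIM_CATEGORIES}); each row sums to 1.
#' @slot n_reads Integer: total reads to simulate.
#' @slot read_length Integer read length (default 100).
#' @slot substitution_error Per-base substitution rate (default 0.001).
#' @slot adapter 5' adapter sequence.
#' @slot oligoa_mean Mean of the geometric oligo(A) length distribution
#'   (default 3, support >= 1).
#' @slot trailer_len_max Maximum templated trailer extension (default 20;
#'   actual lengths uniform on 1..min(trailer_len_max, trailer length)).
#' @slot trim_depth_max Maximum 3' trimming depth (default 10; uniform 1..max).
#' @slot quality_high Phred score of good reads (default 37).
#' @slot quality_low Phred score of bad reads (default 20).
#' @slot quality_low_frac Fraction of reads emitted at the low quality
#'   (default 0.01); exercises the quality filter.
#' @slot seed Integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        gene_mixture = "numeric",
        category_mixture = "matrix",
        n_reads = "integer",
        read_length = "integer",
        substitution_error = "numeric",
        adapter = "character",
        oligoa_mean = "numeric",
        trailer_len_max = "integer",
        trim_depth_max = "integer",
        quality_high = "integer",
        quality_low = "integer",
        quality_low_frac = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (is.null(names(object@gene_mixture)))
        msg <- c(msg, "gene_mixture must be named by gene_id")
    if (abs(sum(object@gene_mixture) - 1) > 1e-9)
        msg <- c(msg, "gene_mixture must sum to 1")
    if (any(object@gene_mixture < 0))
        msg <- c(msg, "gene_mixture must be non-negative")
    cm <- object@category_mixture
    if (!identical(colnames(cm), SIM_CATEGORIES))
        msg <- c(msg, sprintf("category_mixture columns must be exactly {%s}",
                              paste(SIM_CATEGORIES, collapse = ", ")))
    else {
        if (!identical(rownames(cm), names(object@gene_mixture)))
            msg <- c(msg, "category_mixture rows must match gene_mixture names")
        if (any(cm < 0) || any(abs(rowSums(cm) - 1) > 1e-9))
            msg <- c(msg, "each category_mixture row must sum to 1")
    }
    if (object@n_reads <= 0L)
        msg <- c(msg, "n_reads must be positive")
    if (object@substitution_error < 0 || object@substitution_error > 1)
        msg <- c(msg, "substitution_error must be in [0,1]")
    if (grepl("[^ACGT]", object@adapter) || !nzchar(object@adapter))
        msg <- c(msg, "adapter must be a non-empty ACGT string")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param geneIds Character vector of gene ids (defines mixture order).
#' @param geneMixture Per-gene read shares; default uniform. May be an
#'   unnormalized weight vector.
#' @param categoryMixture Either a named numeric vector over
#'   \code{SIM_CATEGORIES} applied to every gene, or a genes x categories
#'   matrix. Default: a plausible precursor population (trailer-rich with
#'   moderate CCA intermediates and some oligo-adenylation).
#' @param nReads Total number of reads (default 10000).
#' @param readLength Read length (default 100).
#' @param substitutionError Per-base substitution rate (default 0.001).
#' @param adapter 5' adapter (default \code{TGGAATTCTCGGGTGCCAAGGC}).
#' @param oligoaMean Mean oligo(A) length, geometric, support >= 1 (default 3).
#' @param trailerLenMax Max trailer extension length (default 20).
#' @param trimDepthMax Max trimming depth (default 10).
#' @param qualityHigh,qualityLow,qualityLowFrac Two-level quality model:
#'   most reads at Q\code{qualityHigh} (37), a \code{qualityLowFrac} (1\%)
#'   fraction at Q\code{qualityLow} (20).
#' @param seed RNG seed (default 1).
#' @return A \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(c("gA", "gB"), nReads = 100)
#' @export
simulationConfig <- function(geneIds,
                             geneMixture = NULL,
                             categoryMixture = NULL,
                             nReads = 10000L,
                             readLength = 100L,
                             substitutionError = 0.001,
                             adapter = DEFAULT_ADAPTER,
                             oligoaMean = 3,
                             trailerLenMax = 20L,
                             trimDepthMax = 10L,
                             qualityHigh = 37L,
                             qualityLow = 20L,
                             qualityLowFrac = 0.01,
                             seed = 1L) {
    geneIds <- as.character(geneIds)
    if (is.null(geneMixture))
        geneMixture <- rep(1 / length(geneIds), length(geneIds))
    geneMixture <- geneMixture / sum(geneMixture)
    names(geneMixture) <- geneIds
    if (is.null(categoryMixture))
        categoryMixture <- c(TRAILER = 0.35, OLIGO_A = 0.10, PLUS_C = 0.05,
                             PLUS_CC = 0.10, PLUS_CCA = 0.20,
                             PROCESSED_EXACT = 0.10, TRIMMED = 0.10)
    if (is.matrix(categoryMixture)) {
        cm <- categoryMixture[, SIM_CATEGORIES, drop = FALSE]
    } else {
        if (is.null(names(categoryMixture)))
            stop("categoryMixture vector must be named")
        cm <- matrix(categoryMixture[SIM_CATEGORIES], nrow = length(geneIds),
                     ncol = length(SIM_CATEGORIES), byrow = TRUE)
        colnames(cm) <- SIM_CATEGORIES
    }
    rownames(cm) <- geneIds
    cm <- cm / rowSums(cm)
    new("SimulationConfig",
        gene_mixture = geneMixture,
        category_mixture = cm,
        n_reads = as.integer(nReads),
        read_length = as.integer(readLength),
        substitution_error = substitutionError,
        adapter = adapter,
        oligoa_mean = oligoaMean,
        trailer_len_max = as.integer(trailerLenMax),
        trim_depth_max = as.integer(trimDepthMax),
        quality_high = as.integer(qualityHigh),
        quality_low = as.integer(qualityLow),
        quality_low_frac = qualityLowFrac,
        seed = as.integer(seed))
}
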