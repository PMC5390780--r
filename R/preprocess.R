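## Read preprocessing: quality filter -> 5' adapter removal -> reverse
## complement into sense orientation -> collapse identical sequences.
##
## Library design context: the sequenced read is the reverse complement of
## (RNA fragment + 3' RNA adapter), so it *begins* with the
## reverse-complemented adapter (TGGAATTCTCGGGTGCCAAGGC) followed by the
## reverse complement of the fragment; trimming that 5' prefix and reverse
## complementing yields the sense fragment whose last base is the RNA 3'
## terminus.

.rc <- function(x) {
    if (length(x) == 0L) return(character(0))
    as.character(reverseComplement(DNAStringSet(x)))
}

#' Reverse complement nucleotide strings
#'
#' Watson-Crick reverse complement over the alphabet \{A,C,G,T,N\} (N maps
#' to N). Vectorized. Any other character is an error naming the offending
#' symbol.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplementStrings(c("ACGT", "AAACCC"))
#' @export
reverseComplementStrings <- function(x) {
    bad <- regmatches(x, regexpr("[^ACGTN]", x))
    bad <- bad[nzchar(bad)]
    if (length(bad))
        stop(sprintf("sequence contains unsupported character '%s'", bad[1]),
             call. = FALSE)
    .rc(x)
}

#' Read and write FASTQ as quality-scaled reads
#'
#' Thin wrappers around Biostrings FASTQ I/O using Sanger/Illumina 1.8+
#' (offset 33) Phred encoding.
#'
#' @param path FASTQ file path.
#' @return \code{readFastqReads}: a \code{QualityScaledDNAStringSet}.
#' @export
readFastqReads <- function(path) {
    s <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    q <- PhredQuality(S4Vectors::mcols(s)$qualities)
    ids <- names(s)
    S4Vectors::mcols(s) <- NULL
    out <- QualityScaledDNAStringSet(s, q)
    names(out) <- ids
    out
}

#' @rdname readFastqReads
#' @param reads A \code{QualityScaledDNAStringSet}.
#' @return \code{writeFastqReads}: \code{path}, invisibly.
#' @export
writeFastqReads <- function(reads, path) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    rec <- paste0("@", ids, "\n", as.character(reads), "\n+\n",
                  as.character(quality(reads)))
    writeLines(rec, path)
    invisible(path)
}

#' Filter reads on Phred quality
#'
#' Retains reads whose mean (default) or minimum per-base Phred score is at
#' least \code{qThreshold}; the comparison is inclusive. The number of
#' discarded reads is recorded in the \code{"n_discarded"} attribute and
#' reported via \code{message}.
#'
#' @param reads A \code{QualityScaledDNAStringSet}.
#' @param qThreshold Phred threshold (default 30).
#' @param method \code{"mean"} (default) or \code{"min"}: how the per-read
#'   score is summarized before comparison. The read-level interpretation of
#'   a vendor "quality >= 30" filter is not uniquely determined, hence the
#'   switch.
#' @return Filtered \code{QualityScaledDNAStringSet} with attribute
#'   \code{n_discarded}.
#' @export
qualityFilter <- function(reads, qThreshold = 30, method = c("mean", "min")) {
    method <- match.arg(method)
    if (length(reads) == 0L) {
        res <- reads
        attr(res, "n_discarded") <- 0L
        return(res)
    }
    ql <- as(quality(reads), "IntegerList")
    stat <- if (method == "mean") sum(ql) / lengths(ql) else min(ql)
    keep <- stat >= qThreshold
    n_disc <- sum(!keep)
    message(sprintf("qualityFilter: discarded %d/%d reads below Q%g (%s)",
                    n_disc, length(reads), qThreshold, method))
    res <- reads[keep]
    attr(res, "n_discarded") <- n_disc
    res
}

## Longest adapter prefix of `read`: the full adapter, or a >=minOverlap
## suffix of the adapter, matching the read start with at most
## floor(maxMismatchFrac * overlap) mismatches. Returns the overlap length
## (0 if none).
.adapterOverlap <- function(read, adapter, minOverlap, maxMismatchFrac) {
    la <- nchar(adapter)
    lr <- nchar(read)
    if (min(la, lr) < minOverlap) return(0L)
    for (ov in seq(min(la, lr), minOverlap)) {
        a <- substr(adapter, la - ov + 1L, la)
        r <- substr(read, 1L, ov)
        mism <- sum(utf8ToInt(a) != utf8ToInt(r))
        if (mism <= floor(maxMismatchFrac * ov))
            return(ov)
    }
    0L
}

#' Remove the 5' adapter from reads
#'
#' Looks for the adapter at the read 5' end: either the full adapter
#' followed by insert, or (for reads starting mid-adapter) a suffix of the
#' adapter of length at least \code{minOverlap} as the read prefix, allowing
#' up to \code{floor(maxMismatchFrac * overlap)} mismatches. The longest
#' qualifying overlap is removed. Reads with no match pass through
#' unmodified (alignment adjudicates them later); reads shorter than
#' \code{minLength} after trimming are discarded.
#'
#' @param seqs Character vector of read sequences (or \code{DNAStringSet}).
#' @param adapter Adapter sequence (default \code{TGGAATTCTCGGGTGCCAAGGC}).
#' @param minOverlap Minimum adapter overlap to trim (default 4).
#' @param maxMismatchFrac Mismatch tolerance as a fraction of the overlap
#'   (default 0.1).
#' @param minLength Minimum read length to keep after trimming (default 15).
#' @return A list with \code{seq} (trimmed sequence, \code{NA} for discarded
#'   reads) and \code{status} (factor: \code{trimmed}, \code{untrimmed},
#'   \code{discarded_short}), both parallel to the input.
#' @examples
#' trimAdapter(paste0("TGGAATTCTCGGGTGCCAAGGC", strrep("ACGT", 10)))
#' @export
trimAdapter <- function(seqs, adapter = DEFAULT_ADAPTER, minOverlap = 4L,
                        maxMismatchFrac = 0.1, minLength = 15L) {
    seqs <- as.character(seqs)
    stopifnot(nzchar(adapter), !grepl("[^ACGT]", adapter))
    n <- length(seqs)
    out <- seqs
    status <- rep("untrimmed", n)
    la <- nchar(adapter)
    ## fast path: exact full-adapter prefix
    exact <- substr(seqs, 1L, la) == adapter & nchar(seqs) >= la
    out[exact] <- substr(seqs[exact], la + 1L, nchar(seqs[exact]))
    status[exact] <- "trimmed"
    for (i in which(!exact)) {
        ov <- .adapterOverlap(seqs[i], adapter, minOverlap, maxMismatchFrac)
        if (ov > 0L) {
            out[i] <- substr(seqs[i], ov + 1L, nchar(seqs[i]))
            status[i] <- "trimmed"
        }
    }
    short <- status == "trimmed" & nchar(out) < minLength
    out[short] <- NA_character_
    status[short] <- "discarded_short"
    list(seq = out,
         status = factor(status,
                         levels = c("trimmed", "untrimmed", "discarded_short")))
}

#' Collapse identical sequences into unique reads with counts
#'
#' @param seqs Character vector of adapter-free, sense-oriented sequences.
#' @return A \code{data.frame} with columns \code{seq} and \code{count},
#'   ordered by descending count then lexicographically; the counts sum to
#'   \code{length(seqs)}.
#' @examples
#' collapseReads(c("ACGT", "ACGT", "ACGTT"))
#' @export
collapseReads <- function(seqs) {
    if (length(seqs) == 0L)
        return(data.frame(seq = character(0), count = integer(0),
                          stringsAsFactors = FALSE))
    tab <- table(seqs)
    df <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$seq), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Run the full preprocessing stage
#'
#' Quality filter, adapter trimming, length filter, reverse complement into
#' sense orientation, and collapsing, with read-count accounting: the input
#' read count always equals quality-discarded + length-discarded + the sum
#' of unique-read counts.
#'
#' @param reads A \code{QualityScaledDNAStringSet} (see
#'   \code{\link{readFastqReads}}).
#' @param adapter,minOverlap,maxMismatchFrac,minLength Passed to
#'   \code{\link{trimAdapter}}.
#' @param qThreshold,qualityMethod Passed to \code{\link{qualityFilter}}.
#' @return A list with \code{unique_reads} (data.frame \code{seq},
#'   \code{count}; sense orientation) and \code{stats} (named list:
#'   \code{n_input}, \code{n_quality_discarded}, \code{n_length_discarded},
#'   \code{n_untrimmed}, \code{n_kept}).
#' @export
preprocessReads <- function(reads, adapter = DEFAULT_ADAPTER,
                            qThreshold = 30, qualityMethod = "mean",
                            minOverlap = 4L, maxMismatchFrac = 0.1,
                            minLength = 15L) {
    n_input <- length(reads)
    filtered <- qualityFilter(reads, qThreshold, qualityMethod)
    n_qdisc <- attr(filtered, "n_discarded")
    tr <- trimAdapter(as.character(filtered), adapter, minOverlap,
                      maxMismatchFrac, minLength)
    keep <- !is.na(tr$seq)
    n_ldisc <- sum(!keep)
    sense <- .rc(tr$seq[keep])
    uniq <- collapseReads(sense)
    list(unique_reads = uniq,
         stats = list(n_input = n_input,
                      n_quality_discarded = n_qdisc,
                      n_length_discarded = n_ldisc,
                      n_untrimmed = sum(tr$status == "untrimmed"),
                      n_kept = sum(keep)))
}
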