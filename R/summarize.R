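## Aggregation into the reporting tables:
##  * per-gene category percentages over all reads assigned to the gene
##    (the "percent of all reads aligned to this tRNA" convention),
##  * shares of the -, +C, +CC, +CCA forms among 3'-end-processed reads,
##  * a processing-efficiency partition (processed / trailer / trimmed),
##  * a mapping-rate QC record.

#' Tabulate 3'-end calls into per-gene category counts
#'
#' @param calls data.frame of calls (from \code{\link{classifyReads}});
#'   rows with \code{gene_id} \code{NA} (unmapped) or \code{"AMBIGUOUS"}
#'   are excluded here and accounted for in QC.
#' @param libraryId Library label attached to every row.
#' @return data.frame with one row per gene: \code{library_id},
#'   \code{gene_id}, one column per category (counts weighted by read
#'   multiplicity) and \code{total_assigned}; genes ordered
#'   lexicographically.
#' @export
tabulateCalls <- function(calls, libraryId = "library1") {
    keep <- !is.na(calls$gene_id) & calls$gene_id != "AMBIGUOUS"
    calls <- calls[keep, , drop = FALSE]
    genes <- sort(unique(calls$gene_id))
    out <- data.frame(library_id = rep(libraryId, length(genes)),
                      gene_id = genes, stringsAsFactors = FALSE)
    for (cat_ in END_CATEGORIES) out[[cat_]] <- integer(nrow(out))
    for (g in seq_along(genes)) {
        sub <- calls[calls$gene_id == genes[g], , drop = FALSE]
        agg <- tapply(sub$count, factor(sub$category, levels = END_CATEGORIES),
                      sum, default = 0L)
        out[g, END_CATEGORIES] <- as.integer(agg)
    }
    out$total_assigned <- as.integer(rowSums(out[, END_CATEGORIES, drop = FALSE]))
    out
}

#' Per-gene category percentages over all assigned reads
#'
#' Each category count is normalized to the total number of reads assigned
#' to that gene and expressed as a percentage. Full precision is kept;
#' \code{round} to one decimal for display.
#'
#' @param counts data.frame from \code{\link{tabulateCalls}}.
#' @return data.frame with the same rows and the category columns replaced
#'   by percentages (rows with \code{total_assigned == 0} become \code{NA}).
#' @export
table1Percentages <- function(counts) {
    out <- counts
    for (cat_ in END_CATEGORIES) {
        out[[cat_]] <- ifelse(counts$total_assigned > 0L,
                              100 * counts[[cat_]] / counts$total_assigned,
                              NA_real_)
    }
    out
}

#' Shares of the -, +C, +CC, +CCA forms among end-processed reads
#'
#' Renormalizes the four end-processed forms (nothing added, +C, +CC, +CCA)
#' to sum to 100, leaving trailer-containing, trimmed and oligo-adenylated
#' reads out of the denominator. Because the operation is a ratio, it gives
#' identical results whether the inputs are raw counts or percentages
#' (scale invariance).
#'
#' @param x Named numeric (or data.frame row set) holding values for
#'   \code{PROCESSED_EXACT}, \code{PLUS_C}, \code{PLUS_CC}, \code{PLUS_CCA};
#'   a data.frame from \code{\link{tabulateCalls}} or
#'   \code{\link{table1Percentages}} is processed row-wise.
#' @return For a vector input, a named numeric of four shares summing to
#'   100; for a data.frame, the data.frame with the four columns replaced by
#'   shares (other category columns dropped) and \code{NA} rows where all
#'   four inputs are zero (with a warning).
#' @examples
#' endProcessedShares(c(PROCESSED_EXACT = 0.6, PLUS_C = 7.6,
#'                      PLUS_CC = 36.9, PLUS_CCA = 12.9))
#' @export
endProcessedShares <- function(x) {
    forms <- END_PROCESSED_CATEGORIES
    if (is.data.frame(x)) {
        out <- x[, setdiff(names(x), setdiff(END_CATEGORIES, forms)),
                 drop = FALSE]
        denom <- rowSums(x[, forms, drop = FALSE])
        if (any(denom == 0, na.rm = TRUE))
            warning("all end-processed forms are zero for some gene(s); NA emitted",
                    call. = FALSE)
        for (f in forms)
            out[[f]] <- ifelse(denom > 0, 100 * x[[f]] / denom, NA_real_)
        return(out)
    }
    v <- x[forms]
    if (anyNA(v)) stop("missing end-processed form values", call. = FALSE)
    denom <- sum(v)
    if (denom == 0) {
        warning("all end-processed forms are zero; NA emitted", call. = FALSE)
        return(stats::setNames(rep(NA_real_, 4L), forms))
    }
    100 * v / denom
}

#' Processing-efficiency partition
#'
#' Fractions of reads per gene that are 3'-end processed (nothing added or
#' +C/+CC/+CCA), trailer-containing, trimmed, or oligo-adenylated; OTHER
#' absorbs the remainder so the fractions sum to at most 1.
#'
#' @param counts data.frame from \code{\link{tabulateCalls}}.
#' @return data.frame with columns \code{library_id}, \code{gene_id},
#'   \code{end_processed}, \code{trailer_containing}, \code{trimmed},
#'   \code{oligo_a}, \code{other}, \code{total_assigned}.
#' @export
processingEfficiency <- function(counts) {
    tot <- counts$total_assigned
    frac <- function(v) ifelse(tot > 0L, v / tot, NA_real_)
    data.frame(library_id = counts$library_id,
               gene_id = counts$gene_id,
               end_processed = frac(rowSums(
                   counts[, END_PROCESSED_CATEGORIES, drop = FALSE])),
               trailer_containing = frac(counts$TRAILER),
               trimmed = frac(counts$TRIMMED),
               oligo_a = frac(counts$OLIGO_A),
               other = frac(counts$OTHER),
               total_assigned = tot,
               stringsAsFactors = FALSE)
}

#' Mapping-rate QC
#'
#' Reports the fraction of preprocessed reads uniquely assigned to a target
#' gene and warns (never fails) when it falls below the expected rate for a
#' well-behaved targeted library (96\% by default).
#'
#' @param nProcessed Number of reads entering alignment.
#' @param nAssigned Number of reads uniquely assigned.
#' @param nAmbiguous Number of reads with tied best scores across genes.
#' @param expectation Warning threshold on the assigned fraction
#'   (default 0.96).
#' @return A list with \code{n_processed}, \code{n_assigned},
#'   \code{n_ambiguous}, \code{assigned_fraction} (NA when no reads) and
#'   \code{below_expectation}.
#' @export
mappingQC <- function(nProcessed, nAssigned, nAmbiguous = 0L,
                      expectation = 0.96) {
    stopifnot(nProcessed >= nAssigned + nAmbiguous)
    frac <- if (nProcessed > 0L) nAssigned / nProcessed else NA_real_
    below <- isTRUE(frac < expectation)
    if (below)
        warning(sprintf(
            "mapping rate %.1f%% is below the %.0f%% expected for a targeted library",
            100 * frac, 100 * expectation), call. = FALSE)
    list(n_processed = nProcessed, n_assigned = nAssigned,
         n_ambiguous = nAmbiguous, assigned_fraction = frac,
         below_expectation = below)
}

#' Summarize one library's calls into all reporting tables
#'
#' @param calls data.frame of calls from \code{\link{classifyReads}}.
#' @param libraryId Library label.
#' @param intronFilter If \code{TRUE} (default) the end-processed shares are
#'   computed over reads that both overlap the intron and are end-processed,
#'   matching the targeted design's focus on intron-containing end-matured
#'   precursors; set \code{FALSE} to drop the intron requirement.
#' @return A list with \code{counts}, \code{percentages},
#'   \code{end_processed_shares}, \code{efficiency}.
#' @export
summarizeLibrary <- function(calls, libraryId = "library1",
                             intronFilter = TRUE) {
    counts <- tabulateCalls(calls, libraryId)
    pct <- table1Percentages(counts)
    shares_input <- if (intronFilter) {
        tabulateCalls(calls[!is.na(calls$intron_containing) &
                            calls$intron_containing, , drop = FALSE],
                      libraryId)
    } else counts
    ## keep gene set aligned with the full table
    shares_input <- shares_input[match(counts$gene_id, shares_input$gene_id), ,
                                 drop = FALSE]
    shares_input$gene_id <- counts$gene_id
    shares_input$library_id <- counts$library_id
    for (cat_ in c(END_CATEGORIES, "total_assigned"))
        shares_input[[cat_]][is.na(shares_input[[cat_]])] <- 0L
    shares <- endProcessedShares(shares_input)
    list(counts = counts,
         percentages = pct,
         end_processed_shares = shares,
         efficiency = processingEfficiency(counts))
}
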