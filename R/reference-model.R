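## Gene-model loading and precursor-reference construction.
##
## The annotation dialect is a flat BED-like TSV with 7 columns:
##   chrom  start  end  gene_id  score  strand  introns
## Intervals on disk are 0-based half-open (BED convention). The `introns`
## column lists gene-relative intron intervals as comma-separated
## "start-end" pairs (again 0-based half-open, relative to the SENSE gene
## start), or "." for none. Internally everything is converted to 1-based
## closed IRanges.

.parseIsotype <- function(gene_id) {
    m <- regmatches(gene_id, regexec("^t([A-Za-z])\\(([ACGTU]{3})\\)", gene_id))[[1]]
    if (length(m) == 3L) paste0(m[2], "(", m[3], ")") else NA_character_
}

.checkAlphabet <- function(s, what = "sequence") {
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    if (length(bad) && nzchar(bad))
        stop(sprintf("%s contains non-ACGTN character '%s'", what, bad),
             call. = FALSE)
    invisible(s)
}

#' Construct a tRNA gene model from sequences
#'
#' Low-level constructor; \code{\link{loadGeneModels}} is the usual entry
#' point. All sequences are given in sense orientation.
#'
#' @param geneId Gene identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param geneStart,geneEnd Genomic gene interval, 1-based closed.
#' @param geneSeq,leaderFlank,trailerFlank Sense-orientation sequences
#'   (character or \code{DNAString}).
#' @param intronRanges Gene-relative \code{IRanges} (1-based closed), or
#'   \code{NULL} for an intron-less gene.
#' @return A validated \code{TRNAGeneModel}.
#' @examples
#' newTRNAGeneModel("tX(AAA)demo", "chrT", "+", 5, 15,
#'                  "CCCGGGTTTAA", "AAAA", "ACCC", IRanges::IRanges(4, 6))
#' @export
newTRNAGeneModel <- function(geneId, chrom, strand, geneStart, geneEnd,
                             geneSeq, leaderFlank = "", trailerFlank = "",
                             intronRanges = NULL) {
    if (is.null(intronRanges)) intronRanges <- IRanges()
    new("TRNAGeneModel",
        gene_id = geneId,
        isotype = .parseIsotype(geneId),
        chrom = chrom,
        strand = strand,
        gene_interval = IRanges(as.integer(geneStart), as.integer(geneEnd)),
        intron_intervals = intronRanges,
        gene_seq = DNAString(as.character(geneSeq)),
        leader_flank = DNAString(as.character(leaderFlank)),
        trailer_flank = DNAString(as.character(trailerFlank)))
}

.parseIntronField <- function(field, row) {
    if (is.na(field) || field == "." || field == "")
        return(IRanges())
    parts <- strsplit(field, ",", fixed = TRUE)[[1]]
    se <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
    if (any(lengths(se) != 3L))
        stop(sprintf("annotation row %d: malformed intron field '%s'",
                     row, field), call. = FALSE)
    s0 <- as.integer(vapply(se, `[`, "", 2L))
    e0 <- as.integer(vapply(se, `[`, "", 3L))
    if (any(s0 >= e0))
        stop(sprintf("annotation row %d: intron interval start >= end", row),
             call. = FALSE)
    IRanges(s0 + 1L, e0)  # 0-based half-open -> 1-based closed
}

#' Load tRNA gene models from a genome and annotation table
#'
#' Reads a (multi-record) genome FASTA and a BED-like annotation table and
#' builds sense-oriented gene models with genomic leader and trailer flanks.
#' For minus-strand genes all sequences are reverse-complemented so that
#' every model reads 5' leader, gene body (introns retained), 3' trailer in
#' the sense of the transcript. Flanks are clipped at chromosome ends.
#'
#' @param genomeFasta Path to the genome FASTA.
#' @param annotation Path to the 7-column annotation TSV (see Details), with
#'   0-based half-open intervals and a gene-relative intron column
#'   (\code{"start-end"} pairs, comma-separated, or \code{"."}).
#' @param leaderLen Leader flank length to extract (default 30).
#' @param trailerLen Trailer flank length to extract (default 50). 50 nt of
#'   trailer places any 3'-extended read end for 100-nt reads.
#' @return Named list of \code{TRNAGeneModel} objects, in annotation order.
#' @seealso \code{\link{buildPrecursorReference}}, \code{\link{writeGeneAnnotation}}
#' @export
loadGeneModels <- function(genomeFasta, annotation, leaderLen = 30L,
                           trailerLen = 50L) {
    genome <- readDNAStringSet(genomeFasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    tab <- utils::read.table(annotation, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "gene_id",
                                           "score", "strand", "introns"),
                             colClasses = c("character", "integer", "integer",
                                            "character", "character",
                                            "character", "character"))
    models <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        if (!row$chrom %in% names(genome))
            stop(sprintf("annotation row %d (%s): chromosome '%s' not in FASTA",
                         i, row$gene_id, row$chrom), call. = FALSE)
        if (row$start >= row$end)
            stop(sprintf("annotation row %d (%s): interval start >= end",
                         i, row$gene_id), call. = FALSE)
        chrlen <- length(genome[[row$chrom]])
        gs <- row$start + 1L  # 1-based closed
        ge <- row$end
        if (gs < 1L || ge > chrlen)
            stop(sprintf("annotation row %d (%s): interval outside chromosome",
                         i, row$gene_id), call. = FALSE)
        gene_genomic <- as.character(genome[[row$chrom]][gs:ge])
        ## the sense leader lies upstream on plus-strand genes but downstream
        ## on minus-strand genes, so the genomic extraction lengths swap
        up_len <- if (row$strand == "-") trailerLen else leaderLen
        dn_len <- if (row$strand == "-") leaderLen else trailerLen
        up_start <- max(1L, gs - up_len)
        up <- if (gs > 1L) as.character(genome[[row$chrom]][up_start:(gs - 1L)]) else ""
        dn_end <- min(chrlen, ge + dn_len)
        dn <- if (ge < chrlen) as.character(genome[[row$chrom]][(ge + 1L):dn_end]) else ""
        introns <- .parseIntronField(row$introns, i)
        if (length(introns) && (any(end(introns) > ge - gs + 1L)))
            stop(sprintf("annotation row %d (%s): intron beyond gene length",
                         i, row$gene_id), call. = FALSE)
        if (row$strand == "+") {
            gene_seq <- gene_genomic; leader <- up; trailer <- dn
        } else if (row$strand == "-") {
            gene_seq <- .rc(gene_genomic)
            leader <- .rc(dn)   # sense leader is downstream on the genome
            trailer <- .rc(up)
        } else {
            stop(sprintf("annotation row %d (%s): bad strand '%s'",
                         i, row$gene_id, row$strand), call. = FALSE)
        }
        models[[i]] <- newTRNAGeneModel(row$gene_id, row$chrom, row$strand,
                                        gs, ge, gene_seq, leader, trailer,
                                        introns)
    }
    names(models) <- tab$gene_id
    models
}

#' Write gene models back to the annotation format
#'
#' Emits the same 7-column BED-like TSV that \code{\link{loadGeneModels}}
#' reads (0-based half-open intervals, gene-relative introns), so that a
#' load/write/reload round trip reproduces identical models given the same
#' genome FASTA and flank lengths.
#'
#' @param models List of \code{TRNAGeneModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(models, path) {
    rows <- vapply(models, function(m) {
        ir <- m@intron_intervals
        intr <- if (length(ir) == 0L) "." else
            paste(sprintf("%d-%d", start(ir) - 1L, end(ir)), collapse = ",")
        paste(m@chrom, start(m@gene_interval) - 1L, end(m@gene_interval),
              m@gene_id, "0", m@strand, intr, sep = "\t")
    }, "")
    writeLines(rows, path)
    invisible(path)
}

#' Build a precursor reference from a gene model
#'
#' Concatenates \code{leader_flank + gene_seq + trailer_flank} and records
#' where the gene sits; \code{gene_last} (position of the last gene base) is
#' the coordinate against which all signed 3'-end offsets are measured.
#'
#' @param model A \code{TRNAGeneModel}.
#' @return A \code{PrecursorReference}.
#' @examples
#' buildPrecursorReference(exampleGeneModel())
#' @export
buildPrecursorReference <- function(model) {
    stopifnot(is(model, "TRNAGeneModel"))
    validObject(model)
    lead <- length(model@leader_flank)
    seq <- DNAString(paste0(as.character(model@leader_flank),
                            as.character(model@gene_seq),
                            as.character(model@trailer_flank)))
    ir <- model@intron_intervals
    new("PrecursorReference",
        gene_id = model@gene_id,
        seq = seq,
        gene_start = lead + 1L,
        gene_last = lead + length(model@gene_seq),
        intron_offsets = IRanges(start(ir) + lead, end(ir) + lead))
}

#' @rdname buildPrecursorReference
#' @param models Named list of \code{TRNAGeneModel}.
#' @return \code{buildPrecursorReferences}: named list of
#'   \code{PrecursorReference}.
#' @export
buildPrecursorReferences <- function(models) {
    refs <- lapply(models, buildPrecursorReference)
    names(refs) <- vapply(models, geneId, "")
    refs
}

#' A toy gene model used in examples
#'
#' An 11-nt "gene" with one 3-nt intron on a 19-nt toy chromosome; handy for
#' demonstrating coordinate conventions.
#'
#' @return A \code{TRNAGeneModel}.
#' @examples
#' exampleGeneModel()
#' @export
exampleGeneModel <- function() {
    newTRNAGeneModel("tX(AAA)demo", "chrT", "+", 5, 15,
                     "CCCGGGTTTAA", "AAAA", "ACCC", IRanges(4, 6))
}
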