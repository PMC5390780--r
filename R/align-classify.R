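## Alignment and 3'-end classification.
##
## Each unique sense read is aligned locally (Smith-Waterman, affine gaps,
## blastn-style +1/-3, gap 2+k) against every precursor reference; the best
## gene wins, ties are AMBIGUOUS. The 3' call walks back from the
## alignment's 3' terminus peeling terminal non-matching columns into the
## suffix, then greedily extends the templated end forward while the read
## continues to match the reference (maximal templated extent); whatever
## read tail remains is the genomically non-encoded suffix, and the signed
## end offset is measured against the last gene base.

.substMatrix <- function(scoring) {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(-scoring@mismatch_penalty, 5, 5,
                dimnames = list(letters, letters))
    diag(m)[1:4] <- scoring@match_reward
    m["N", "N"] <- -scoring@mismatch_penalty  # N never matches anything
    m
}

.refDNAString <- function(ref) {
    if (is(ref, "PrecursorReference")) ref@seq else DNAString(as.character(ref))
}

#' Optimal local alignment of reads against one reference
#'
#' Smith-Waterman-equivalent local alignment with affine gap costs
#' (a gap of length k costs \code{gap_open + k * gap_extend}), computed by
#' \code{Biostrings::pairwiseAlignment}. Word-size seeding of the original
#' BLAST-based analysis is treated as an optimization only: the result is
#' always the optimal local alignment.
#'
#' @param seqs Character vector or \code{DNAStringSet} of read sequences.
#' @param ref A \code{PrecursorReference}, \code{DNAString} or string.
#' @param scoring An \code{AlignmentScoring}.
#' @param scoreOnly If \code{TRUE} return only the numeric scores.
#' @return A \code{PairwiseAlignments} object, or numeric scores.
#' @export
localAlign <- function(seqs, ref, scoring = alignmentScoring(),
                       scoreOnly = FALSE) {
    pairwiseAlignment(DNAStringSet(as.character(seqs)), .refDNAString(ref),
                      type = "local",
                      substitutionMatrix = .substMatrix(scoring),
                      gapOpening = scoring@gap_open,
                      gapExtension = scoring@gap_extend,
                      scoreOnly = scoreOnly)
}

## Best hit per read across references. Returns assignment data.frame and,
## for each reference, the PairwiseAlignments of the reads assigned to it.
.alignBest <- function(seqs, refs, scoring) {
    stopifnot(length(refs) > 0L)
    gene_ids <- vapply(refs, geneId, "")
    S <- vapply(refs, function(r) localAlign(seqs, r, scoring, scoreOnly = TRUE),
                numeric(length(seqs)))
    if (length(seqs) == 1L) S <- matrix(S, nrow = 1L)
    best <- apply(S, 1L, max)
    nbest <- rowSums(S == best)
    which_best <- max.col(S, ties.method = "first")
    gene <- gene_ids[which_best]
    gene[nbest > 1L] <- "AMBIGUOUS"
    gene[best < scoring@min_score] <- NA_character_
    alns <- vector("list", length(refs))
    names(alns) <- gene_ids
    for (g in seq_along(refs)) {
        idx <- which(!is.na(gene) & gene == gene_ids[g])
        if (length(idx))
            alns[[g]] <- list(idx = idx,
                              pa = localAlign(seqs[idx], refs[[g]], scoring))
    }
    list(assignment = data.frame(gene_id = gene, score = best,
                                 stringsAsFactors = FALSE),
         alns = alns)
}

#' Align unique reads to precursor references and pick the best gene
#'
#' @param seqs Character vector of unique sense read sequences.
#' @param refs Named list of \code{PrecursorReference}.
#' @param scoring An \code{AlignmentScoring}.
#' @return A data.frame parallel to \code{seqs} with columns
#'   \code{gene_id} (\code{NA} = unmapped, \code{"AMBIGUOUS"} = tied best
#'   score across genes), \code{score}, and for uniquely assigned reads the
#'   alignment intervals \code{read_start}, \code{read_end},
#'   \code{ref_start}, \code{ref_end} (1-based closed) and
#'   \code{n_mismatch}.
#' @export
alignReads <- function(seqs, refs, scoring = alignmentScoring()) {
    ab <- .alignBest(as.character(seqs), refs, scoring)
    out <- ab$assignment
    out$read_start <- out$read_end <- out$ref_start <- out$ref_end <- NA_integer_
    out$n_mismatch <- NA_integer_
    for (g in names(ab$alns)) {
        a <- ab$alns[[g]]
        if (is.null(a)) next
        pa <- a$pa
        out$read_start[a$idx] <- start(pattern(pa))
        out$read_end[a$idx] <- end(pattern(pa))
        out$ref_start[a$idx] <- start(subject(pa))
        out$ref_end[a$idx] <- end(subject(pa))
        out$n_mismatch[a$idx] <- Biostrings::nmismatch(pa)
    }
    out
}

## Extract (templated end position on reference, non-templated suffix) for
## one read given its alignment columns. `apc`/`asc` are the aligned pattern
## and subject as character vectors (with "-" gaps), or NULL for a clean
## (gap- and mismatch-free) alignment.
.extractCall <- function(readSeq, refChars, ps, pe, ss, se, apc, asc) {
    L <- nchar(readSeq)
    tail_after <- if (pe < L) substr(readSeq, pe + 1L, L) else ""
    if (is.null(apc)) {
        pos <- se
        suffix <- tail_after
    } else {
        is_match <- apc == asc & apc != "-" & apc %in% c("A", "C", "G", "T")
        k <- if (any(is_match)) max(which(is_match)) else 0L
        if (k == 0L)
            return(list(pos = NA_integer_, suffix = readSeq))
        ncol_ <- length(apc)
        peeled <- if (k < ncol_) {
            pc <- apc[(k + 1L):ncol_]
            paste(pc[pc != "-"], collapse = "")
        } else ""
        pos <- ss - 1L + sum(asc[seq_len(k)] != "-")
        suffix <- paste0(peeled, tail_after)
    }
    ## greedy templated extension: read bases explained by the reference
    ## stay templated (maximal templated extent)
    nref <- length(refChars)
    while (nzchar(suffix) && pos < nref) {
        b <- substr(suffix, 1L, 1L)
        rb <- refChars[pos + 1L]
        if (rb != b || !rb %in% c("A", "C", "G", "T")) break
        pos <- pos + 1L
        suffix <- substr(suffix, 2L, nchar(suffix))
    }
    list(pos = pos, suffix = suffix)
}

## Opposite ("added-first") policy: peel terminal templated bases back into
## the suffix when they could equally be non-templated additions: first a
## terminal templated A-run, then templated C/CC/CCA sitting immediately
## after the gene end.
.addedFirstTransform <- function(pos, suffix, refChars, gene_last, min_pos) {
    if (is.na(pos)) return(list(pos = pos, suffix = suffix))
    while (pos >= min_pos && pos >= 1L && refChars[pos] == "A") {
        suffix <- paste0("A", suffix)
        pos <- pos - 1L
    }
    j <- pos - gene_last
    if (j >= 1L && j <= 3L && pos >= min_pos) {
        templ <- paste(refChars[(gene_last + 1L):pos], collapse = "")
        if (templ == substr("CCA", 1L, j)) {
            suffix <- paste0(templ, suffix)
            pos <- gene_last
        }
    }
    list(pos = pos, suffix = suffix)
}

#' Locate a read's 3' end relative to the gene end
#'
#' Aligns a single read to one precursor reference and extracts the signed
#' end offset (0 = last templated base coincides with the last gene base,
#' positive = extends into the trailer, negative = ends inside the gene
#' body) and the genomically non-encoded 3' suffix, under the
#' maximal-templated-extent rule (terminal alignment mismatches are peeled
#' into the suffix; suffix bases the genome can explain are re-absorbed as
#' templated).
#'
#' @param readSeq A single sense read sequence.
#' @param ref A \code{PrecursorReference}.
#' @param scoring An \code{AlignmentScoring}.
#' @param addedFirst If \code{TRUE}, boundary bases that match both the
#'   genomic trailer and a plausible non-templated addition (terminal A-run;
#'   C/CC/CCA just after the gene end) are assigned to the suffix instead of
#'   the template.
#' @return A list with \code{end_offset}, \code{suffix} and \code{category}.
#' @examples
#' ref <- buildPrecursorReference(exampleGeneModel())
#' callThreePrime("CCCGGGTTTAACCA", ref)  # gene body + non-templated CCA
#' @export
callThreePrime <- function(readSeq, ref, scoring = alignmentScoring(),
                           addedFirst = FALSE) {
    stopifnot(is(ref, "PrecursorReference"))
    pa <- localAlign(readSeq, ref, scoring)
    refChars <- strsplit(as.character(ref@seq), "")[[1]]
    ps <- start(pattern(pa)); pe <- end(pattern(pa))
    ss <- start(subject(pa)); se <- end(subject(pa))
    perfect <- score(pa) == (pe - ps + 1L) * scoring@match_reward &&
        (se - ss) == (pe - ps)
    if (perfect) {
        ext <- .extractCall(readSeq, refChars, ps, pe, ss, se, NULL, NULL)
    } else {
        apc <- strsplit(as.character(pattern(pa)), "")[[1]]
        asc <- strsplit(as.character(subject(pa)), "")[[1]]
        ext <- .extractCall(readSeq, refChars, ps, pe, ss, se, apc, asc)
    }
    if (addedFirst)
        ext <- .addedFirstTransform(ext$pos, ext$suffix, refChars,
                                    ref@gene_last, ss)
    if (is.na(ext$pos))
        return(list(end_offset = NA_integer_, suffix = ext$suffix,
                    category = "OTHER"))
    off <- ext$pos - ref@gene_last
    list(end_offset = off, suffix = ext$suffix,
         category = classifySuffix(off, ext$suffix))
}

#' Does an alignment overlap the intron?
#'
#' The targeted library design selects fragments primed inside the intron,
#' so genuine precursor reads should overlap it; reads that do not are still
#' counted but flagged, and are excluded from the end-processed share
#' denominator when the intron filter is on.
#'
#' @param refStart,refEnd Alignment interval(s) on the reference (1-based
#'   closed); vectorized.
#' @param ref A \code{PrecursorReference}.
#' @param minOverlap Minimum overlap in bases (default 6).
#' @return Logical vector. Genes without introns give \code{FALSE} with a
#'   one-time warning.
#' @export
checkIntron <- function(refStart, refEnd, ref, minOverlap = 6L) {
    ir <- ref@intron_offsets
    if (length(ir) == 0L) {
        warning(sprintf("gene %s has no introns; intron flag is FALSE",
                        ref@gene_id), call. = FALSE)
        return(rep(FALSE, length(refStart)))
    }
    res <- rep(FALSE, length(refStart))
    for (k in seq_along(ir)) {
        ov <- pmin(refEnd, end(ir)[k]) - pmax(refStart, start(ir)[k]) + 1L
        res <- res | (ov >= minOverlap)
    }
    res
}

#' Classify a 3'-end call into the reporting categories
#'
#' Applies the category rules in fixed decision order; exactly one category
#' is returned per call. A full or partial CCA counts only when it sits
#' immediately after the gene end (\code{endOffset == 0}); an oligo(A) run
#' of one or more terminal adenosines dominates, optionally on top of a
#' C/CC/CCA at the gene end; empty suffixes split into exactly processed
#' (offset 0), trailer-containing (positive) and trimmed (negative);
#' anything else, including suffixes containing N, is OTHER.
#'
#' @param endOffset Integer vector of signed end offsets.
#' @param suffix Character vector of non-templated suffixes.
#' @return Character vector of categories (see \code{END_CATEGORIES}).
#' @examples
#' classifySuffix(c(0, 0, 0, 0, 12, -5, 4), c("CCA", "CC", "C", "", "", "A", "CCA"))
#' @export
classifySuffix <- function(endOffset, suffix) {
    n <- max(length(endOffset), length(suffix))
    endOffset <- rep_len(as.integer(endOffset), n)
    suffix <- rep_len(as.character(suffix), n)
    res <- rep(NA_character_, n)
    bad <- (grepl("[^ACGT]", suffix) & nzchar(suffix)) | is.na(endOffset)
    res[bad] <- "OTHER"
    empty <- !nzchar(suffix)
    rem <- sub("A+$", "", suffix)
    has_a_run <- suffix != rem
    take <- function(cond, lab) res[is.na(res) & cond] <<- lab
    take(endOffset == 0L & suffix == "CCA", "PLUS_CCA")
    take(has_a_run & (rem == "" |
         (endOffset == 0L & rem %in% c("C", "CC", "CCA"))), "OLIGO_A")
    take(endOffset == 0L & suffix == "CC", "PLUS_CC")
    take(endOffset == 0L & suffix == "C", "PLUS_C")
    take(empty & endOffset == 0L, "PROCESSED_EXACT")
    take(empty & endOffset > 0L, "TRAILER")
    take(empty & endOffset < 0L, "TRIMMED")
    res[is.na(res)] <- "OTHER"
    res
}

#' Per-gene boundary-ambiguity flags
#'
#' A gene whose genomic trailer begins with C, CC or CCA cannot distinguish
#' a templated trailer base from a non-templated CCA addition at the
#' sequence level; such genes are flagged so users can interpret their
#' calls with the templated-first/added-first policy in mind.
#'
#' @param refs Named list of \code{PrecursorReference} (or models).
#' @return Named logical vector.
#' @export
geneAmbiguityFlags <- function(refs) {
    vapply(refs, function(r) {
        tr <- if (is(r, "PrecursorReference")) {
            s <- as.character(r@seq)
            substr(s, r@gene_last + 1L, min(nchar(s), r@gene_last + 3L))
        } else as.character(trailerFlank(r))
        substr(tr, 1L, 1L) == "C"
    }, NA)
}

#' Align, locate and classify the 3' ends of unique reads
#'
#' The main per-library classification stage: aligns every unique read to
#' all precursor references, resolves the best gene (ties are AMBIGUOUS and
#' excluded from per-gene tables), extracts the signed end offset and
#' non-templated suffix, flags intron overlap, and assigns one category per
#' read.
#'
#' @param uniqueReads data.frame with \code{seq}, \code{count} (from
#'   \code{\link{preprocessReads}} / \code{\link{collapseReads}}).
#' @param refs Named list of \code{PrecursorReference}.
#' @param scoring An \code{AlignmentScoring}.
#' @param addedFirst Boundary policy (see \code{\link{callThreePrime}}).
#' @param intronMinOverlap Minimum intron overlap (default 6).
#' @return A list with
#'   \code{calls}: data.frame (\code{seq}, \code{count}, \code{gene_id},
#'   \code{score}, \code{end_offset}, \code{suffix},
#'   \code{intron_containing}, \code{category}, \code{boundary_ambiguous});
#'   \code{stats}: named list with weighted read counts
#'   (\code{n_reads_total}, \code{n_reads_assigned},
#'   \code{n_reads_unmapped}, \code{n_reads_ambiguous},
#'   \code{n_boundary_ambiguous});
#'   \code{gene_ambiguity}: per-gene trailer ambiguity flags.
#' @export
classifyReads <- function(uniqueReads, refs, scoring = alignmentScoring(),
                          addedFirst = FALSE, intronMinOverlap = 6L) {
    seqs <- uniqueReads$seq
    counts <- uniqueReads$count
    n <- length(seqs)
    calls <- data.frame(seq = seqs, count = counts,
                        gene_id = NA_character_, score = NA_real_,
                        end_offset = NA_integer_, suffix = NA_character_,
                        intron_containing = NA, category = NA_character_,
                        boundary_ambiguous = FALSE,
                        stringsAsFactors = FALSE)
    if (n == 0L) {
        return(list(calls = calls,
                    stats = list(n_reads_total = 0L, n_reads_assigned = 0L,
                                 n_reads_unmapped = 0L, n_reads_ambiguous = 0L,
                                 n_boundary_ambiguous = 0L),
                    gene_ambiguity = geneAmbiguityFlags(refs)))
    }
    ab <- .alignBest(seqs, refs, scoring)
    calls$gene_id <- ab$assignment$gene_id
    calls$score <- ab$assignment$score
    mm <- scoring@match_reward
    for (g in names(ab$alns)) {
        a <- ab$alns[[g]]
        if (is.null(a)) next
        ref <- refs[[match(g, vapply(refs, geneId, ""))]]
        refChars <- strsplit(as.character(ref@seq), "")[[1]]
        pa <- a$pa
        ps <- start(pattern(pa)); pe <- end(pattern(pa))
        ss <- start(subject(pa)); se <- end(subject(pa))
        sc <- score(pa)
        perfect <- sc == (pe - ps + 1L) * mm & (se - ss) == (pe - ps)
        apc_all <- asc_all <- NULL
        if (any(!perfect)) {
            apc_all <- strsplit(as.character(pattern(pa))[!perfect], "")
            asc_all <- strsplit(as.character(subject(pa))[!perfect], "")
        }
        imap <- cumsum(!perfect)
        for (j in seq_along(a$idx)) {
            i <- a$idx[j]
            if (perfect[j]) {
                ext <- .extractCall(seqs[i], refChars, ps[j], pe[j], ss[j],
                                    se[j], NULL, NULL)
            } else {
                ext <- .extractCall(seqs[i], refChars, ps[j], pe[j], ss[j],
                                    se[j], apc_all[[imap[j]]],
                                    asc_all[[imap[j]]])
            }
            alt <- .addedFirstTransform(ext$pos, ext$suffix, refChars,
                                        ref@gene_last, ss[j])
            differs <- !identical(alt, ext[c("pos", "suffix")]) &&
                !(is.na(ext$pos) && is.na(alt$pos))
            if (addedFirst) ext <- alt
            calls$boundary_ambiguous[i] <- differs
            if (is.na(ext$pos)) {
                calls$category[i] <- "OTHER"
                calls$suffix[i] <- ext$suffix
                next
            }
            calls$end_offset[i] <- ext$pos - ref@gene_last
            calls$suffix[i] <- ext$suffix
            calls$category[i] <- classifySuffix(calls$end_offset[i], ext$suffix)
            calls$intron_containing[i] <-
                checkIntron(ss[j], ext$pos, ref, intronMinOverlap)
        }
    }
    unmapped <- is.na(calls$gene_id)
    ambiguous <- !unmapped & calls$gene_id == "AMBIGUOUS"
    assigned <- !unmapped & !ambiguous
    list(calls = calls,
         stats = list(n_reads_total = sum(counts),
                      n_reads_assigned = sum(counts[assigned]),
                      n_reads_unmapped = sum(counts[unmapped]),
                      n_reads_ambiguous = sum(counts[ambiguous]),
                      n_boundary_ambiguous =
                          sum(counts[calls$boundary_ambiguous])),
         gene_ambiguity = geneAmbiguityFlags(refs))
}
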