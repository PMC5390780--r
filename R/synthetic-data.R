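## Ground-truth library simulation: the inverse of the targeted library
## prep. A sense RNA fragment starts inside the intron and ends at the
## (possibly modified) 3' terminus; the sequenced read is the 5' adapter
## followed by the reverse complement of the fragment, truncated or padded
## with templated upstream sequence to the read length, plus substitution
## errors and a two-level Phred quality model.
##
## RNG consumption order (fixed for cross-platform determinism): gene draw,
## category draw, per-(gene,category) endpoint draws in gene-then-category
## order, low-quality mask, per-read error counts, error positions/bases.

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.kmerSet <- function(s, k = 8L) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s)))
}

#' Generate synthetic intron-containing tRNA-like fixture genes
#'
#' Builds five synthetic stand-ins for the intron-containing target genes
#' (isoleucine-UAU, phenylalanine-GAA, lysine-UUU, leucine-CAA,
#' tryptophan-CCA families), each 80-110 nt with one 14-32 nt intron,
#' pairwise 8-mer-distinct gene bodies, and genomic trailers that start with
#' G or T so that non-templated additions at the gene end are never
#' genomically templated (ambiguity-free by default). With
#' \code{ambiguous = TRUE} the first gene's trailer instead begins
#' \code{"CCA"}, for boundary-policy tests. Two genes are placed on the
#' minus strand to exercise strand handling.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param ambiguous Emit one gene with a CCA-leading trailer (default
#'   \code{FALSE}).
#' @return A list with \code{models} (named list of \code{TRNAGeneModel},
#'   leader 30 nt / trailer 50 nt), \code{genome} (named character vector,
#'   one synthetic chromosome) and \code{annotation} (data.frame in the
#'   on-disk column layout).
#' @seealso \code{\link{writeFixtureFiles}}
#' @export
makeFixtureGenes <- function(seed = 1L, ambiguous = FALSE) {
    set.seed(as.integer(seed))
    ids <- c("tI(UAU)S1", "tF(GAA)S1", "tK(UUU)S1", "tL(CAA)S1", "tW(CCA)S1")
    strands <- c("+", "-", "+", "-", "+")
    n <- length(ids)
    genes <- introns <- leaders <- trailers <- vector("list", n)
    kmers <- vector("list", n)
    for (i in seq_len(n)) {
        for (attempt in seq_len(100L)) {
            gene_len <- sample(80:110, 1L)
            e3 <- sample(20:35, 1L)
            intron_len <- sample(14:32, 1L)
            if (gene_len - e3 - intron_len < 10L) next
            g <- .randSeq(gene_len)
            km <- .kmerSet(g)
            clash <- FALSE
            for (j in seq_len(i - 1L))
                if (length(intersect(km, kmers[[j]]))) { clash <- TRUE; break }
            if (clash) next
            genes[[i]] <- g
            kmers[[i]] <- km
            introns[[i]] <- IRanges(gene_len - e3 - intron_len + 1L,
                                    gene_len - e3)
            break
        }
        if (is.null(genes[[i]]))
            stop("could not generate 8-mer-distinct fixture genes")
        leaders[[i]] <- .randSeq(40L)
        tr <- .randSeq(60L)
        if (ambiguous && i == 1L) {
            substr(tr, 1L, 3L) <- "CCA"
        } else {
            substr(tr, 1L, 1L) <- sample(c("G", "T"), 1L)
        }
        trailers[[i]] <- tr
    }
    spacer <- function() .randSeq(20L)
    chrom_parts <- list(spacer())
    offset <- 20L
    models <- vector("list", n)
    ann <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      score = character(0), strand = character(0),
                      introns = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        context <- paste0(leaders[[i]], genes[[i]], trailers[[i]])
        block <- if (strands[i] == "+") context else .rc(context)
        gene_len <- nchar(genes[[i]])
        if (strands[i] == "+") {
            gs <- offset + 40L + 1L
        } else {
            gs <- offset + 60L + 1L
        }
        ge <- gs + gene_len - 1L
        ir <- introns[[i]]
        models[[i]] <- newTRNAGeneModel(
            ids[i], "chrSyn", strands[i], gs, ge, genes[[i]],
            substr(leaders[[i]], 11L, 40L),   # last 30 nt of the context leader
            substr(trailers[[i]], 1L, 50L),   # first 50 nt of the context trailer
            ir)
        ann <- rbind(ann, data.frame(
            chrom = "chrSyn", start = gs - 1L, end = ge, gene_id = ids[i],
            score = "0", strand = strands[i],
            introns = sprintf("%d-%d", start(ir) - 1L, end(ir)),
            stringsAsFactors = FALSE))
        chrom_parts <- c(chrom_parts, block, spacer())
        offset <- offset + nchar(block) + 20L
    }
    names(models) <- ids
    list(models = models,
         genome = c(chrSyn = paste(unlist(chrom_parts), collapse = "")),
         annotation = ann)
}

#' Write fixture genome and annotation to files
#'
#' @param fixture Result of \code{\link{makeFixtureGenes}}.
#' @param dir Output directory (created if missing).
#' @return Named character vector with paths \code{genome} and
#'   \code{annotation}.
#' @export
writeFixtureFiles <- function(fixture, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    writeXStringSet(DNAStringSet(fixture$genome), fa)
    bed <- file.path(dir, "genes.tsv")
    with(fixture$annotation,
         writeLines(paste(chrom, start, end, gene_id, score, strand, introns,
                          sep = "\t"), bed))
    c(genome = fa, annotation = bed)
}

## Sample (cut position on the reference, non-templated suffix) for one
## category. Enforces that the reference base immediately after the cut
## differs from the first suffix base, so the truth decomposition is the
## unique maximal-templated one; positions are resampled (bounded) where
## the constraint can be satisfied by moving the cut.
.sampleEndpoints <- function(ref, category, n, config) {
    refChars <- strsplit(as.character(ref@seq), "")[[1]]
    glast <- ref@gene_last
    Tlen <- min(config@trailer_len_max, length(ref@seq) - glast)
    Dmax <- config@trim_depth_max
    p_geom <- 1 / config@oligoa_mean
    next_ok <- function(cut, first_base)
        cut >= length(refChars) | refChars[pmin(cut + 1L, length(refChars))] != first_base
    resample <- function(draw_cut, first_base, n) {
        cut <- draw_cut(n)
        for (it in seq_len(100L)) {
            bad <- !next_ok(cut, first_base)
            if (!any(bad)) break
            cut[bad] <- draw_cut(sum(bad))
        }
        if (any(!next_ok(cut, first_base)))
            stop(sprintf("cannot place %s reads without templated ambiguity for %s",
                         category, ref@gene_id), call. = FALSE)
        cut
    }
    fixed_cut_check <- function(first_base) {
        if (refChars[glast + 1L] == first_base)
            stop(sprintf(
                "gene %s trailer begins with '%s'; %s at the gene end is ambiguous",
                ref@gene_id, first_base, category), call. = FALSE)
    }
    cut <- integer(n); suffix <- character(n)
    if (category == "PROCESSED_EXACT") {
        cut[] <- glast
    } else if (category == "TRAILER") {
        cut <- glast + sample.int(Tlen, n, replace = TRUE)
    } else if (category == "TRIMMED") {
        cut <- glast - sample.int(Dmax, n, replace = TRUE)
    } else if (category %in% c("PLUS_C", "PLUS_CC", "PLUS_CCA")) {
        sfx <- c(PLUS_C = "C", PLUS_CC = "CC", PLUS_CCA = "CCA")[[category]]
        fixed_cut_check("C")
        cut[] <- glast
        suffix[] <- sfx
    } else if (category == "OLIGO_A") {
        ## a non-templated suffix must not be absorbable by the aligner:
        ## reject placements where some suffix prefix ending in a match
        ## scores >= 0 against the reference continuation (the local
        ## alignment would then extend past the truth cut point)
        absorbable <- function(cut, sfx) {
            v <- strsplit(sfx, "")[[1]]
            s <- 0L
            for (j in seq_along(v)) {
                if (cut + j > length(refChars)) break
                hit <- refChars[cut + j] == v[j]
                s <- s + if (hit) 1L else -3L
                if (hit && s >= 0L) return(TRUE)
            }
            FALSE
        }
        base <- sample(c("exact", "ccaprefix", "trailer", "trimmed"), n,
                       replace = TRUE)
        run <- 1L + stats::rgeom(n, p_geom)
        pre <- character(n)
        i_cca <- base == "ccaprefix"
        pre[i_cca] <- sample(c("C", "CC", "CCA"), sum(i_cca), replace = TRUE)
        ## "CC" + a single A would read as a full CCA, which is a different
        ## category by definition; require a run of >= 2 there
        repeat {
            bad <- pre == "CC" & run == 1L
            if (!any(bad)) break
            run[bad] <- 1L + stats::rgeom(sum(bad), p_geom)
        }
        if (any(base == "exact") && refChars[glast + 1L] == "A")
            fixed_cut_check("A")
        if (any(i_cca)) fixed_cut_check("C")
        cut[] <- glast
        i_tr <- base == "trailer"
        if (any(i_tr))
            cut[i_tr] <- resample(function(m) glast + sample.int(Tlen, m, TRUE),
                                  "A", sum(i_tr))
        i_tm <- base == "trimmed"
        if (any(i_tm))
            cut[i_tm] <- resample(function(m) glast - sample.int(Dmax, m, TRUE),
                                  "A", sum(i_tm))
        suffix <- paste0(pre, strrep("A", run))
        for (i in seq_len(n)) {
            for (it in seq_len(100L)) {
                if (!absorbable(cut[i], suffix[i])) break
                ## movable cuts: redraw the position (and the run); fixed
                ## cuts at the gene end: redraw the run length only
                if (base[i] == "trailer")
                    cut[i] <- resample(function(m) glast + sample.int(Tlen, m, TRUE),
                                       "A", 1L)
                else if (base[i] == "trimmed")
                    cut[i] <- resample(function(m) glast - sample.int(Dmax, m, TRUE),
                                       "A", 1L)
                k <- 1L + stats::rgeom(1L, p_geom)
                if (pre[i] == "CC" && k == 1L) k <- 2L
                suffix[i] <- paste0(pre[i], strrep("A", k))
            }
            if (absorbable(cut[i], suffix[i]))
                stop(sprintf(
                    "cannot place an unambiguous oligo(A) read for %s",
                    ref@gene_id), call. = FALSE)
        }
    } else {
        stop(sprintf("cannot simulate category '%s'", category), call. = FALSE)
    }
    list(cut = cut, suffix = suffix)
}

#' Simulate one sense RNA fragment with known truth
#'
#' Draws a fragment for one gene and category: the 5' end is uniform inside
#' the intron (the intron-primed selection of the library design) and the 3'
#' end is placed per category, with any non-templated suffix appended.
#'
#' @param ref A \code{PrecursorReference}.
#' @param category One of the simulatable categories (see
#'   \code{SIM_CATEGORIES}).
#' @param config A \code{SimulationConfig} (sampling parameters).
#' @return A list with \code{fragment} (sense sequence), \code{frag_start}
#'   (reference coordinate of the fragment 5' end) and \code{truth} (list:
#'   \code{gene_id}, \code{true_category}, \code{true_end_offset},
#'   \code{true_suffix}).
#' @export
simulateFragment <- function(ref, category,
                             config = simulationConfig(geneId(ref))) {
    ep <- .sampleEndpoints(ref, category, 1L, config)
    ir <- ref@intron_offsets
    frag_start <- start(ir)[1L] + sample.int(width(ir)[1L], 1L) - 1L
    templated <- as.character(ref@seq[frag_start:ep$cut])
    list(fragment = paste0(templated, ep$suffix),
         frag_start = frag_start,
         truth = list(gene_id = ref@gene_id,
                      true_category = category,
                      true_end_offset = ep$cut - ref@gene_last,
                      true_suffix = ep$suffix))
}

#' Wrap a sense fragment as a sequencing read
#'
#' The read is \code{adapter + reverseComplement(fragment)}, truncated to
#' \code{read_length} (reads anchor at the RNA 3' end, so the 3'-most part
#' of the fragment is retained) or padded with templated 5' extension of the
#' fragment when a reference and fragment start are supplied. Substitution
#' errors are applied at the configured rate and a constant Phred string is
#' attached (low quality with probability \code{quality_low_frac}).
#'
#' @param fragment Sense fragment sequence.
#' @param config A \code{SimulationConfig}.
#' @param ref Optional \code{PrecursorReference} for templated padding.
#' @param fragStart Reference coordinate of the fragment 5' end (required
#'   for padding).
#' @return A list with \code{seq} and \code{qual} (Phred+33 string).
#' @export
wrapAsRead <- function(fragment, config, ref = NULL, fragStart = NULL) {
    w <- config@read_length - nchar(config@adapter)
    if (nchar(fragment) < w && !is.null(ref) && !is.null(fragStart)) {
        pad <- w - nchar(fragment)
        pad_start <- max(1L, fragStart - pad)
        if (pad_start < fragStart)
            fragment <- paste0(as.character(ref@seq[pad_start:(fragStart - 1L)]),
                               fragment)
    }
    core <- .rc(fragment)
    read <- paste0(config@adapter, core)
    read <- substr(read, 1L, config@read_length)
    read <- .applyErrors(read, config@substitution_error)
    q <- if (stats::runif(1L) < config@quality_low_frac)
        config@quality_low else config@quality_high
    list(seq = read, qual = strrep(intToUtf8(q + 33L), nchar(read)))
}

## Vectorized substitution errors at a fixed per-base rate.
.applyErrors <- function(reads, rate) {
    if (rate <= 0) return(reads)
    len <- nchar(reads)
    n_err <- stats::rbinom(length(reads), len, rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0L)) {
        pos <- sample.int(len[i], n_err[i])
        for (p in pos) {
            orig <- substr(reads[i], p, p)
            repl <- sample(setdiff(bases, orig), 1L)
            substr(reads[i], p, p) <- repl
        }
    }
    reads
}

#' Simulate a targeted pre-tRNA sequencing library with ground truth
#'
#' Draws \code{n_reads} reads (gene by \code{gene_mixture}, then 3'-end
#' category by the gene's \code{category_mixture} row), constructs each read
#' as the library prep would, and returns the reads together with a truth
#' table row-aligned with the FASTQ. Identical seeds give identical output.
#'
#' @param config A \code{SimulationConfig}; gene names must match
#'   \code{models}.
#' @param models Named list of \code{TRNAGeneModel} (or
#'   \code{PrecursorReference}).
#' @param fastqPath,truthPath Optional output paths (FASTQ, TSV).
#' @return A list with \code{reads} (\code{QualityScaledDNAStringSet}) and
#'   \code{truth} (data.frame: \code{read_id}, \code{gene_id},
#'   \code{true_category}, \code{true_end_offset}, \code{true_suffix},
#'   \code{sense_seq} - the error-free sense sequence the preprocessed read
#'   should reproduce).
#' @export
simulateLibrary <- function(config, models, fastqPath = NULL,
                            truthPath = NULL) {
    validObject(config)
    set.seed(config@seed)
    gene_ids <- names(config@gene_mixture)
    refs <- lapply(models[gene_ids], function(m)
        if (is(m, "PrecursorReference")) m else buildPrecursorReference(m))
    n <- config@n_reads
    w <- config@read_length - nchar(config@adapter)
    gene <- sample(gene_ids, n, replace = TRUE, prob = config@gene_mixture)
    category <- character(n)
    cut <- integer(n)
    suffix <- character(n)
    for (g in gene_ids) {
        idx <- which(gene == g)
        if (!length(idx)) next
        category[idx] <- sample(SIM_CATEGORIES, length(idx), replace = TRUE,
                                prob = config@category_mixture[g, ])
        for (cat_ in SIM_CATEGORIES) {
            ci <- idx[category[idx] == cat_]
            if (!length(ci)) next
            ep <- .sampleEndpoints(refs[[g]], cat_, length(ci), config)
            cut[ci] <- ep$cut
            suffix[ci] <- ep$suffix
        }
    }
    ## 3'-anchored effective sense sequence: last `w` bases of the padded /
    ## truncated fragment (suffix plus as much templated context as fits)
    sense <- character(n)
    for (g in gene_ids) {
        idx <- which(gene == g)
        if (!length(idx)) next
        refseq <- as.character(refs[[g]]@seq)
        ns <- pmin(nchar(suffix[idx]), w)
        sfx <- substr(suffix[idx], pmax(1L, nchar(suffix[idx]) - ns + 1L),
                      nchar(suffix[idx]))
        tl <- w - ns
        ts <- pmax(1L, cut[idx] - tl + 1L)
        templ <- substring(refseq, ts, cut[idx])
        sense[idx] <- paste0(templ, sfx)
    }
    reads <- paste0(config@adapter, .rc(sense))
    reads <- substr(reads, 1L, config@read_length)
    low <- stats::runif(n) < config@quality_low_frac
    reads <- .applyErrors(reads, config@substitution_error)
    qchar <- ifelse(low, intToUtf8(config@quality_low + 33L),
                    intToUtf8(config@quality_high + 33L))
    quals <- strrep(qchar, nchar(reads))
    ids <- paste0("read", seq_len(n))
    qreads <- QualityScaledDNAStringSet(DNAStringSet(reads),
                                        PhredQuality(quals))
    names(qreads) <- ids
    glast <- vapply(refs, function(r) r@gene_last, 0L)
    truth <- data.frame(read_id = ids, gene_id = gene,
                        true_category = category,
                        true_end_offset = cut - glast[gene],
                        true_suffix = suffix,
                        sense_seq = sense,
                        stringsAsFactors = FALSE)
    if (!is.null(fastqPath)) writeFastqReads(qreads, fastqPath)
    if (!is.null(truthPath))
        utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    list(reads = qreads, truth = truth)
}
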