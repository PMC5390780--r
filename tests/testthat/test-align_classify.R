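test_that("identity reads align full-length with the expected score", {
    fix <- makeFixtureGenes(seed = 6)
    refs <- buildPrecursorReferences(fix$models)
    ref <- refs[[2]]
    read <- as.character(refSeq(ref)[21:60])
    hits <- alignReads(read, refs)
    expect_identical(hits$gene_id, geneId(ref))
    expect_identical(hits$score, 40)
    expect_identical(hits$read_start, 1L)
    expect_identical(hits$read_end, 40L)
    expect_identical(hits$ref_start, 21L)
    expect_identical(hits$ref_end, 60L)
    expect_identical(hits$n_mismatch, 0L)
})

test_that("reads below the score threshold are unmapped", {
    fix <- makeFixtureGenes(seed = 6)
    refs <- buildPrecursorReferences(fix$models)
    hits <- alignReads(strrep("N", 30), refs)
    expect_true(is.na(hits$gene_id))
})

test_that("tied best scores across genes give an AMBIGUOUS verdict", {
    fix <- makeFixtureGenes(seed = 6)
    refs <- buildPrecursorReferences(fix$models)
    twin <- refs[[1]]
    twin@gene_id <- "tQ(AAA)S9"
    both <- c(refs[1], list(`tQ(AAA)S9` = twin))
    read <- as.character(refSeq(refs[[1]])[31:70])
    hits <- alignReads(read, both)
    expect_identical(hits$gene_id, "AMBIGUOUS")
    single <- alignReads(read, refs[1])
    expect_identical(single$gene_id, geneId(refs[[1]]))
})

test_that("local alignment scores equal the brute-force DP oracle", {
    set.seed(31)
    scoring <- alignmentScoring()
    for (i in 1:100) {
        read <- random_seq(sample(10:40, 1))
        ref <- random_seq(sample(40:120, 1))
        expect_identical(localAlign(read, ref, scoring, scoreOnly = TRUE),
                         oracle_local_score(read, ref))
    }
})

test_that("3' calls recover offset and suffix under maximal templated extent", {
    fix <- makeFixtureGenes(seed = 6)
    refs <- buildPrecursorReferences(fix$models)
    ref <- refs[[1]]
    glast <- end(geneRange(ref))
    istart <- start(intronRanges(ref))
    body <- as.character(refSeq(ref)[istart:glast])

    # exactly processed
    expect_identical(callThreePrime(body, ref)[c("end_offset", "category")],
                     list(end_offset = 0L, category = "PROCESSED_EXACT"))
    # non-templated CC at the gene end (trailer starts G/T by construction)
    cc <- callThreePrime(paste0(body, "CC"), ref)
    expect_identical(cc$end_offset, 0L)
    expect_identical(cc$suffix, "CC")
    expect_identical(cc$category, "PLUS_CC")
    # oligo(A) on a trimmed 3' end: pick a gene whose base before the cut
    # point is not A so the A-run is unambiguously non-templated
    ref2 <- NULL
    for (r in refs) {
        rc <- strsplit(as.character(refSeq(r)), "")[[1]]
        if (rc[end(geneRange(r)) - 2L] != "A") { ref2 <- r; break }
    }
    body2 <- as.character(refSeq(ref2)[start(intronRanges(ref2)):
                                       (end(geneRange(ref2)) - 3L)])
    oa <- callThreePrime(paste0(body2, "AAAA"), ref2)
    expect_identical(oa$end_offset, -3L)
    expect_identical(oa$suffix, "AAAA")
    expect_identical(oa$category, "OLIGO_A")
    # trailer-containing
    tr <- callThreePrime(as.character(refSeq(ref)[istart:(glast + 8L)]), ref)
    expect_identical(tr$end_offset, 8L)
    expect_identical(tr$category, "TRAILER")
})

test_that("terminal mismatches are peeled into the suffix", {
    fix <- makeFixtureGenes(seed = 6)
    refs <- buildPrecursorReferences(fix$models)
    ref <- refs[[3]]
    glast <- end(geneRange(ref))
    body <- as.character(refSeq(ref)[start(intronRanges(ref)):glast])
    # an internal substitution error is tolerated, the call is unchanged
    mut <- body
    substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "G" else "A"
    call <- callThreePrime(mut, ref)
    expect_identical(call$end_offset, 0L)
    expect_identical(call$category, "PROCESSED_EXACT")
})

test_that("intron overlap flagging uses the minimum-overlap rule", {
    ref <- make_intron_ref()
    ir <- intronRanges(ref)
    expect_true(checkIntron(start(ir) - 4L, end(ir) + 4L, ref))   # spans intron
    expect_false(checkIntron(end(ir) - 1L, end(ir) + 10L, ref))   # overlap 2 < 6
    expect_false(checkIntron(end(ir) + 1L, end(ir) + 12L, ref))   # abuts only
    expect_true(checkIntron(end(ir) - 5L, end(ir) + 4L, ref))     # overlap 6
    noint <- pretRNAends::buildPrecursorReference(
        newTRNAGeneModel("tN(AAA)noi", "c", "+", 1, 20, strrep("ACGT", 5)))
    expect_warning(res <- checkIntron(1L, 10L, noint), "no introns")
    expect_false(res)
})

test_that("suffix classification matches the exhaustive truth table", {
    suffixes <- all_suffixes(4)
    expect_length(suffixes, 341L)
    for (off in c(-2L, 0L, 3L)) {
        expected <- vapply(suffixes, oracle_classify, "", off = off)
        got <- classifySuffix(rep(off, length(suffixes)), suffixes)
        expect_identical(unname(got), unname(expected),
                         label = sprintf("offset %d", off))
    }
    # hand-audited spot values
    expect_identical(classifySuffix(c(0, 0, 0, 0), c("CCA", "CC", "C", "")),
                     c("PLUS_CCA", "PLUS_CC", "PLUS_C", "PROCESSED_EXACT"))
    expect_identical(classifySuffix(c(12, 12, -5), c("", "AA", "A")),
                     c("TRAILER", "OLIGO_A", "OLIGO_A"))
    expect_identical(classifySuffix(4, "CCA"), "OTHER")  # CCA not at gene end
    expect_identical(classifySuffix(c(0, 0), c("CCAAA", "CCG")),
                     c("OLIGO_A", "OTHER"))
    expect_identical(classifySuffix(0, "CCNA"), "OTHER")
})

test_that("templated trailer bases win under the default policy and flip under added-first", {
    fix <- makeFixtureGenes(seed = 8, ambiguous = TRUE)
    refs <- buildPrecursorReferences(fix$models)
    amb <- geneAmbiguityFlags(refs)
    expect_identical(sum(amb), 1L)
    ref <- refs[[which(amb)]]
    glast <- end(geneRange(ref))
    # read carrying exactly the genomic CCA that begins the trailer
    read <- as.character(refSeq(ref)[start(intronRanges(ref)):(glast + 3L)])
    uniq <- data.frame(seq = read, count = 1L, stringsAsFactors = FALSE)
    def <- classifyReads(uniq, refs)
    expect_identical(def$calls$category, "TRAILER")
    expect_identical(def$calls$end_offset, 3L)
    expect_true(def$calls$boundary_ambiguous)
    expect_identical(def$stats$n_boundary_ambiguous, 1L)
    added <- classifyReads(uniq, refs, addedFirst = TRUE)
    expect_identical(added$calls$category, "PLUS_CCA")
    expect_identical(added$calls$end_offset, 0L)
    # ambiguity-free fixtures raise no flags
    expect_identical(sum(geneAmbiguityFlags(
        buildPrecursorReferences(makeFixtureGenes(seed = 8)$models))), 0L)
})

test_that("category partition: every assigned read gets exactly one category", {
    fix <- makeFixtureGenes(seed = 9)
    cfg <- simulationConfig(names(fix$models), nReads = 1500, seed = 33)
    lib <- simulateLibrary(cfg, fix$models)
    pre <- suppressMessages(preprocessReads(lib$reads))
    cls <- classifyReads(pre$unique_reads, buildPrecursorReferences(fix$models))
    assigned <- !is.na(cls$calls$gene_id) & cls$calls$gene_id != "AMBIGUOUS"
    expect_false(anyNA(cls$calls$category[assigned]))
    counts <- tabulateCalls(cls$calls)
    expect_identical(sum(counts$total_assigned), cls$stats$n_reads_assigned)
    per_gene <- rowSums(counts[, pretRNAends:::END_CATEGORIES, drop = FALSE])
    expect_identical(as.integer(per_gene), counts$total_assigned)
})
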