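test_that("fixture genes are valid, deterministic and 8-mer distinct", {
    fix <- makeFixtureGenes(seed = 1)
    expect_length(fix$models, 5L)
    for (m in fix$models) {
        expect_true(validObject(m, test = TRUE))
        expect_identical(length(intronRanges(m)), 1L)
        expect_true(width(intronRanges(m)) >= 14 && width(intronRanges(m)) <= 32)
        gl <- length(geneSeq(m))
        expect_true(gl >= 80 && gl <= 110)
        # trailers start G/T: additions at the gene end are never templated
        expect_true(substr(as.character(trailerFlank(m)), 1, 1) %in% c("G", "T"))
    }
    kmers <- lapply(fix$models, function(m) {
        s <- as.character(geneSeq(m))
        unique(substring(s, 1:(nchar(s) - 7), 8:nchar(s)))
    })
    for (i in 1:4) for (j in (i + 1):5)
        expect_length(intersect(kmers[[i]], kmers[[j]]), 0L)
    # byte-identical regeneration
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeFixtureFiles(makeFixtureGenes(seed = 5), d1)
    writeFixtureFiles(makeFixtureGenes(seed = 5), d2)
    expect_identical(readLines(file.path(d1, "genome.fa")),
                     readLines(file.path(d2, "genome.fa")))
    expect_identical(readLines(file.path(d1, "genes.tsv")),
                     readLines(file.path(d2, "genes.tsv")))
})

test_that("the ambiguous variant emits exactly one CCA-leading trailer", {
    fix <- makeFixtureGenes(seed = 1, ambiguous = TRUE)
    starts <- vapply(fix$models, function(m)
        substr(as.character(trailerFlank(m)), 1, 3), "")
    expect_identical(sum(starts == "CCA"), 1L)
})

test_that("simulated fragments satisfy their truth records", {
    fix <- makeFixtureGenes(seed = 2)
    refs <- buildPrecursorReferences(fix$models)
    ref <- refs[[1]]
    cfg <- simulationConfig(names(fix$models), seed = 3)
    set.seed(3)
    fr <- simulateFragment(ref, "PLUS_CCA", cfg)
    expect_identical(fr$truth$true_end_offset, 0L)
    expect_identical(fr$truth$true_suffix, "CCA")
    glast <- end(geneRange(ref))
    expect_identical(fr$fragment,
                     paste0(as.character(refSeq(ref)[fr$frag_start:glast]), "CCA"))
    # fragment starts inside the intron
    expect_true(fr$frag_start >= start(intronRanges(ref)) &&
                fr$frag_start <= end(intronRanges(ref)))
    fr2 <- simulateFragment(ref, "PROCESSED_EXACT", cfg)
    expect_identical(fr2$truth$true_suffix, "")
    fr3 <- simulateFragment(ref, "OLIGO_A", cfg)
    expect_match(fr3$truth$true_suffix, "A$")
    expect_gte(nchar(gsub("[^A]*", "", fr3$truth$true_suffix)), 1L)
})

test_that("wrapping a fragment is the exact inverse of preprocessing", {
    fix <- makeFixtureGenes(seed = 2)
    refs <- buildPrecursorReferences(fix$models)
    ref <- refs[[2]]
    cfg <- simulationConfig(names(fix$models), substitutionError = 0,
                            qualityLowFrac = 0, seed = 4)
    set.seed(4)
    fr <- simulateFragment(ref, "TRAILER", cfg)
    wrapped <- wrapAsRead(fr$fragment, cfg, ref, fr$frag_start)
    expect_identical(nchar(wrapped$seq), 100L)
    reads <- make_qreads(wrapped$seq, wrapped$qual)
    pre <- suppressMessages(preprocessReads(reads))
    recovered <- pre$unique_reads$seq
    # the recovered sense sequence and the fragment agree at the 3' end
    # (the read window is 3'-anchored)
    k <- min(nchar(recovered), nchar(fr$fragment))
    expect_identical(substr(recovered, nchar(recovered) - k + 1, nchar(recovered)),
                     substr(fr$fragment, nchar(fr$fragment) - k + 1,
                            nchar(fr$fragment)))
    # long fragments keep their 3'-most portion
    long_frag <- paste0(random_seq(90), fr$fragment)
    w2 <- wrapAsRead(long_frag, cfg)
    expect_identical(nchar(w2$seq), 100L)
    core <- reverseComplementStrings(substr(w2$seq, 23, 100))
    expect_identical(core, substr(long_frag, nchar(long_frag) - 77,
                                  nchar(long_frag)))
})

test_that("library simulation is deterministic and honors its mixtures", {
    fix <- makeFixtureGenes(seed = 2)
    cfg <- simulationConfig(names(fix$models), nReads = 400, seed = 7)
    a <- simulateLibrary(cfg, fix$models)
    b <- simulateLibrary(cfg, fix$models)
    expect_identical(as.character(a$reads), as.character(b$reads))
    expect_identical(a$truth, b$truth)
    # FASTQ bytes identical too
    d <- withr::local_tempdir()
    f1 <- file.path(d, "a.fastq"); f2 <- file.path(d, "b.fastq")
    simulateLibrary(cfg, fix$models, fastqPath = f1)
    simulateLibrary(cfg, fix$models, fastqPath = f2)
    expect_identical(readLines(f1), readLines(f2))

    # degenerate mixtures
    cm <- stats::setNames(c(0, 0, 0, 0, 1, 0, 0),
                          pretRNAends:::SIM_CATEGORIES)
    cfg_cca <- simulationConfig(names(fix$models), categoryMixture = cm,
                                nReads = 120, seed = 8)
    lib_cca <- simulateLibrary(cfg_cca, fix$models)
    expect_true(all(lib_cca$truth$true_category == "PLUS_CCA"))
    cfg_one <- simulationConfig(names(fix$models),
                                geneMixture = c(1, 0, 0, 0, 0),
                                nReads = 120, seed = 9)
    lib_one <- simulateLibrary(cfg_one, fix$models)
    expect_true(all(lib_one$truth$gene_id == names(fix$models)[1]))
})

test_that("truth records are consistent with the call invariants", {
    fix <- makeFixtureGenes(seed = 2)
    cfg <- simulationConfig(names(fix$models), nReads = 600, seed = 10)
    lib <- simulateLibrary(cfg, fix$models)
    tr <- lib$truth
    expect_identical(classifySuffix(tr$true_end_offset, tr$true_suffix),
                     tr$true_category)
})
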