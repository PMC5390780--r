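test_that("gene models load with correct sequences and strand handling", {
    paths <- write_toy_genome()
    models <- loadGeneModels(paths["genome"], paths["annotation"],
                             leaderLen = 4, trailerLen = 4)
    m <- models[[1]]
    expect_identical(geneId(m), "tX(AAA)toy")
    expect_identical(as.character(geneSeq(m)), "CCCGGGTTTAA")
    expect_identical(as.character(leaderFlank(m)), "AAAA")
    expect_identical(as.character(trailerFlank(m)), "ACCC")
    expect_identical(start(intronRanges(m)), 4L)  # 0-based [3,6) on disk
    expect_identical(end(intronRanges(m)), 6L)

    minus <- loadGeneModels(paths["genome"],
                            write_toy_genome(strand = "-")["annotation"],
                            leaderLen = 4, trailerLen = 4)[[1]]
    expect_identical(as.character(geneSeq(minus)), "TTAAACCCGGG")
    expect_identical(as.character(leaderFlank(minus)), "GGGT")  # rc of downstream ACCC
    expect_identical(as.character(trailerFlank(minus)), "TTTT")
})

test_that("malformed annotations are rejected with informative errors", {
    paths <- write_toy_genome()
    dir <- dirname(paths["annotation"])
    bad1 <- file.path(dir, "bad1.tsv")
    writeLines("chrMissing\t4\t15\tgX\t0\t+\t.", bad1)
    expect_error(loadGeneModels(paths["genome"], bad1, 4, 4), "chrMissing")
    bad2 <- file.path(dir, "bad2.tsv")
    writeLines("chrT\t15\t4\tgX\t0\t+\t.", bad2)
    expect_error(loadGeneModels(paths["genome"], bad2, 4, 4), "start >= end")
    bad3 <- file.path(dir, "bad3.tsv")
    writeLines("chrT\t4\t15\tgX\t0\t+\t3-20", bad3)  # intron beyond gene
    expect_error(loadGeneModels(paths["genome"], bad3, 4, 4), "intron")
})

test_that("precursor references obey the concatenation contract", {
    ref <- buildPrecursorReference(exampleGeneModel())
    expect_identical(as.character(refSeq(ref)), "AAAACCCGGGTTTAAACCC")
    expect_identical(start(geneRange(ref)), 5L)   # 0-based gene_start 4
    expect_identical(end(geneRange(ref)), 15L)    # 0-based gene_end 15
    expect_identical(start(intronRanges(ref)), 8L)  # 0-based [7,10)
    expect_identical(end(intronRanges(ref)), 10L)

    # gene at chromosome end: empty trailer, gene_last == length(seq)
    m <- newTRNAGeneModel("tY(AAA)end", "chrT", "+", 5, 15,
                          "CCCGGGTTTAA", "AAAA", "")
    ref2 <- buildPrecursorReference(m)
    expect_identical(end(geneRange(ref2)), length(refSeq(ref2)))
})

test_that("references contain the gene body exactly once at gene_start", {
    fix <- makeFixtureGenes(seed = 3)
    for (m in fix$models) {
        ref <- buildPrecursorReference(m)
        hits <- gregexpr(as.character(geneSeq(m)), as.character(refSeq(ref)),
                         fixed = TRUE)[[1]]
        expect_identical(as.integer(hits), start(geneRange(ref)))
    }
})

test_that("annotation write/reload round trip reproduces identical models", {
    fix <- makeFixtureGenes(seed = 2)
    dir <- withr::local_tempdir()
    paths <- writeFixtureFiles(fix, dir)
    reread <- loadGeneModels(paths["genome"], paths["annotation"],
                             leaderLen = 30, trailerLen = 50)
    ann2 <- file.path(dir, "roundtrip.tsv")
    writeGeneAnnotation(reread, ann2)
    again <- loadGeneModels(paths["genome"], ann2, 30, 50)
    expect_identical(names(again), names(fix$models))
    for (id in names(fix$models)) {
        for (acc in list(geneSeq, leaderFlank, trailerFlank))
            expect_identical(as.character(acc(again[[id]])),
                             as.character(acc(fix$models[[id]])))
        expect_identical(intronRanges(again[[id]]),
                         intronRanges(fix$models[[id]]))
        expect_identical(geneStrand(again[[id]]),
                         geneStrand(fix$models[[id]]))
    }
})

test_that("strand flip is an involution on gene sequences", {
    set.seed(5)
    for (i in 1:20) {
        s <- random_seq(sample(40:120, 1))
        expect_identical(reverseComplementStrings(reverseComplementStrings(s)), s)
    }
})

test_that("model validity catches bad intron intervals", {
    expect_error(newTRNAGeneModel("tX(AAA)v", "c", "+", 5, 15,
                                  "CCCGGGTTTAA", "", "",
                                  IRanges::IRanges(4, 20)),
                 "intron")
    expect_error(newTRNAGeneModel("tX(AAA)v", "c", "+", 5, 15,
                                  "CCCGGGTTTAA", "", "",
                                  IRanges::IRanges(c(2, 4), c(5, 8))),
                 "disjoint")
})
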