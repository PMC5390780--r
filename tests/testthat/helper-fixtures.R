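# Tiny on-disk fixtures built in code.

# 19-nt toy chromosome with an 11-nt gene [5,15] (1-based) carrying a 3-nt
# intron at gene-relative [4,6]; flanks of 4 give leader AAAA / trailer ACCC.
write_toy_genome <- function(dir = NULL, strand = "+", intron = "3-6") {
    if (is.null(dir)) {
        dir <- tempfile("toyfix")
        dir.create(dir)
    }
    fa <- file.path(dir, "toy.fa")
    writeLines(c(">chrT", "AAAACCCGGGTTTAAACCC"), fa)
    ann <- file.path(dir, "toy.tsv")
    writeLines(paste("chrT", 4, 15, "tX(AAA)toy", 0, strand, intron,
                     sep = "\t"), ann)
    c(genome = fa, annotation = ann)
}

make_qreads <- function(seqs, quals) {
    r <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(r) <- paste0("r", seq_along(seqs))
    r
}

# A reference with a long intron for intron-overlap tests:
# leader 5, 5' exon 10, intron 12, 3' exon 10, trailer 8.
make_intron_ref <- function() {
    set.seed(99)
    gene <- random_seq(32)
    m <- pretRNAends::newTRNAGeneModel("tZ(AAA)syn", "chrZ", "+", 6, 37,
                                       gene, random_seq(5), random_seq(8),
                                       IRanges::IRanges(11, 22))
    pretRNAends::buildPrecursorReference(m)
}
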