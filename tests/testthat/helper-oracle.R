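# Independent oracles, kept deliberately separate from the package
# implementation they check.

# Brute-force Gotoh local alignment score: full dynamic programming over
# all cells, affine gaps (a gap of length k costs open + k * ext),
# match/mismatch scoring. O(nm); used on small instances only.
oracle_local_score <- function(read, ref, match = 1, mismatch = -3,
                               open = 2, ext = 1) {
    a <- strsplit(read, "")[[1]]
    b <- strsplit(ref, "")[[1]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)  # gap in read (consuming ref)
    F <- matrix(-Inf, n + 1, m + 1)  # gap in ref (consuming read)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            E[i + 1, j + 1] <- max(E[i + 1, j] - ext, H[i + 1, j] - open - ext)
            F[i + 1, j + 1] <- max(F[i, j + 1] - ext, H[i, j + 1] - open - ext)
            s <- if (a[i] == b[j]) match else mismatch
            H[i + 1, j + 1] <- max(0, H[i, j] + s,
                                   E[i + 1, j + 1], F[i + 1, j + 1])
            if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
        }
    }
    best
}

# Independent formulation of the 3'-end category rules, written
# category-first (membership tests) rather than in the implementation's
# first-match-wins rule order.
oracle_classify <- function(off, s) {
    if (is.na(off) || grepl("[^ACGT]", s)) return("OTHER")
    if (s == "") {
        if (off == 0) return("PROCESSED_EXACT")
        return(if (off > 0) "TRAILER" else "TRIMMED")
    }
    if (off == 0 && s %in% c("C", "CC", "CCA"))
        return(c(C = "PLUS_C", CC = "PLUS_CC", CCA = "PLUS_CCA")[[s]])
    core <- sub("A+$", "", s)
    n_a <- nchar(s) - nchar(core)
    if (n_a >= 1 && core == "") return("OLIGO_A")
    if (n_a >= 1 && off == 0 && core %in% c("C", "CC", "CCA"))
        return("OLIGO_A")
    "OTHER"
}

# All ACGT strings of length 0..k.
all_suffixes <- function(k) {
    out <- ""
    bases <- c("A", "C", "G", "T")
    cur <- ""
    lev <- bases
    for (len in seq_len(k)) {
        out <- c(out, lev)
        lev <- as.vector(outer(lev, bases, paste0))
    }
    out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
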