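# Shared fixtures and independent oracles for the suite.

# Four reads, two variable columns (1 and 3, H = 1 bit each), one
# conserved column; the canonical hand-checkable alignment.
toyAlignment <- function() {
    otAlignment(c("AAC", "AAG", "TAC", "TAG"),
        rep("S1", 4), paste0("r", 1:4))
}

# The two published example sample-by-oligotype tables (13 Arctic
# sediment samples, one OTU decomposed by MED and by OP, both
# broken-stick filtered) shipped under extdata.
exampleTables <- function() {
    list(
        med = readOTTable(system.file("extdata", "arctic_otu_med_bsm.tsv",
            package = "oligotypeR")),
        op = readOTTable(system.file("extdata", "arctic_otu_op_bsm.tsv",
            package = "oligotypeR")))
}

# Brute-force Shannon entropy of one character vector: explicit
# histogram and direct summation, independent of columnEntropies().
bruteEntropy <- function(chars, base = 2) {
    h <- 0
    for (cc in unique(chars)) {
        f <- sum(chars == cc) / length(chars)
        h <- h - f * log(f, base = base)
    }
    h
}

# Random alignment over a given alphabet, as a character matrix plus the
# OTAlignment built from it.
randomAlignment <- function(n, len, alphabet = c("A", "C", "G", "U", "-"),
    nSamples = 3) {
    m <- matrix(sample(alphabet, n * len, replace = TRUE), n, len)
    aln <- otAlignment(apply(m, 1, paste0, collapse = ""),
        sample(paste0("S", seq_len(nSamples)), n, replace = TRUE),
        paste0("r", seq_len(n)))
    list(matrix = m, alignment = aln)
}

# Noise-free planted spec: 4 subpopulations separable at two columns.
plantedSpec <- function(seed = 11, noiseRate = 0, nSamples = 4,
    readsPerSample = 120) {
    synthSpec(nSamples, readsPerSample, 60,
        components = list(
            list(position = 10, chars = c("A", "C", "G", "U")),
            list(position = 40, chars = c("A", "A", "C", "C"))),
        mixing = matrix(c(0.55, 0.15, 0.15, 0.15,
                          0.15, 0.55, 0.15, 0.15,
                          0.15, 0.15, 0.55, 0.15,
                          0.15, 0.15, 0.15, 0.55)[
            seq_len(4 * nSamples)], nSamples, 4, byrow = TRUE),
        noiseRate = noiseRate, seed = seed)
}

# TRUE iff two label vectors induce the same partition of the reads
# (labels themselves may differ).
samePartition <- function(a, b) {
    all(vapply(split(b, a), function(g) length(unique(g)) == 1L,
        logical(1))) &&
    all(vapply(split(a, b), function(g) length(unique(g)) == 1L,
        logical(1)))
}
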