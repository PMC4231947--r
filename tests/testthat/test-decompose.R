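test_that("supervised oligotyping concatenates characters in given order", {
    aln <- toyAlignment()
    a <- oligotype(aln, c(1, 3))
    expect_identical(otAssignments(a), c("AC", "AG", "TC", "TG"))
    # order follows the input positions
    rev <- oligotype(aln, c(3, 1))
    expect_identical(otAssignments(rev), c("CA", "GA", "CT", "GT"))
    # a homogeneous column alone yields a single oligotype
    expect_length(unique(otAssignments(oligotype(aln, 2))), 1)
    expect_error(oligotype(aln, 9), "1..3")
    expect_error(oligotype(aln, integer(0)), "at least one")
})

test_that("one-pass equals oligotyping at the high-entropy positions", {
    aln <- toyAlignment()
    op <- onePass(aln, 0.5)
    expect_identical(op@positionsUsed, c(1L, 3L))
    expect_identical(otAssignments(op),
        otAssignments(oligotype(aln, c(1, 3))))
    expect_equal(length(unique(otAssignments(op))), 4)
    # labels all share the length of the position set
    expect_true(all(nchar(otAssignments(op)) == 2))
    # no position above threshold -> one oligotype with the empty label
    hom <- otAlignment(c("AC", "AC", "AC"), rep("S", 3), paste0("r", 1:3))
    expect_identical(unique(otAssignments(onePass(hom, 0))), "")
})

test_that("MED recursion follows the maximal-entropy split path", {
    aln <- toyAlignment()
    a <- med(aln, threshold = 0.5, minNodeSize = 1)
    # tie between positions 1 and 3 resolves to position 1, then each
    # child splits at 3: leaf labels are the split-path concatenations
    expect_identical(otAssignments(a), c("AC", "AG", "TC", "TG"))
    expect_equal(a@parameters$splits[[1]]$position, 1)
    # homogeneous alignment stops at the root: one empty-label OT
    hom <- otAlignment(c("AC", "AC"), rep("S", 2), c("r1", "r2"))
    expect_identical(unique(otAssignments(med(hom, 0.2, 1))), "")
    # minNodeSize gates splitting: 4 reads < 5 -> leaf at root
    expect_identical(unique(otAssignments(med(aln, 0.5, 5))), "")
})

test_that("MED labels have unequal lengths when splits nest", {
    # col 1 is 4-way uniform (2 bits) and splits first; col 2 varies
    # only inside the "A" branch (overall 1.06 bits), so only that
    # child splits again -> leaf labels of unequal depth
    reads <- c("ACA", "ACA", "AGA", "AGA",
               rep("CAA", 4), rep("GAA", 4), rep("UAA", 4))
    aln <- otAlignment(reads, rep("S", 16), paste0("r", 1:16))
    a <- med(aln, threshold = 0.2, minNodeSize = 1)
    labs <- sort(unique(otAssignments(a)))
    expect_identical(labs, c("AC", "AG", "C", "G", "U"))
    expect_equal(a@parameters$splits[[1]]$position, 1)
})

test_that("every method partitions all reads", {
    gen <- generateAlignment(plantedSpec(seed = 21, noiseRate = 0.01))
    n <- nReads(gen$alignment)
    for (a in list(onePass(gen$alignment, 0.3),
                   med(gen$alignment, 0.3, 5),
                   oligotype(gen$alignment, c(10, 40)))) {
        expect_length(otAssignments(a), n)
        expect_equal(sum(table(otAssignments(a))), n)
    }
})

test_that("MED is deterministic across reruns", {
    gen <- generateAlignment(plantedSpec(seed = 22, noiseRate = 0.02))
    a1 <- med(gen$alignment, 0.25, 8)
    a2 <- med(gen$alignment, 0.25, 8)
    expect_identical(otAssignments(a1), otAssignments(a2))
})

test_that("batch screening flags files by maximal entropy", {
    dir <- withr::local_tempdir()
    # three files with planted maximal entropies 0 (homogeneous),
    # ~1 bit, and 2 bits
    writeAlignment(otAlignment(rep("ACGT", 5), rep("S", 5),
        paste0("r", 1:5)), file.path(dir, "flat.fasta"))
    writeAlignment(otAlignment(c("AAAA", "AAAA", "CAAA", "CAAA"),
        rep("S", 4), paste0("r", 1:4)), file.path(dir, "mid.fasta"))
    writeAlignment(otAlignment(c("AAAA", "CAAA", "GAAA", "UAAA"),
        rep("S", 4), paste0("r", 1:4)), file.path(dir, "high.fasta"))
    res <- batchScreen(dir, threshold = 0.6)
    expect_equal(nrow(res), 3)
    expect_identical(res$flagged[match(c("flat.fasta", "mid.fasta",
        "high.fasta"), res$file)], c(FALSE, TRUE, TRUE))
    expect_equal(res$max_entropy[res$file == "flat.fasta"], 0)
    # a homogeneous file is never flagged at any threshold >= 0
    expect_false(batchScreen(dir, threshold = 0)$flagged[
        match("flat.fasta", res$file)])

    # invalid files are reported, not fatal
    writeLines(c(">bad", "ACGT"), file.path(dir, "broken.fasta"))
    res2 <- batchScreen(dir, threshold = 0.6)
    expect_equal(sum(!is.na(res2$error)), 1)
    expect_match(res2$error[res2$file == "broken.fasta"], "malformed")

    expect_error(batchScreen(withr::local_tempdir()), "no input")
})
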