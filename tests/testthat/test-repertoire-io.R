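writeLinesTSV <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}

test_that("immunoSEQ tables parse with correct totals and frame handling", {
    f <- writeLinesTSV(c(
        "rearrangement\tamino_acid\ttemplates\tframe_type",
        "TGTGCCAGCA\tCASSA\t10\tIn",
        "TGTGCCAGCB\tCASSB\t5\tin_frame",
        "TGTGCCAGCC\tCASSC\t2\tIN",
        "TGTGCCAGCD\tCASSD\t7\tStop",
        "TGTGCCAGCE\tCASSE\t3\tOut"))
    rep <- readImmunoSeq(f, "S1", "tumor")
    expect_s4_class(rep, "TCRRepertoire")
    expect_equal(nrow(clones(rep)), 5)
    expect_equal(totalTemplates(rep), 27)
    expect_equal(productiveTemplates(rep), 17)
    # non-productive rows carry no amino-acid sequence
    expect_true(all(clones(rep)$amino_acid_seq[
        clones(rep)$frame_type != "in_frame"] == ""))
})

test_that("immunoSEQ reader drops zero-template rows and merges nt duplicates", {
    f <- writeLinesTSV(c(
        "rearrangement\tamino_acid\ttemplates\tframe_type",
        "TGTAAA\tCASSA\t4\tIn",
        "TGTAAA\tCASSA\t6\tIn",
        "TGTCCC\tCASSC\t0\tIn"))
    rep <- readImmunoSeq(f, "S1", "tumor")
    expect_equal(nrow(clones(rep)), 1)
    expect_equal(clones(rep)$templates, 10)
})

test_that("a header-only table gives an empty repertoire", {
    f <- writeLinesTSV("rearrangement\tamino_acid\ttemplates\tframe_type")
    rep <- readImmunoSeq(f, "S1", "blood")
    expect_equal(nrow(clones(rep)), 0)
    expect_equal(totalTemplates(rep), 0)
    expect_equal(productiveTemplates(rep), 0)
})

test_that("format errors name the offending column or row", {
    f <- writeLinesTSV(c("rearrangement\tamino_acid\tframe_type",
                         "TGT\tCAF\tIn"))
    expect_error(readImmunoSeq(f, "S", "tumor"), "templates")
    f2 <- writeLinesTSV(c(
        "rearrangement\tamino_acid\ttemplates\tframe_type",
        "TGTA\tCAF\t3\tIn",
        "TGTB\tCBF\tx7\tIn"))
    expect_error(readImmunoSeq(f2, "S", "tumor"), "row 2")
    f3 <- writeLinesTSV(c(
        "rearrangement\tamino_acid\ttemplates\tframe_type",
        "TGTA\tCAF\t3\tbanana"))
    expect_error(readImmunoSeq(f3, "S", "tumor"), "frame_type")
})

test_that("AIRR tables parse productive flags and default duplicate_count", {
    f <- writeLinesTSV(c(
        "junction\tjunction_aa\tduplicate_count\tproductive",
        "TGTGCA\tCASSA\t7\tT",
        "TGTGCC\tCASSB\t3\tF"))
    rep <- readAIRR(f, "S1", "blood")
    expect_equal(productiveTemplates(rep), 7)
    expect_equal(totalTemplates(rep), 10)
    f2 <- writeLinesTSV(c("junction\tjunction_aa\tproductive",
                          "TGTGCA\tCASSA\ttrue",
                          "TGTGCC\tCASSB\tfalse"))
    rep2 <- readAIRR(f2, "S1", "blood")
    expect_true(all(clones(rep2)$templates == 1))
})

test_that("both dialects round-trip a synthetic repertoire identically", {
    r <- generateRepertoire(tinyConfig(), "HIV_neg", "tumor", "S1",
                            seed = 11)$repertoire
    # AIRR cannot represent the out-of-frame/stop distinction; restrict the
    # fixture to clones both dialects express
    cl <- clones(r)
    cl <- cl[cl$frame_type != "has_stop", , drop = FALSE]
    r <- TCRRepertoire("S1", "tumor", cl)
    f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
    writeImmunoSeq(r, f1)
    writeAIRR(r, f2)
    writeRepertoire(r, f3)
    a <- readImmunoSeq(f1, "S1", "tumor")
    b <- readAIRR(f2, "S1", "tumor")
    c3 <- readRepertoire(f3, "S1", "tumor")
    key <- function(x) {
        cl <- clones(x)
        cl[order(cl$nucleotide_seq), ]
    }
    expect_equal(key(a), key(b))
    expect_equal(key(a), key(c3))
    expect_equal(key(a), key(r))
})

test_that("productiveSubset keeps exactly in-frame clones and is idempotent", {
    r <- makeRep("S", "tumor",
                 nt = paste0("N", 1:5),
                 aa = c("CAF", "CBF", "CCF", "", ""),
                 templates = c(3, 2, 1, 5, 4),
                 frame = c("in_frame", "in_frame", "in_frame",
                           "has_stop", "out_of_frame"))
    p <- productiveSubset(r)
    expect_equal(nrow(clones(p)), 3)
    expect_equal(totalTemplates(p), 6)
    expect_equal(clones(productiveSubset(p)), clones(p))
    allProd <- countsRep(c(4, 4))
    expect_equal(clones(productiveSubset(allProd)), clones(allProd))
})

test_that("QC threshold is strict and the partition is exhaustive and ordered", {
    reps <- list(countsRep(rep(1, 99), id = "A"),
                 countsRep(rep(1, 100), id = "B"),
                 countsRep(rep(1, 101), id = "C"))
    qc <- qcFilter(reps, 100)
    expect_equal(vapply(qc$passed, sampleId, character(1)), "C")
    expect_equal(unname(vapply(qc$failed, sampleId, character(1))),
                 c("A", "B"))
    expect_equal(length(qc$passed) + length(qc$failed), length(reps))
    qc0 <- qcFilter(reps, 0)
    expect_equal(length(qc0$passed), 3)
    # brute-force recount on a random cohort
    set.seed(1)
    cohort <- lapply(1:30, function(i)
        countsRep(rep(1, sample(50:200, 1)), id = paste0("S", i)))
    qc2 <- qcFilter(cohort, 100)
    expect_equal(length(qc2$passed),
                 sum(vapply(cohort, productiveTemplates, numeric(1)) > 100))
})

test_that("repertoire construction enforces the clone-table invariants", {
    expect_error(makeRep("S", "tumor", "N1", "CAF", 0.5, "in_frame"),
                 "integers")
    expect_error(makeRep("S", "tumor", "N1", "", 2, "in_frame"), "in_frame")
    expect_error(makeRep("S", "tumor", "N1", "CAF", 2, "weird"), "frame_type")
    expect_error(makeRep("S", "elbow", "N1", "CAF", 2, "in_frame"), "tissue")
})

test_that("clinical tables are validated on read", {
    cfg <- tinyConfig()
    pats <- data.frame(patient_id = sprintf("P%02d", 1:9),
                       group = rep(c("HIV_neg", "HIV_pos_ART_naive",
                                     "HIV_pos_ART_exp"), each = 3))
    cli <- generateClinical(cfg, pats, seed = 5)
    f <- tempfile(fileext = ".csv")
    write.csv(cli, f, row.names = FALSE)
    back <- readClinicalTable(f)
    expect_equal(back$patient_id, cli$patient_id)
    expect_true(all(back$pfs_months <= back$os_months))
    bad <- cli
    bad$pfs_months[1] <- bad$os_months[1] + 5
    write.csv(bad, f, row.names = FALSE)
    expect_error(readClinicalTable(f), "pfs_months")
    bad2 <- cli
    bad2$art_months[bad2$group == "HIV_pos_ART_naive"][1] <- 12
    write.csv(bad2, f, row.names = FALSE)
    expect_error(readClinicalTable(f), "ART")
})
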