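test_that("clone sets collapse nucleotide variants and drop non-productive", {
    r <- makeRep("S", "tumor",
                 nt = c("TGTA", "TGTB", "TGTC", "TGTD"),
                 aa = c("CAF", "CAF", "CBF", ""),
                 templates = c(2, 3, 1, 9),
                 frame = c("in_frame", "in_frame", "in_frame",
                           "out_of_frame"))
    expect_setequal(cloneSet(r), c("CAF", "CBF"))
    onlyNp <- makeRep("S", "tumor", "TGTA", "", 5, "has_stop")
    expect_length(cloneSet(onlyNp), 0)
})

test_that("pairwise overlap follows the smaller-repertoire definition", {
    expect_equal(pairwiseOverlap(c("a", "b"), c("a", "b")), 1)
    expect_equal(pairwiseOverlap(c("a", "b"), c("x", "y", "z")), 0)
    expect_equal(pairwiseOverlap(c("a", "b", "c"), c("b", "c", "d", "e")),
                 2 / 3)
    expect_error(pairwiseOverlap(character(0), "a"), "empty")
    # symmetry and containment => 1
    set.seed(4)
    for (i in 1:20) {
        a <- sample(letters, sample(3:15, 1))
        b <- sample(letters, sample(3:15, 1))
        expect_equal(pairwiseOverlap(a, b), pairwiseOverlap(b, a))
        expect_equal(pairwiseOverlap(a, b), naivePairwiseOverlap(a, b))
        expect_equal(pairwiseOverlap(a, c(a, "ZZ")), 1)
    }
})

test_that("overlap matrices handle identical and disjoint cohorts", {
    same <- lapply(1:3, function(i)
        countsRep(c(3, 2, 1), id = paste0("S", i)))
    m <- overlapMatrix(same)
    expect_true(all(m == 1))
    disjoint <- lapply(1:3, function(i)
        countsRep(c(3, 2), id = paste0("S", i),
                  aa = paste0("C", i, c("A", "B"), "F")))
    m2 <- overlapMatrix(disjoint)
    expect_equal(m2, diag(1, 3), ignore_attr = TRUE)
    expect_equal(rownames(m2), c("S1", "S2", "S3"))
})

test_that("reference overlap extracts within- and between-group pairs once", {
    reps <- lapply(1:5, function(i)
        randomAaRep(paste0("S", i)))
    grp <- setNames(c("X", "X", "Y", "Y", "Z"), paste0("S", 1:5))
    m <- overlapMatrix(reps)
    ro <- referenceOverlap(m, grp, "X")
    expect_equal(sum(ro$comparison == "within_X"), 1)  # one unordered pair
    expect_equal(sum(ro$comparison == "Y"), 4)
    expect_equal(sum(ro$comparison == "Z"), 2)
    expect_true(all(ro$sample_a != ro$sample_b))
})

test_that("venn partition assigns each key to exactly one region", {
    reps <- list(countsRep(5, id = "A", aa = "CXF"),
                 countsRep(5, id = "B", aa = "CXF"),
                 countsRep(5, id = "C", aa = "CXF"))
    grp <- setNames(c("g1", "g2", "g3"), c("A", "B", "C"))
    v <- vennPartition(reps, grouping = grp)
    expect_equal(v$count[v$region == "g1+g2+g3"], 1)
    expect_equal(sum(v$count), 1)
    # private clones populate only exclusive regions
    reps2 <- list(countsRep(c(2, 2), id = "A", aa = c("CAF", "CBF")),
                  countsRep(c(2, 2), id = "B", aa = c("CCF", "CDF")))
    v2 <- vennPartition(reps2, grouping = setNames(c("g1", "g2"),
                                                   c("A", "B")))
    expect_equal(v2$count[v2$region == "g1"], 2)
    expect_equal(v2$count[v2$region == "g2"], 2)
    expect_equal(v2$count[v2$region == "g1+g2"], 0)
})

test_that("venn, publicity and exclusive sharing match naive set oracles", {
    set.seed(12)
    for (trial in 1:20) {
        n <- sample(4:8, 1)
        ids <- paste0("S", seq_len(n))
        groups <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
        reps <- lapply(seq_len(n), function(i)
            randomAaRep(ids[i], nClones = sample(5:25, 1),
                        keyPool = sprintf("CK%02dF", 1:40)))
        grp <- setNames(groups, ids)
        sets <- lapply(reps, cloneSet)
        # venn
        v <- vennPartition(reps, grouping = grp)
        oracle <- naiveVennCounts(sets, groups)
        for (region in v$region)
            expect_equal(v$count[v$region == region],
                         oracle[[region]] %||% 0L)
        expect_equal(sum(v$count), length(unique(unlist(sets))))
        # publicity at several thresholds, incl. nesting
        p2 <- publicity(reps, minSamples = 2, grouping = grp)
        p3 <- publicity(reps, minSamples = 3, grouping = grp)
        o2 <- naivePublicity(sets, ids, 2)
        expect_setequal(p2$key, names(o2))
        for (k in p2$key)
            expect_equal(strsplit(p2$sample_ids[p2$key == k], ",")[[1]],
                         o2[[k]])
        expect_true(all(p3$key %in% p2$key))
        # exclusive sharing within {g1, g2}
        ex <- exclusiveShared(reps, inGroups = c("g1", "g2"),
                              minSamples = 2, grouping = grp)
        oex <- naiveExclusive(sets, ids, groups, c("g1", "g2"), 2)
        expect_setequal(ex$records$key, names(oex) %||% character(0))
        for (k in ex$records$key)
            expect_equal(ex$records$occupancy[ex$records$key == k],
                         oex[[k]])
    }
})

test_that("publicity orders records by sample count then key", {
    reps <- list(countsRep(c(1, 1), id = "A", aa = c("CAF", "CBF")),
                 countsRep(c(1, 1), id = "B", aa = c("CAF", "CBF")),
                 countsRep(1, id = "C", aa = "CBF"))
    grp <- setNames(rep("g", 3), c("A", "B", "C"))
    p <- publicity(reps, minSamples = 2, grouping = grp)
    expect_equal(p$key, c("CBF", "CAF"))
    expect_equal(p$sample_count, c(3L, 2L))
    expect_equal(p$n_g, c(3L, 2L))
})

test_that("exclusive sharing reports per-sample frequencies of each partition", {
    reps <- list(
        countsRep(c(6, 4), id = "A", aa = c("CSHF", "CPRIVF")),
        countsRep(c(2, 8), id = "B", aa = c("CSHF", "CXF")),
        countsRep(c(5, 5), id = "C", aa = c("CYF", "CZF")))
    grp <- setNames(c("naive", "naive", "neg"), c("A", "B", "C"))
    ex <- exclusiveShared(reps, inGroups = c("naive", "exp"),
                          minSamples = 2, grouping = grp)
    expect_equal(ex$records$key, "CSHF")
    expect_equal(ex$records$occupancy, "naive")
    sf <- ex$sampleFrequencies
    expect_equal(sf$frequency[sf$sample_id == "A" & sf$occupancy == "naive"],
                 0.6)
    expect_equal(sf$frequency[sf$sample_id == "B" & sf$occupancy == "naive"],
                 0.2)
})

test_that("a clone shared with an outside group is not exclusive", {
    reps <- list(countsRep(1, id = "A", aa = "CKF"),
                 countsRep(1, id = "B", aa = "CKF"),
                 countsRep(1, id = "C", aa = "CKF"))
    grp <- setNames(c("pos1", "pos2", "neg"), c("A", "B", "C"))
    ex <- exclusiveShared(reps, inGroups = c("pos1", "pos2"),
                          minSamples = 2, grouping = grp)
    expect_equal(nrow(ex$records), 0)
})

test_that("tumor-blood overlap is directional and ignores blood-only clones", {
    tumor <- paste0("T", 1:10)
    blood <- c(paste0("T", 1:4), paste0("B", 1:50))
    expect_equal(tumorBloodOverlap(tumor, blood), 0.4)
    expect_equal(tumorBloodOverlap(tumor, c(tumor, "EXTRA")), 1)
    expect_equal(tumorBloodOverlap(tumor, blood),
                 tumorBloodOverlap(tumor, c(blood, paste0("B", 51:99))))
    expect_error(tumorBloodOverlap(character(0), blood), "empty")
    set.seed(6)
    for (i in 1:10) {
        ts <- sample(letters, 10); bs <- sample(letters, 12)
        expect_equal(tumorBloodOverlap(ts, bs), naiveTumorBlood(ts, bs))
    }
})

test_that("the paired-cohort table matches per-patient overlap", {
    sc <- generateCohort(tinyConfig(masterSeed = 8))
    tb <- tumorBloodTable(sc$cohort)
    expect_equal(nrow(tb), 6)  # two paired patients per group
    man <- manifest(sc$cohort)
    for (i in seq_len(nrow(tb))) {
        ts <- cloneSet(sc$cohort[[tb$tumor_sample[i]]])
        bs <- cloneSet(sc$cohort[[tb$blood_sample[i]]])
        expect_equal(tb$overlap[i], naiveTumorBlood(ts, bs))
    }
    expect_true(all(tb$overlap >= 0 & tb$overlap <= 1))
})
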