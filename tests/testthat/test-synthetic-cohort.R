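test_that("repertoire generation is a pure function of config and seed", {
    cfg <- tinyConfig()
    r1 <- generateRepertoire(cfg, "HIV_neg", "tumor", "S1", seed = 5)
    r2 <- generateRepertoire(cfg, "HIV_neg", "tumor", "S1", seed = 5)
    expect_identical(clones(r1$repertoire), clones(r2$repertoire))
    expect_identical(r1$truth$poolFreq, r2$truth$poolFreq)
    r3 <- generateRepertoire(cfg, "HIV_neg", "tumor", "S1", seed = 6)
    expect_false(identical(clones(r1$repertoire), clones(r3$repertoire)))
    # generation does not disturb the caller's RNG stream
    set.seed(123); a <- runif(1)
    set.seed(123); invisible(generateRepertoire(cfg, "HIV_neg", "tumor",
                                                "S9", seed = 7))
    expect_identical(runif(1), a)
})

test_that("the uniform concentration limit reproduces 1/sqrt(C) clonality", {
    cfg <- tinyConfig(clonalConcentration = list(
        tumor = c(HIV_neg = 1e6, HIV_pos_ART_naive = 1e6,
                  HIV_pos_ART_exp = 1e6),
        blood = c(HIV_neg = 1e6, HIV_pos_ART_naive = 1e6,
                  HIV_pos_ART_exp = 1e6)),
        clonePoolSize = 100,
        depthMedian = c(tumor = 50000, blood = 50000),
        depthSigma = c(tumor = 1e-9, blood = 1e-9),
        productiveFraction = c(tumor = 1, blood = 1))
    r <- generateRepertoire(cfg, "HIV_neg", "tumor", "U1", seed = 2)
    s <- simpsonClonality(cloneFrequencies(r$repertoire))
    expect_lt(abs(s - 0.1) / 0.1, 0.02)
})

test_that("a near-degenerate concentration yields monoclonal repertoires", {
    cfg <- tinyConfig(clonalConcentration = list(
        tumor = c(HIV_neg = 1e-3, HIV_pos_ART_naive = 1e-3,
                  HIV_pos_ART_exp = 1e-3),
        blood = c(HIV_neg = 1e-3, HIV_pos_ART_naive = 1e-3,
                  HIV_pos_ART_exp = 1e-3)),
        clonePoolSize = 20,
        depthMedian = c(tumor = 1000, blood = 1000),
        depthSigma = c(tumor = 0.1, blood = 0.1))
    hits <- 0
    for (i in 1:60) {
        r <- generateRepertoire(cfg, "HIV_neg", "tumor",
                                paste0("D", i), seed = 1000 + i)
        mx <- maxProductiveFrequency(cloneFrequencies(r$repertoire))
        if (mx > 0.9) hits <- hits + 1
    }
    expect_gte(hits / 60, 0.95)
})

test_that("decreasing concentration increases measured clonality", {
    means <- vapply(c(0.03, 0.3, 3), function(alpha) {
        cfg <- tinyConfig(clonalConcentration = list(
            tumor = c(HIV_neg = alpha, HIV_pos_ART_naive = alpha,
                      HIV_pos_ART_exp = alpha),
            blood = c(HIV_neg = alpha, HIV_pos_ART_naive = alpha,
                      HIV_pos_ART_exp = alpha)),
            depthMedian = c(tumor = 385, blood = 1000),
            depthSigma = c(tumor = 0.3, blood = 0.3))
        mean(vapply(1:12, function(i) {
            r <- generateRepertoire(cfg, "HIV_neg", "tumor",
                                    paste0("A", i), seed = 500 + i)
            simpsonClonality(cloneFrequencies(r$repertoire))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(means) < 0))
})

test_that("the productive fraction is recovered at depth", {
    cfg <- tinyConfig(depthMedian = c(tumor = 10000, blood = 10000),
                      depthSigma = c(tumor = 1e-9, blood = 1e-9))
    r <- generateRepertoire(cfg, "HIV_neg", "tumor", "PF1", seed = 4)
    rep_ <- r$repertoire
    frac <- productiveTemplates(rep_) / totalTemplates(rep_)
    expect_lt(abs(frac - 0.77), 3 * sqrt(0.77 * 0.23 / 10000))
})

test_that("paired blood honours the planted overlap at its extremes", {
    cfg <- tinyConfig(depthMedian = c(tumor = 385, blood = 20000),
                      depthSigma = c(tumor = 0.2, blood = 0.2))
    t1 <- generateRepertoire(cfg, "HIV_neg", "tumor", "PT1", seed = 3)
    b1 <- generatePairedBlood(cfg, t1$repertoire, "HIV_neg", "PB1",
                              omega = 1, seed = 4)
    ov1 <- tumorBloodOverlap(cloneSet(t1$repertoire),
                             cloneSet(b1$repertoire))
    expect_gte(ov1, 0.95)
    b0 <- generatePairedBlood(cfg, t1$repertoire, "HIV_neg", "PB0",
                              omega = 0, seed = 5)
    expect_equal(tumorBloodOverlap(cloneSet(t1$repertoire),
                                   cloneSet(b0$repertoire)), 0)
    expect_error(generatePairedBlood(cfg, t1$repertoire, "HIV_neg", "PBX",
                                     omega = 1.2), "omega")
})

test_that("clinical records satisfy their invariants", {
    cfg <- tinyConfig()
    pats <- data.frame(patient_id = sprintf("P%03d", 1:60),
                       group = rep(c("HIV_neg", "HIV_pos_ART_naive",
                                     "HIV_pos_ART_exp"), each = 20))
    cli <- generateClinical(cfg, pats, seed = 9)
    expect_equal(nrow(cli), 60)
    expect_true(all(cli$pfs_months <= cli$os_months))
    expect_true(all(cli$os_months >= 0))
    naive <- cli$group == "HIV_pos_ART_naive"
    expd <- cli$group == "HIV_pos_ART_exp"
    expect_true(all(cli$art_months[naive] <= 6))
    expect_true(all(cli$art_months[expd] > 6))
    expect_true(all(is.na(cli$art_months[cli$group == "HIV_neg"])))
    expect_identical(cli, generateClinical(cfg, pats, seed = 9))
})

test_that("null survival effects produce no spurious group association", {
    cfg <- tinyConfig(survival = list(
        baselineHazard = log(2) / 20,
        groupLogHR = c(HIV_neg = 0, HIV_pos_ART_naive = 0,
                       HIV_pos_ART_exp = 0),
        ageLogHR = 0, censoringHazard = 0.01, adminCensorMonths = 60))
    pats <- data.frame(patient_id = sprintf("P%03d", 1:300),
                       group = rep(c("HIV_neg", "HIV_pos_ART_naive"), 150))
    cli <- generateClinical(cfg, pats, seed = 13)
    cli$naive <- as.integer(cli$group == "HIV_pos_ART_naive")
    fit <- coxFit(cli, "os_months", "os_event", "naive")
    se <- (log(fit$ci_high) - log(fit$hr)) / 1.96
    expect_lt(abs(log(fit$hr)) / se, 3.5)
})

test_that("the planted epitope fraction drives the database size", {
    cfg0 <- tinyConfig(annotatedFraction = 0)
    expect_equal(nrow(entries(generateEpitopeDB(cfg0, sprintf("K%03d", 1:500),
                                                seed = 2))), 0)
    cfg1 <- tinyConfig(annotatedFraction = 1)
    keys <- sprintf("K%03d", 1:200)
    db <- generateEpitopeDB(cfg1, keys, seed = 2)
    a <- annotateCloneSet(keys, db)
    expect_equal(a$matched_fraction, 1)
    expect_true(all(entries(db)$species %in%
                    c("InfluenzaA", "CMV", "EBV", "HIV", "other")))
})

test_that("full cohorts have the configured composition and are reproducible", {
    sc <- generateCohort(tinyConfig(masterSeed = 19))
    man <- manifest(sc$cohort)
    expect_equal(sum(man$tissue == "tumor"), 9)
    expect_equal(sum(man$tissue == "blood"), 6)
    expect_equal(length(unique(man$patient_id)), 9)
    expect_equal(nrow(clinical(sc$cohort)), 9)
    sc2 <- generateCohort(tinyConfig(masterSeed = 19))
    expect_identical(lapply(repertoires(sc$cohort), clones),
                     lapply(repertoires(sc2$cohort), clones))
    expect_identical(clinical(sc$cohort), clinical(sc2$cohort))
    expect_identical(entries(sc$epitopeDB), entries(sc2$epitopeDB))
    sc3 <- generateCohort(tinyConfig(masterSeed = 20))
    expect_false(identical(entries(sc$epitopeDB), entries(sc3$epitopeDB)))
})

test_that("written cohorts reload through the normal readers", {
    sc <- generateCohort(tinyConfig(masterSeed = 23))
    dir <- tempfile()
    manOut <- writeCohort(sc, dir, dialect = "immunoseq")
    expect_true(all(file.exists(manOut$file)))
    sid <- manifest(sc$cohort)$sample_id[1]
    back <- readImmunoSeq(file.path(dir, "repertoires",
                                    paste0(sid, ".tsv")),
                          sid, tissue(sc$cohort[[sid]]))
    key <- function(x) { cl <- clones(x); cl[order(cl$nucleotide_seq), ] }
    expect_equal(key(back), key(sc$cohort[[sid]]))
    cli <- readClinicalTable(file.path(dir, "clinical.csv"))
    expect_equal(nrow(cli), nrow(clinical(sc$cohort)))
    db <- readEpitopeDB(file.path(dir, "epitope_db.tsv"))
    expect_equal(nrow(entries(db)), nrow(entries(sc$epitopeDB)))
    # rerunning the generator reproduces identical files
    dir2 <- tempfile()
    manOut2 <- writeCohort(generateCohort(tinyConfig(masterSeed = 23)), dir2,
                           dialect = "immunoseq")
    expect_identical(manOut$md5, manOut2$md5)
})
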