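# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes -- group-dependent clonal concentration
# (Dirichlet-multinomial clone sizes), tissue-dependent sequencing depth,
# a shared public-clone pool, paired tumor-blood recirculation, planted
# epitope annotations and proportional-hazards survival -- and records the
# ground truth needed to validate every pipeline stage.

#' CohortConfig: full parameterization of a synthetic cohort
#'
#' See [cohortConfig()] for the meaning and defaults of every slot.
#'
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
    tumorCounts = "numeric", bloodCounts = "numeric",
    pairedCounts = "numeric", clonePoolSize = "numeric",
    nonproductivePoolSize = "numeric", publicPoolSize = "numeric",
    sharingProb = "numeric", clonalConcentration = "list",
    depthMedian = "numeric", depthSigma = "numeric",
    productiveFraction = "numeric", pairedOverlap = "numeric",
    pairedOverlapAgeSlope = "numeric", sharedCloneAlpha = "numeric",
    annotatedFraction = "numeric", speciesMix = "numeric",
    survival = "list", masterSeed = "numeric"))

setValidity("CohortConfig", function(object) {
    msg <- character()
    prob01 <- function(x) all(x >= 0 & x <= 1)
    if (!prob01(object@sharingProb) || !prob01(object@pairedOverlap) ||
        !prob01(object@productiveFraction) ||
        !prob01(object@annotatedFraction))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(unlist(object@clonalConcentration) <= 0))
        msg <- c(msg, "clonal concentrations must be positive")
    if (any(c(object@tumorCounts, object@bloodCounts,
              object@pairedCounts) < 0))
        msg <- c(msg, "sample counts must be non-negative")
    if (any(object@pairedCounts > object@bloodCounts) ||
        any(object@pairedCounts > object@tumorCounts))
        msg <- c(msg, "paired counts cannot exceed tumor or blood counts")
    if (length(msg)) msg else TRUE
})

#' Build a synthetic-cohort configuration
#'
#' Defaults mirror the structure of a three-group DLBCL TCR-sequencing
#' cohort: 19/11/27 tumors and 7/7/7 blood samples for HIV-negative,
#' HIV-positive/ART-naive and HIV-positive/ART-experienced patients, 16 of
#' them with paired tumor and blood; log-normal total-template depths with
#' medians 385 (tumor) and 27,000 (blood); productive-template fractions
#' 0.77 (tumor) and 0.80 (blood); ART-naive tumors drawn with a much lower
#' Dirichlet concentration (more clonal); a shared public-clone pool; a
#' paired-overlap parameter per group that decreases with patient age; 5% of
#' clone keys planted in the epitope database; and exponential
#' proportional-hazards survival with group and age effects.
#'
#' @param tumorCounts,bloodCounts,pairedCounts named per-group sample counts.
#' @param clonePoolSize clones in each sample's underlying frequency pool.
#' @param nonproductivePoolSize distinct non-productive rearrangements used
#'   to absorb non-productive templates.
#' @param publicPoolSize size of the cohort-wide public clone pool.
#' @param sharingProb per-group probability that a clone key is drawn from
#'   the public pool rather than invented privately.
#' @param clonalConcentration list with `tumor` and `blood` named vectors of
#'   symmetric-Dirichlet concentrations (lower = more clonal).
#' @param depthMedian,depthSigma per-tissue log-normal total-template depth.
#' @param productiveFraction per-tissue probability that a template is
#'   productive.
#' @param pairedOverlap per-group baseline fraction of a tumor's clones
#'   recirculating in the paired blood.
#' @param pairedOverlapAgeSlope decrease in paired overlap per year of age
#'   above 46.
#' @param sharedCloneAlpha Dirichlet concentration given to recirculating
#'   tumor clones in the paired blood pool (large enough that planted
#'   overlap is identifiable at realistic blood depths).
#' @param annotatedFraction fraction of clone keys planted in the epitope
#'   database.
#' @param speciesMix named probability vector of antigen species.
#' @param survival list: `baselineHazard` (per month), `groupLogHR` (named),
#'   `ageLogHR` (per year, centred at 46), `censoringHazard` (per month),
#'   `adminCensorMonths`.
#' @param masterSeed integer; every random stream derives from it.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(
    tumorCounts = c(HIV_neg = 19, HIV_pos_ART_naive = 11,
                    HIV_pos_ART_exp = 27),
    bloodCounts = c(HIV_neg = 7, HIV_pos_ART_naive = 7,
                    HIV_pos_ART_exp = 7),
    pairedCounts = c(HIV_neg = 6, HIV_pos_ART_naive = 5,
                     HIV_pos_ART_exp = 5),
    clonePoolSize = 3000,
    nonproductivePoolSize = 300,
    publicPoolSize = 500,
    sharingProb = c(HIV_neg = 0.04, HIV_pos_ART_naive = 0.02,
                    HIV_pos_ART_exp = 0.06),
    clonalConcentration = list(
        tumor = c(HIV_neg = 3, HIV_pos_ART_naive = 0.3,
                  HIV_pos_ART_exp = 3),
        blood = c(HIV_neg = 0.15, HIV_pos_ART_naive = 0.15,
                  HIV_pos_ART_exp = 0.15)),
    depthMedian = c(tumor = 385, blood = 27000),
    depthSigma = c(tumor = 2.0, blood = 0.8),
    productiveFraction = c(tumor = 0.77, blood = 0.80),
    pairedOverlap = c(HIV_neg = 0.05, HIV_pos_ART_naive = 0.45,
                      HIV_pos_ART_exp = 0.20),
    pairedOverlapAgeSlope = 0.004,
    sharedCloneAlpha = 5,
    annotatedFraction = 0.05,
    speciesMix = c(InfluenzaA = 0.30, CMV = 0.25, EBV = 0.20, HIV = 0.15,
                   other = 0.10),
    survival = list(baselineHazard = log(2) / 20,
                    groupLogHR = c(HIV_neg = 0, HIV_pos_ART_naive = -0.6,
                                   HIV_pos_ART_exp = 0.2),
                    ageLogHR = 0.015, censoringHazard = 0.01,
                    adminCensorMonths = 60),
    masterSeed = 20240523) {
    new("CohortConfig", tumorCounts = tumorCounts, bloodCounts = bloodCounts,
        pairedCounts = pairedCounts, clonePoolSize = clonePoolSize,
        nonproductivePoolSize = nonproductivePoolSize,
        publicPoolSize = publicPoolSize, sharingProb = sharingProb,
        clonalConcentration = clonalConcentration, depthMedian = depthMedian,
        depthSigma = depthSigma, productiveFraction = productiveFraction,
        pairedOverlap = pairedOverlap,
        pairedOverlapAgeSlope = pairedOverlapAgeSlope,
        sharedCloneAlpha = sharedCloneAlpha,
        annotatedFraction = annotatedFraction, speciesMix = speciesMix,
        survival = survival, masterSeed = masterSeed)
}

#' The cohort-wide public clone pool
#'
#' Deterministic given the master seed.
#'
#' @param config a [CohortConfig-class].
#' @return character vector of public clone keys.
#' @export
publicClonePool <- function(config) {
    withSeed(deriveSeed(config@masterSeed, "public_pool"),
             randomCDR3(config@publicPoolSize))
}

.drawDepth <- function(config, tissue) {
    repeat {
        total <- round(stats::rlnorm(1, log(config@depthMedian[[tissue]]),
                                     config@depthSigma[[tissue]]))
        if (total >= 1) break
        # a zero-depth draw is redrawn
    }
    min(total, 5e5)
}

# allocate `total` templates over a frequency pool and build the clone table;
# `aaKeys` gives the amino-acid key of every pool clone
.buildCloneTable <- function(total, freq, aaKeys, productiveFraction,
                             nonproductivePoolSize) {
    n <- as.vector(stats::rmultinom(1, total, freq))
    keep <- which(n > 0)
    kprod <- stats::rbinom(length(keep), n[keep], productiveFraction)
    prodSel <- kprod > 0
    k <- kprod[prodSel]
    aaK <- aaKeys[keep][prodSel]
    nt <- randomDNA(length(k))
    variant <- k >= 2 & stats::runif(length(k)) < 0.15
    # the second nucleotide variant of a clonotype is minor (~2% of templates)
    k2 <- 1 + stats::rbinom(length(k), pmax(k - 2, 0), 0.02)
    k1 <- ifelse(variant, k - k2, k)
    prodRows <- data.frame(nucleotide_seq = nt, amino_acid_seq = aaK,
                           templates = k1, frame_type = "in_frame",
                           stringsAsFactors = FALSE)
    if (any(variant)) {
        prodRows <- rbind(prodRows, data.frame(
            nucleotide_seq = randomDNA(sum(variant)),
            amino_acid_seq = aaK[variant],
            templates = (k - k1)[variant], frame_type = "in_frame",
            stringsAsFactors = FALSE))
    }
    npTot <- total - sum(kprod)
    npRows <- NULL
    if (npTot > 0) {
        M <- min(nonproductivePoolSize, npTot)
        np <- as.vector(stats::rmultinom(1, npTot, rep(1, M)))
        np <- np[np > 0]
        npRows <- data.frame(
            nucleotide_seq = randomDNA(length(np)), amino_acid_seq = "",
            templates = np,
            frame_type = sample(c("out_of_frame", "has_stop"), length(np),
                                replace = TRUE),
            stringsAsFactors = FALSE)
    }
    list(clones = rbind(prodRows, npRows),
         truth = list(sampledCounts = n[keep], productiveCounts = kprod,
                      poolIndex = keep, total = total))
}

# per-group/tissue clone keys: public with sharingProb, else private
.drawKeys <- function(n, config, group, publicPool) {
    isPublic <- stats::runif(n) < config@sharingProb[[group]]
    keys <- character(n)
    nPub <- sum(isPublic)
    if (nPub > 0)
        keys[isPublic] <- publicPool[sample(length(publicPool),
                                            min(nPub, length(publicPool)))]
    keys[!isPublic] <- randomCDR3(n - nPub)
    list(keys = keys, isPublic = isPublic)
}

#' Generate one synthetic repertoire
#'
#' Clone frequencies are drawn from a symmetric Dirichlet over
#' `clonePoolSize` clones with the group/tissue concentration; the total
#' template depth is log-normal; templates are allocated multinomially and
#' each is productive independently with the tissue's productive fraction.
#' Clone keys come from the public pool with the group's sharing
#' probability, otherwise they are private; each amino-acid key carries one
#' or occasionally two nucleotide variants. The same `(config, seed)` always
#' yields an identical repertoire.
#'
#' @param config a [CohortConfig-class].
#' @param group group label.
#' @param tissue `"tumor"` or `"blood"`.
#' @param sampleId sample identifier.
#' @param seed RNG seed (default: derived from the master seed and
#'   `sampleId`).
#' @param publicPool public clone pool (default [publicClonePool()]).
#' @return list with `repertoire` (a [TCRRepertoire-class]) and `truth`
#'   (pool frequencies, per-clone sampled and productive counts, key
#'   assignment).
#' @export
generateRepertoire <- function(config, group, tissue, sampleId,
                               seed = NULL, publicPool = NULL) {
    if (is.null(seed)) seed <- deriveSeed(config@masterSeed, sampleId)
    if (is.null(publicPool)) publicPool <- publicClonePool(config)
    withSeed(seed, {
        C <- config@clonePoolSize
        alpha <- config@clonalConcentration[[tissue]][[group]]
        g <- stats::rgamma(C, shape = alpha)
        if (sum(g) == 0) g[sample(C, 1)] <- 1  # guard vs extreme-alpha underflow
        freq <- g / sum(g)
        total <- .drawDepth(config, tissue)
        keyDraw <- .drawKeys(C, config, group, publicPool)
        built <- .buildCloneTable(total, freq, keyDraw$keys,
                                  config@productiveFraction[[tissue]],
                                  config@nonproductivePoolSize)
        truth <- c(built$truth,
                   list(poolFreq = freq, aaKeys = keyDraw$keys,
                        isPublic = keyDraw$isPublic, alpha = alpha,
                        group = group, tissue = tissue, seed = seed))
        list(repertoire = TCRRepertoire(sampleId, tissue, built$clones),
             truth = truth)
    })
}

#' Generate the paired blood repertoire for a tumor sample
#'
#' The blood clone pool is the union of a fraction `omega` of the tumor's
#' realized clone keys (recirculating clones, given concentration
#' `sharedCloneAlpha` so they are reliably sampled at blood depth) and
#' independent blood clones drawn as in [generateRepertoire()]. The
#' measured [tumorBloodOverlap()] of the realized pair recovers `omega` in
#' expectation, up to sampling-depth losses.
#'
#' @inheritParams generateRepertoire
#' @param tumorRep the patient's tumor [TCRRepertoire-class].
#' @param omega fraction of tumor clones recirculating in blood, in
#'   `[0, 1]`.
#' @return list with `repertoire` and `truth` (including `sharedKeys`, the
#'   intended recirculating subset).
#' @export
generatePairedBlood <- function(config, tumorRep, group, sampleId, omega,
                                seed = NULL, publicPool = NULL) {
    if (omega < 0 || omega > 1)
        stop("omega must lie in [0, 1]", call. = FALSE)
    if (is.null(seed)) seed <- deriveSeed(config@masterSeed, sampleId)
    if (is.null(publicPool)) publicPool <- publicClonePool(config)
    withSeed(seed, {
        tumorKeys <- cloneSet(tumorRep)
        nShared <- round(omega * length(tumorKeys))
        shared <- if (nShared > 0) sample(tumorKeys, nShared) else character(0)
        C <- config@clonePoolSize
        nNew <- max(C - nShared, 0)
        keyDraw <- .drawKeys(nNew, config, group, publicPool)
        # keep blood-only keys distinct from the tumor's
        clash <- keyDraw$keys %in% tumorKeys
        if (any(clash)) keyDraw$keys[clash] <- randomCDR3(sum(clash))
        poolKeys <- c(shared, keyDraw$keys)
        alphaB <- config@clonalConcentration[["blood"]][[group]]
        g <- c(stats::rgamma(nShared, shape = config@sharedCloneAlpha),
               stats::rgamma(nNew, shape = alphaB))
        if (sum(g) == 0) g[1] <- 1
        freq <- g / sum(g)
        total <- .drawDepth(config, "blood")
        built <- .buildCloneTable(total, freq, poolKeys,
                                  config@productiveFraction[["blood"]],
                                  config@nonproductivePoolSize)
        truth <- c(built$truth,
                   list(poolFreq = freq, aaKeys = poolKeys,
                        sharedKeys = shared, omega = omega,
                        group = group, tissue = "blood", seed = seed))
        list(repertoire = TCRRepertoire(sampleId, "blood", built$clones),
             truth = truth)
    })
}

#' Generate clinical records with proportional-hazards survival
#'
#' Ages, sex and routine covariates are drawn per patient; overall survival
#' follows an exponential proportional-hazards model with the configured
#' group and age log-hazard-ratios, with independent exponential censoring
#' and administrative censoring. Progression is an additional exponential
#' risk, so progression-free survival never exceeds overall survival.
#' ART-duration values are consistent with group labels (naive: at most 6
#' months; experienced: more than 6).
#'
#' @param config a [CohortConfig-class].
#' @param patients data.frame with columns `patient_id` and `group`.
#' @param seed RNG seed (default: derived from the master seed).
#' @return data.frame of clinical records (one row per patient).
#' @export
generateClinical <- function(config, patients, seed = NULL) {
    if (is.null(seed)) seed <- deriveSeed(config@masterSeed, "clinical")
    sv <- config@survival
    withSeed(seed, {
        n <- nrow(patients)
        group <- patients$group
        age <- pmin(pmax(round(stats::rnorm(n, 46, 13)), 18), 85)
        sex <- sample(c("F", "M"), n, replace = TRUE)
        ldh <- round(stats::rlnorm(n, log(400), 0.5))
        ecog <- sample(0:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
        stage_gt2 <- stats::rbinom(n, 1, 0.5)
        ki67 <- round(stats::runif(n, 40, 95))
        eber <- stats::rbinom(n, 1, 0.1)
        coo <- sample(c("GC", "non_GC"), n, replace = TRUE,
                      prob = c(0.48, 0.52))
        viral <- numeric(n)
        naive <- group == "HIV_pos_ART_naive"
        expd <- group == "HIV_pos_ART_exp"
        viral[naive] <- round(stats::rlnorm(sum(naive), log(9800), 1))
        viral[expd] <- ifelse(stats::rbinom(sum(expd), 1, 0.7) == 1, 0,
                              round(stats::rlnorm(sum(expd), log(500), 1)))
        viral[!naive & !expd] <- NA
        cd4 <- rep(NA_real_, n)
        cd4[naive] <- pmax(round(stats::rnorm(sum(naive), 150, 80)), 5)
        cd4[expd] <- pmax(round(stats::rnorm(sum(expd), 350, 150)), 5)
        art <- rep(NA_real_, n)
        art[naive] <- round(pmin(stats::rexp(sum(naive), log(2) / 0.2), 6), 1)
        art[expd] <- round(6 + stats::rlnorm(sum(expd), log(52), 0.6), 1)
        lp <- sv$groupLogHR[group] + sv$ageLogHR * (age - 46)
        hazard <- sv$baselineHazard * exp(lp)
        tDeath <- stats::rexp(n, hazard)
        tCens <- pmin(stats::rexp(n, sv$censoringHazard),
                      sv$adminCensorMonths)
        tProg <- stats::rexp(n, hazard * 0.5)
        pfsTrue <- pmin(tDeath, tProg)
        data.frame(patient_id = patients$patient_id, group = group,
                   age = age, sex = sex,
                   os_months = round(pmin(tDeath, tCens), 2),
                   os_event = as.integer(tDeath <= tCens),
                   pfs_months = round(pmin(pfsTrue, tCens), 2),
                   pfs_event = as.integer(pfsTrue <= tCens),
                   ldh = ldh, ecog = ecog, stage_gt2 = stage_gt2,
                   ki67 = ki67, eber = eber, cell_of_origin = coo,
                   hiv_viral_load = viral, cd4_count = cd4,
                   art_months = art, stringsAsFactors = FALSE)
    })
}

#' Plant an epitope database over a set of clone keys
#'
#' Selects `annotatedFraction` of the supplied keys independently and gives
#' each one species entry drawn from the configured species mix (a small
#' fraction receive a second species, exercising multi-species clones).
#'
#' @param config a [CohortConfig-class].
#' @param pool character vector of clone keys to annotate from.
#' @param seed RNG seed (default: derived from the master seed).
#' @return an [EpitopeDB-class].
#' @export
generateEpitopeDB <- function(config, pool, seed = NULL) {
    if (is.null(seed)) seed <- deriveSeed(config@masterSeed, "epitope_db")
    withSeed(seed, {
        pool <- unique(pool)
        sel <- pool[stats::runif(length(pool)) < config@annotatedFraction]
        if (!length(sel)) return(EpitopeDB())
        mix <- config@speciesMix / sum(config@speciesMix)
        species <- sample(names(mix), length(sel), replace = TRUE, prob = mix)
        rows <- data.frame(cdr3_aa = sel, species = species,
                           epitope = .randomStrings(length(sel),
                                                    .AA_LETTERS, 9L),
                           mhc_class = sample(c("MHCI", "MHCII"),
                                              length(sel), replace = TRUE),
                           stringsAsFactors = FALSE)
        dup <- stats::runif(length(sel)) < 0.05
        if (any(dup)) {
            extra <- rows[dup, , drop = FALSE]
            extra$species <- sample(names(mix), sum(dup), replace = TRUE,
                                    prob = mix)
            extra$epitope <- .randomStrings(sum(dup), .AA_LETTERS, 9L)
            rows <- rbind(rows, extra)
        }
        EpitopeDB(rows)
    })
}

#' Generate a full synthetic cohort
#'
#' Builds the patient roster from the configured per-group counts (tumors,
#' blood samples, paired patients), generates clinical records, every tumor
#' and blood repertoire (paired bloods via [generatePairedBlood()], with the
#' per-patient overlap parameter decreasing with age), and the planted
#' epitope database over all productive clone keys. Entirely deterministic
#' given the configuration, including its master seed.
#'
#' @param config a [CohortConfig-class].
#' @return list of class `SyntheticCohort`: `cohort` (a
#'   [TCRCohort-class]), `epitopeDB`, `truth` (per-sample ground-truth
#'   slices plus per-patient planted overlaps) and `config`.
#' @export
generateCohort <- function(config = cohortConfig()) {
    groups <- names(config@tumorCounts)
    pats <- list(); k <- 0L
    for (g in groups) {
        nT <- config@tumorCounts[[g]]
        nP <- config@pairedCounts[[g]]
        nBonly <- config@bloodCounts[[g]] - nP
        for (i in seq_len(nT)) {
            k <- k + 1L
            pats[[k]] <- data.frame(patient_id = sprintf("P%03d", k),
                                    group = g, hasTumor = TRUE,
                                    hasBlood = i <= nP,
                                    stringsAsFactors = FALSE)
        }
        for (i in seq_len(nBonly)) {
            k <- k + 1L
            pats[[k]] <- data.frame(patient_id = sprintf("P%03d", k),
                                    group = g, hasTumor = FALSE,
                                    hasBlood = TRUE, stringsAsFactors = FALSE)
        }
    }
    patients <- do.call(rbind, pats)
    clin <- generateClinical(config, patients)
    pool <- publicClonePool(config)
    reps <- list(); man <- list(); truth <- list()
    omegaTab <- list()
    for (i in seq_len(nrow(patients))) {
        pid <- patients$patient_id[i]
        g <- patients$group[i]
        age <- clin$age[clin$patient_id == pid]
        tumorRep <- NULL
        if (patients$hasTumor[i]) {
            sid <- paste0(pid, "_T")
            r <- generateRepertoire(config, g, "tumor", sid,
                                    publicPool = pool)
            tumorRep <- r$repertoire
            reps[[sid]] <- tumorRep; truth[[sid]] <- r$truth
            man[[length(man) + 1L]] <- data.frame(
                sample_id = sid, patient_id = pid, tissue = "tumor",
                group = g, stringsAsFactors = FALSE)
        }
        if (patients$hasBlood[i]) {
            sid <- paste0(pid, "_B")
            if (!is.null(tumorRep)) {
                omega <- min(max(config@pairedOverlap[[g]] -
                                 config@pairedOverlapAgeSlope * (age - 46),
                                 0.02), 0.95)
                r <- generatePairedBlood(config, tumorRep, g, sid, omega,
                                         publicPool = pool)
                omegaTab[[length(omegaTab) + 1L]] <- data.frame(
                    patient_id = pid, group = g, age = age, omega = omega,
                    stringsAsFactors = FALSE)
            } else {
                r <- generateRepertoire(config, g, "blood", sid,
                                        publicPool = pool)
            }
            reps[[sid]] <- r$repertoire; truth[[sid]] <- r$truth
            man[[length(man) + 1L]] <- data.frame(
                sample_id = sid, patient_id = pid, tissue = "blood",
                group = g, stringsAsFactors = FALSE)
        }
    }
    cohort <- TCRCohort(reps, do.call(rbind, man), clin)
    allKeys <- unique(unlist(lapply(reps, cloneSet), use.names = FALSE))
    db <- generateEpitopeDB(config, sort(allKeys))
    structure(list(cohort = cohort, epitopeDB = db,
                   truth = list(samples = truth,
                                pairedOverlap = if (length(omegaTab))
                                    do.call(rbind, omegaTab) else
                                    data.frame(),
                                survival = config@survival,
                                publicPool = pool),
                   config = config),
              class = "SyntheticCohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits one rearrangement TSV per sample (immunoSEQ-export or AIRR
#' dialect), the clinical CSV, the epitope TSV, a planted-parameter table
#' and a manifest listing every file with its md5 checksum.
#'
#' @param x a `SyntheticCohort` from [generateCohort()].
#' @param dir output directory (created if needed).
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(x, dir, dialect = c("immunoseq", "airr")) {
    dialect <- match.arg(dialect)
    stopifnot(inherits(x, "SyntheticCohort"))
    dir.create(file.path(dir, "repertoires"), recursive = TRUE,
               showWarnings = FALSE)
    man <- manifest(x$cohort)
    files <- character(0)
    for (sid in man$sample_id) {
        f <- file.path(dir, "repertoires", paste0(sid, ".tsv"))
        if (dialect == "immunoseq")
            writeImmunoSeq(x$cohort[[sid]], f) else writeAIRR(x$cohort[[sid]], f)
        files <- c(files, f)
    }
    clinF <- file.path(dir, "clinical.csv")
    utils::write.csv(clinical(x$cohort), clinF, row.names = FALSE)
    dbF <- file.path(dir, "epitope_db.tsv")
    writeEpitopeDB(x$epitopeDB, dbF)
    truthF <- file.path(dir, "planted_parameters.tsv")
    po <- x$truth$pairedOverlap
    utils::write.table(po, truthF, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, clinF, dbF, truthF)
    out <- cbind(data.frame(file = files, md5 = unname(tools::md5sum(files)),
                            stringsAsFactors = FALSE))
    mf <- file.path(dir, "manifest.tsv")
    utils::write.table(out, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}
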