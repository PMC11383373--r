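# End-to-end orchestration: ingest -> QC -> downsampled clonality ->
# expansion profiles -> group contrasts -> Venn/publicity/exclusive sharing
# -> tumor-blood overlap -> epitope annotation -> survival analyses.
# Each stage is an exported function; runRepertoireAnalysis() chains them
# and every output is a pure function of (cohort, epitope table, options).

.tryStage <- function(notes, label, expr) {
    res <- tryCatch(expr, error = function(e) {
        attr(e, "stageLabel") <- label
        e
    })
    if (inherits(res, "error")) {
        notes[[length(notes) + 1L]] <- sprintf("%s: skipped (%s)", label,
                                               conditionMessage(res))
        list(value = NULL, notes = notes)
    } else list(value = res, notes = notes)
}

.groupValues <- function(tab, col) split(tab[[col]], tab$group)

# prepend a constant column without inheriting stray row names
.withCol <- function(d, name, value) {
    rownames(d) <- NULL
    d2 <- cbind(stats::setNames(data.frame(rep(value, nrow(d)),
                                           stringsAsFactors = FALSE), name),
                d)
    rownames(d2) <- NULL
    d2
}

#' Run the full repertoire analysis
#'
#' Orchestrates the complete analysis of a cohort: sample manifest and
#' productive-template QC; downsampling depth (recomputed as the minimum
#' productive count among QC-passing samples when `depth = "auto"`);
#' downsampled clonality metrics and non-downsampled expansion profiles with
#' tissue and HIV/ART-group contrasts; all-sample sharing analyses per
#' tissue (overlap matrix, overlap with reference to the ART-naive group,
#' Venn partition, publicity, HIV-exclusive shared clones); paired
#' tumor-blood overlap with its age correlation, group contrast and
#' median-cutoff survival analysis; epitope annotation with group and
#' per-species contrasts; and survival analyses (Kaplan-Meier by group, Cox
#' fits for median-dichotomized clonality metrics, and a per-clone survival
#' screen over public clones at unadjusted p < 0.05). Group comparisons that
#' a small cohort cannot support are skipped and logged in `notes` rather
#' than failing the run.
#'
#' @param cohort a [TCRCohort-class].
#' @param epitopeDB optional [EpitopeDB-class]; annotation stages are
#'   skipped when absent.
#' @param minProductive QC threshold (strict; default 100).
#' @param depth `"auto"` or integer downsampling depth.
#' @param iterations downsampling iterations.
#' @param masterSeed master seed for all random stages.
#' @param publicityMinSamples publicity threshold (default 5).
#' @param exclusiveMinSamples exclusive-sharing threshold (default 2).
#' @param denominatorMode epitope-proportion denominator, see
#'   [annotateCloneSet()].
#' @param referenceGroup group used as reference for sample-level overlap
#'   contrasts (default `"HIV_pos_ART_naive"`).
#' @return list of class `RepertoireAnalysis` with the stage tables
#'   (`manifest`, `clonality`, `clonalityContrasts`, `expansionContrasts`,
#'   `venn`, `referenceOverlap`, `publicity`, `exclusiveShared`,
#'   `tumorBlood`, `annotation`, `survival`, ...), a `meta` block recording
#'   options, seed, depth, per-stage sample counts and the options hash, and
#'   `notes` logging skipped stages.
#' @export
runRepertoireAnalysis <- function(cohort, epitopeDB = NULL,
                                  minProductive = 100, depth = "auto",
                                  iterations = 100, masterSeed = 1L,
                                  publicityMinSamples = 5,
                                  exclusiveMinSamples = 2,
                                  denominatorMode = "all_tcrs",
                                  referenceGroup = "HIV_pos_ART_naive") {
    stopifnot(is(cohort, "TCRCohort"))
    notes <- list()
    opts <- list(minProductive = minProductive, depth = depth,
                 iterations = iterations, masterSeed = masterSeed,
                 publicityMinSamples = publicityMinSamples,
                 exclusiveMinSamples = exclusiveMinSamples,
                 denominatorMode = denominatorMode,
                 referenceGroup = referenceGroup)
    man <- cohortManifest(cohort, minProductive)
    qc <- qcFilter(cohort, minProductive)
    if (!length(qc$passed))
        stop("QC stage: no sample exceeds the productive-template threshold",
             call. = FALSE)
    usedDepth <- if (identical(depth, "auto")) autoDepth(qc$passed) else depth

    ## clonality (QC-passing samples, downsampled) + expansion profiles
    clon <- cohortClonality(cohort, minProductive, usedDepth, iterations,
                            masterSeed)
    contrasts <- list()
    tissueOf <- clon$tissue
    metricCols <- c("simpson_clonality", "max_productive_frequency",
                    "unique_productive_rearrangements")
    binCols <- intersect(c("small", "medium", "large", "hyperexpanded"),
                         names(clon))
    if (length(unique(tissueOf)) == 2) {
        for (mcol in c(metricCols, binCols)) {
            st <- .tryStage(notes, paste0("tissue contrast ", mcol),
                wilcoxonRankSum(clon[[mcol]][tissueOf == "blood"],
                                clon[[mcol]][tissueOf == "tumor"],
                                variable = mcol))
            notes <- st$notes
            if (!is.null(st$value)) {
                row <- st$value
                row$group_a <- "blood"; row$group_b <- "tumor"
                mt <- stats::median(clon[[mcol]][tissueOf == "tumor"])
                row$fold_change <- if (mt == 0) NA_real_ else
                    stats::median(clon[[mcol]][tissueOf == "blood"]) / mt
                contrasts[[length(contrasts) + 1L]] <-
                    .withCol(row, "scope", "blood_vs_tumor")
            }
        }
    }
    if ("group" %in% names(clon)) {
        for (tis in unique(tissueOf)) {
            sub <- clon[tissueOf == tis, , drop = FALSE]
            for (mcol in c(metricCols, binCols)) {
                vals <- .groupValues(sub, mcol)
                vals <- vals[vapply(vals, length, integer(1)) >= 2]
                if (length(vals) < 2) next
                st <- .tryStage(notes, sprintf("%s KW %s", tis, mcol),
                                kruskalWallis(vals, variable = mcol))
                notes <- st$notes
                if (!is.null(st$value)) {
                    v <- st$value
                    v$group_a <- NA; v$group_b <- NA
                    v$fold_change <- NA; v$exact <- NA
                    contrasts[[length(contrasts) + 1L]] <-
                        .withCol(v, "scope", paste0(tis, "_groups"))
                }
                st <- .tryStage(notes, sprintf("%s pairwise %s", tis, mcol),
                                pairwiseWilcoxon(vals, variable = mcol))
                notes <- st$notes
                if (!is.null(st$value)) {
                    pw <- st$value
                    pw$fold_change_flag <- NULL
                    contrasts[[length(contrasts) + 1L]] <-
                        .withCol(pw, "scope", paste0(tis, "_groups"))
                }
            }
        }
    }
    clonalityContrasts <- if (length(contrasts)) {
        common <- c("scope", "variable", "test", "group_a", "group_b",
                    "statistic", "p_value", "fold_change")
        do.call(rbind, lapply(contrasts, function(d) {
            for (cc in setdiff(common, names(d))) d[[cc]] <- NA
            d[common]
        }))
    } else data.frame()
    # BH across the per-tissue Kruskal-Wallis family, as for covariate scans
    if (nrow(clonalityContrasts)) {
        clonalityContrasts$p_adjusted <- NA_real_
        for (sc in unique(clonalityContrasts$scope)) {
            iKW <- which(clonalityContrasts$scope == sc &
                         clonalityContrasts$test == "kruskal_wallis")
            if (length(iKW))
                clonalityContrasts$p_adjusted[iKW] <-
                    bhAdjust(clonalityContrasts$p_value[iKW])
        }
    }

    ## sharing analyses: all samples, per tissue
    venn <- list(); refOv <- list(); pub <- list(); excl <- list()
    for (tis in unique(man$tissue)) {
        st <- .tryStage(notes, paste0("venn ", tis),
                        vennPartition(cohort, tis))
        notes <- st$notes; venn[[tis]] <- st$value
        st <- .tryStage(notes, paste0("overlap ", tis), {
            m <- overlapMatrix(cohort, tis)
            grp <- stats::setNames(manifest(cohort)$group,
                                   manifest(cohort)$sample_id)
            referenceOverlap(m, grp, referenceGroup)
        })
        notes <- st$notes; refOv[[tis]] <- st$value
        st <- .tryStage(notes, paste0("publicity ", tis),
                        publicity(cohort, tis, publicityMinSamples))
        notes <- st$notes; pub[[tis]] <- st$value
        st <- .tryStage(notes, paste0("exclusive shared ", tis),
                        exclusiveShared(cohort, tis,
                                        inGroups = c("HIV_pos_ART_naive",
                                                     "HIV_pos_ART_exp"),
                                        minSamples = exclusiveMinSamples))
        notes <- st$notes; excl[[tis]] <- st$value
    }

    ## paired tumor-blood overlap
    tb <- tumorBloodTable(cohort)
    tbStats <- list()
    if (nrow(tb) >= 3 && "age" %in% names(tb)) {
        st <- .tryStage(notes, "tumor-blood vs age",
                        spearmanCor(tb$age, tb$overlap,
                                    variable = "tumor_blood_overlap_vs_age"))
        notes <- st$notes
        if (!is.null(st$value)) tbStats$age <- st$value
    }
    if (nrow(tb) >= 4) {
        vals <- split(tb$overlap, tb$group)
        vals <- vals[vapply(vals, length, integer(1)) >= 2]
        if (length(vals) >= 2) {
            st <- .tryStage(notes, "tumor-blood group contrast",
                            pairwiseWilcoxon(vals,
                                             variable = "tumor_blood_overlap"))
            notes <- st$notes
            if (!is.null(st$value)) tbStats$group <- st$value
        }
    }

    ## annotation
    annotation <- NULL; annContrasts <- NULL
    if (!is.null(epitopeDB)) {
        st <- .tryStage(notes, "annotation", suppressWarnings(
            annotateCohort(cohort, epitopeDB, denominatorMode)))
        notes <- st$notes; annotation <- st$value
        if (!is.null(annotation) && nrow(annotation) &&
            "group" %in% names(annotation)) {
            rows <- list()
            for (tis in unique(annotation$tissue)) {
                sub <- annotation[annotation$tissue == tis, , drop = FALSE]
                vals <- split(sub$matched_fraction, sub$group)
                vals <- vals[vapply(vals, length, integer(1)) >= 2]
                if (length(vals) >= 2) {
                    st <- .tryStage(notes, paste0("matched fraction ", tis),
                                    pairwiseWilcoxon(vals,
                                                     variable = "matched_fraction"))
                    notes <- st$notes
                    if (!is.null(st$value))
                        rows[[length(rows) + 1L]] <-
                            .withCol(st$value, "tissue", tis)
                }
                st <- .tryStage(notes, paste0("species contrast ", tis),
                                suppressWarnings(speciesContrast(sub)))
                notes <- st$notes
                if (!is.null(st$value) && nrow(st$value))
                    rows[[length(rows) + 1L]] <-
                        .withCol(st$value, "tissue", tis)
            }
            annContrasts <- if (length(rows)) {
                common <- Reduce(union, lapply(rows, names))
                do.call(rbind, lapply(rows, function(d) {
                    for (cc in setdiff(common, names(d))) d[[cc]] <- NA
                    d[common]
                }))
            } else data.frame()
        }
    }

    ## survival
    surv <- list()
    cli <- clinical(cohort)
    if (nrow(cli) && sum(cli$os_event) >= 2) {
        st <- .tryStage(notes, "KM by group",
                        kmCurve(cli, "os_months", "os_event", "group",
                                endpoint = "OS"))
        notes <- st$notes; surv$kmByGroup <- st$value
        cli2 <- cli
        cli2$hiv <- ifelse(cli2$group == "HIV_neg", "neg", "pos")
        st <- .tryStage(notes, "Cox HIV status",
                        coxFit(cli2, "os_months", "os_event", "hiv",
                               endpoint = "OS"))
        notes <- st$notes; surv$coxHIV <- st$value
        ## median-dichotomized clonality biomarkers (per tissue)
        fits <- list()
        for (tis in unique(clon$tissue)) {
            sub <- clon[clon$tissue == tis & !is.na(clon$patient_id), ,
                        drop = FALSE]
            if (nrow(sub) < 6) next
            for (mcol in metricCols) {
                dat <- cli[match(sub$patient_id, cli$patient_id), ,
                           drop = FALSE]
                st <- .tryStage(notes, sprintf("Cox %s %s", tis, mcol), {
                    split_ <- medianDichotomize(
                        stats::setNames(sub[[mcol]], sub$patient_id))
                    dat$biomarker <- factor(split_[dat$patient_id],
                                            levels = c("low", "high"))
                    do.call(rbind, lapply(
                        c(OS = "os", PFS = "pfs"), function(ep)
                            coxFit(dat, paste0(ep, "_months"),
                                   paste0(ep, "_event"), "biomarker",
                                   endpoint = toupper(ep))))
                })
                notes <- st$notes
                if (!is.null(st$value)) {
                    v <- st$value
                    v$variable <- paste(tis, mcol, "high_vs_low")
                    fits[[length(fits) + 1L]] <- v
                }
            }
        }
        ## tumor-blood overlap biomarker
        if (nrow(tb) >= 6) {
            st <- .tryStage(notes, "Cox tumor-blood overlap", {
                dat <- cli[match(tb$patient_id, cli$patient_id), ,
                           drop = FALSE]
                split_ <- medianDichotomize(
                    stats::setNames(tb$overlap, tb$patient_id))
                dat$biomarker <- factor(split_[dat$patient_id],
                                        levels = c("low", "high"))
                do.call(rbind, lapply(c(OS = "os", PFS = "pfs"), function(ep)
                    coxFit(dat, paste0(ep, "_months"), paste0(ep, "_event"),
                           "biomarker", endpoint = toupper(ep))))
            })
            notes <- st$notes
            if (!is.null(st$value)) {
                v <- st$value
                v$variable <- "tumor_blood_overlap high_vs_low"
                fits[[length(fits) + 1L]] <- v
            }
        }
        surv$biomarkers <- if (length(fits)) {
            b <- do.call(rbind, fits); rownames(b) <- NULL; b
        } else data.frame()
        ## per-clone survival screen over public clones (unadjusted p < 0.05)
        screens <- list()
        for (tis in names(pub)) {
            p <- pub[[tis]]
            if (is.null(p) || !nrow(p)) next
            manT <- man[man$tissue == tis, , drop = FALSE]
            for (ki in seq_len(nrow(p))) {
                carriers <- strsplit(p$sample_ids[ki], ",")[[1]]
                pids <- manT$patient_id[manT$sample_id %in% carriers]
                dat <- cli[cli$patient_id %in% manT$patient_id, ,
                           drop = FALSE]
                dat$carrier <- as.integer(dat$patient_id %in% pids)
                for (ep in c("os", "pfs")) {
                    fit <- tryCatch(coxFit(dat, paste0(ep, "_months"),
                                           paste0(ep, "_event"), "carrier",
                                           endpoint = toupper(ep)),
                                    error = function(e) NULL)
                    if (!is.null(fit)) {
                        fit$key <- p$key[ki]; fit$tissue <- tis
                        screens[[length(screens) + 1L]] <- fit
                    }
                }
            }
        }
        surv$cloneScreen <- if (length(screens)) {
            s <- do.call(rbind, screens)
            s$significant <- !is.na(s$p_value) & s$p_value < 0.05 &
                s$flagged == ""
            rownames(s) <- NULL
            s
        } else data.frame()
    }

    meta <- list(options = opts, depth = usedDepth,
                 nSamples = nrow(man),
                 nPassed = length(qc$passed),
                 nPassedByTissue = table(vapply(qc$passed, tissue,
                                                character(1))),
                 optionsHash = objectHash(opts))
    structure(list(manifest = man, clonality = clon,
                   clonalityContrasts = clonalityContrasts,
                   venn = venn, referenceOverlap = refOv, publicity = pub,
                   exclusiveShared = excl, tumorBlood = tb,
                   tumorBloodStats = tbStats, annotation = annotation,
                   annotationContrasts = annContrasts, survival = surv,
                   meta = meta,
                   notes = unlist(notes, use.names = FALSE)),
              class = "RepertoireAnalysis")
}

#' Write an analysis bundle to disk
#'
#' Serialises every table of a [runRepertoireAnalysis()] result as TSV and
#' writes a markdown summary (`report.md`) of sample attrition, group
#' contrasts and survival fits. Each table file ends with a comment line
#' carrying the options hash so outputs are traceable to their
#' configuration.
#'
#' @param res a `RepertoireAnalysis` object.
#' @param dir output directory (created if needed).
#' @return character vector of written files, invisibly.
#' @export
writeAnalysisBundle <- function(res, dir) {
    stopifnot(inherits(res, "RepertoireAnalysis"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    hash <- res$meta$optionsHash
    wtab <- function(tab, name) {
        if (is.null(tab) || !is.data.frame(tab) || !nrow(tab)) return()
        f <- file.path(dir, paste0(name, ".tsv"))
        utils::write.table(tab, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        cat(sprintf("# options_hash: %s\n", hash), file = f, append = TRUE)
        files <<- c(files, f)
    }
    wtab(res$manifest, "manifest")
    wtab(res$clonality, "clonality")
    wtab(res$clonalityContrasts, "clonality_contrasts")
    for (tis in names(res$venn)) wtab(res$venn[[tis]], paste0("venn_", tis))
    for (tis in names(res$referenceOverlap))
        wtab(res$referenceOverlap[[tis]], paste0("reference_overlap_", tis))
    for (tis in names(res$publicity))
        wtab(res$publicity[[tis]], paste0("publicity_", tis))
    for (tis in names(res$exclusiveShared)) {
        ex <- res$exclusiveShared[[tis]]
        if (is.null(ex)) next
        wtab(ex$records, paste0("exclusive_shared_", tis))
        wtab(ex$sampleFrequencies, paste0("exclusive_shared_freq_", tis))
    }
    wtab(res$tumorBlood, "tumor_blood_overlap")
    wtab(res$annotation, "annotation")
    wtab(res$annotationContrasts, "annotation_contrasts")
    if (length(res$survival)) {
        if (!is.null(res$survival$kmByGroup)) {
            wtab(res$survival$kmByGroup$points, "km_points")
            wtab(res$survival$kmByGroup$median, "km_median")
        }
        wtab(res$survival$coxHIV, "cox_hiv")
        wtab(res$survival$biomarkers, "cox_biomarkers")
        wtab(res$survival$cloneScreen, "clone_survival_screen")
    }
    rpt <- file.path(dir, "report.md")
    con <- file(rpt, "w")
    on.exit(close(con))
    cat("# Repertoire analysis report\n\n", file = con)
    cat(sprintf("- options hash: %s\n- master seed: %s\n- downsampling depth: %d (%d iterations)\n",
                hash, res$meta$options$masterSeed, res$meta$depth,
                res$meta$options$iterations), file = con)
    cat(sprintf("- samples: %d sequenced; %d passed QC (>%d productive templates)\n",
                res$meta$nSamples, res$meta$nPassed,
                res$meta$options$minProductive), file = con)
    for (tis in names(res$meta$nPassedByTissue))
        cat(sprintf("    - %s: %d of %d\n", tis,
                    res$meta$nPassedByTissue[[tis]],
                    sum(res$manifest$tissue == tis)), file = con)
    if (!is.null(res$clonalityContrasts) && nrow(res$clonalityContrasts)) {
        cat("\n## Group contrasts\n\n", file = con)
        utils::write.table(res$clonalityContrasts, con, sep = " | ",
                           quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$survival$biomarkers) &&
        is.data.frame(res$survival$biomarkers) &&
        nrow(res$survival$biomarkers)) {
        cat("\n## Survival biomarkers (median cutoff)\n\n", file = con)
        utils::write.table(res$survival$biomarkers, con, sep = " | ",
                           quote = FALSE, row.names = FALSE)
    }
    if (length(res$notes)) {
        cat("\n## Notes\n\n", file = con)
        cat(paste0("- ", res$notes, "\n"), file = con, sep = "")
    }
    files <- c(files, rpt)
    invisible(files)
}
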