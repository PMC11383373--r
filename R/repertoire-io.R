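# Reading and writing rearrangement tables (immunoSEQ-export and AIRR
# dialects), normalization to TCRRepertoire, and sample-level QC.

.IMMUNOSEQ_MAP <- list(
    nucleotide_seq = c("rearrangement", "nucleotide", "nucleotide_seq"),
    amino_acid_seq = c("amino_acid", "aminoAcid", "amino_acid_seq"),
    templates      = c("templates", "count (templates/reads)", "count",
                       "templates_reads"),
    frame_type     = c("frame_type", "sequenceStatus", "frame"))

.pickColumn <- function(header, candidates, what, path) {
    hit <- candidates[candidates %in% header]
    if (!length(hit))
        stop(sprintf("file '%s' is missing a '%s' column (looked for: %s)",
                     path, what, paste(candidates, collapse = ", ")),
             call. = FALSE)
    hit[[1L]]
}

.parseTemplates <- function(x, path) {
    bad <- !grepl("^[0-9]+$", trimws(x))
    if (any(bad))
        stop(sprintf("file '%s': non-integer template count at data row %d ('%s')",
                     path, which(bad)[1L], x[which(bad)[1L]]), call. = FALSE)
    as.numeric(x)
}

.parseFrame <- function(x, path) {
    key <- gsub("[^a-z]", "", tolower(x))
    map <- c("in" = "in_frame", inframe = "in_frame",
             out = "out_of_frame", outofframe = "out_of_frame",
             stop = "has_stop", hasstop = "has_stop", stopcodon = "has_stop")
    out <- unname(map[key])
    if (anyNA(out))
        stop(sprintf("file '%s': unrecognized frame_type value '%s' at data row %d",
                     path, x[which(is.na(out))[1L]], which(is.na(out))[1L]),
             call. = FALSE)
    out
}

.readTSV <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", na.strings = NULL)
}

#' Read an immunoSEQ-style rearrangement export
#'
#' Parses a tab-separated rearrangement table as exported by the Adaptive
#' immunoSEQ platform and normalizes it into a [TCRRepertoire-class]. Column
#' names vary across export versions, so each logical column accepts several
#' aliases and a custom `columnMap` can be supplied. Rows with a template
#' count of zero are dropped; duplicate nucleotide rows are merged by summing
#' templates. Frame parsing is case-insensitive and raises on unknown values.
#'
#' @param path path to a TSV file.
#' @param sampleId sample identifier for the resulting repertoire.
#' @param tissue `"tumor"` or `"blood"`.
#' @param columnMap optional named list overriding the default column aliases
#'   (names `nucleotide_seq`, `amino_acid_seq`, `templates`, `frame_type`).
#' @return a [TCRRepertoire-class].
#' @seealso [readAIRR()], [writeImmunoSeq()]
#' @export
readImmunoSeq <- function(path, sampleId, tissue, columnMap = NULL) {
    map <- .IMMUNOSEQ_MAP
    if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
    tab <- .readTSV(path)
    cols <- vapply(names(map), function(f)
        .pickColumn(names(tab), map[[f]], f, path), character(1))
    if (nrow(tab) == 0L)
        return(TCRRepertoire(sampleId, tissue, .emptyClones()))
    templates <- .parseTemplates(tab[[cols["templates"]]], path)
    frame <- .parseFrame(tab[[cols["frame_type"]]], path)
    aa <- tab[[cols["amino_acid_seq"]]]
    aa[frame != "in_frame"] <- ""
    TCRRepertoire(sampleId, tissue, data.frame(
        nucleotide_seq = tab[[cols["nucleotide_seq"]]],
        amino_acid_seq = aa, templates = templates, frame_type = frame,
        stringsAsFactors = FALSE))
}

#' Read an AIRR Rearrangement TSV
#'
#' Parses a table following the AIRR Rearrangement schema: `junction` is the
#' CDR3 nucleotide sequence, `junction_aa` the amino-acid sequence,
#' `duplicate_count` the template count (1 when the column is absent) and
#' `productive` a `T`/`F` (or `true`/`false`) flag. `productive = T` maps to
#' `in_frame`; non-productive rows are recorded as `out_of_frame` with a
#' blanked amino-acid sequence, since the flag does not distinguish
#' out-of-frame junctions from stop codons.
#'
#' @inheritParams readImmunoSeq
#' @return a [TCRRepertoire-class].
#' @export
readAIRR <- function(path, sampleId, tissue) {
    tab <- .readTSV(path)
    for (col in c("junction", "junction_aa", "productive"))
        if (!col %in% names(tab))
            stop(sprintf("file '%s' is missing a '%s' column (AIRR schema)",
                         path, col), call. = FALSE)
    if (nrow(tab) == 0L)
        return(TCRRepertoire(sampleId, tissue, .emptyClones()))
    templates <- if ("duplicate_count" %in% names(tab))
        .parseTemplates(tab$duplicate_count, path) else rep(1, nrow(tab))
    pr <- tolower(trimws(tab$productive))
    if (!all(pr %in% c("t", "f", "true", "false")))
        stop(sprintf("file '%s': productive flag must be T/F or true/false",
                     path), call. = FALSE)
    productive <- pr %in% c("t", "true")
    aa <- tab$junction_aa
    aa[!productive] <- ""
    TCRRepertoire(sampleId, tissue, data.frame(
        nucleotide_seq = tab$junction, amino_acid_seq = aa,
        templates = templates,
        frame_type = ifelse(productive, "in_frame", "out_of_frame"),
        stringsAsFactors = FALSE))
}

.emptyClones <- function() data.frame(
    nucleotide_seq = character(), amino_acid_seq = character(),
    templates = numeric(), frame_type = character(),
    stringsAsFactors = FALSE)

#' Write a repertoire in immunoSEQ-export style
#' @param x a [TCRRepertoire-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeImmunoSeq <- function(x, path) {
    cl <- clones(x)
    out <- data.frame(rearrangement = cl$nucleotide_seq,
                      amino_acid = cl$amino_acid_seq,
                      templates = cl$templates,
                      frame_type = c(in_frame = "In", out_of_frame = "Out",
                                     has_stop = "Stop")[cl$frame_type],
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a repertoire as AIRR Rearrangement TSV
#' @inheritParams writeImmunoSeq
#' @return `path`, invisibly.
#' @export
writeAIRR <- function(x, path) {
    cl <- clones(x)
    out <- data.frame(junction = cl$nucleotide_seq,
                      junction_aa = cl$amino_acid_seq,
                      duplicate_count = cl$templates,
                      productive = ifelse(cl$frame_type == "in_frame",
                                          "T", "F"),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read the normalized repertoire format
#'
#' The normalized format is a four-column TSV (`nucleotide_seq`,
#' `amino_acid_seq`, `templates`, `frame_type`), one file per sample.
#'
#' @inheritParams writeImmunoSeq
#' @return `writeRepertoire`: `path` invisibly; `readRepertoire`: a
#'   [TCRRepertoire-class].
#' @export
writeRepertoire <- function(x, path) {
    utils::write.table(clones(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeRepertoire
#' @inheritParams readImmunoSeq
#' @export
readRepertoire <- function(path, sampleId, tissue) {
    tab <- .readTSV(path)
    need <- c("nucleotide_seq", "amino_acid_seq", "templates", "frame_type")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop(sprintf("file '%s' is missing column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (nrow(tab) == 0L)
        return(TCRRepertoire(sampleId, tissue, .emptyClones()))
    tab$templates <- .parseTemplates(tab$templates, path)
    tab$frame_type <- .parseFrame(tab$frame_type, path)
    TCRRepertoire(sampleId, tissue, tab[need])
}

#' Partition a cohort by the productive-template QC threshold
#'
#' A sample passes QC when it has strictly more than `minProductive`
#' productive templates (the inclusion rule for clonality analysis). The
#' partition is exhaustive, disjoint and order-preserving.
#'
#' @param cohort a list of [TCRRepertoire-class] objects or a
#'   [TCRCohort-class].
#' @param minProductive QC threshold (default 100; strict inequality).
#' @return `list(passed = , failed = )` of repertoire lists.
#' @export
qcFilter <- function(cohort, minProductive = 100) {
    stopifnot(minProductive >= 0)
    reps <- if (is(cohort, "TCRCohort")) repertoires(cohort) else cohort
    prod <- vapply(reps, productiveTemplates, numeric(1))
    list(passed = reps[prod > minProductive],
         failed = reps[prod <= minProductive])
}

#' Summarise a cohort's samples and QC status
#'
#' @param cohort a [TCRCohort-class] or list of repertoires.
#' @param minProductive QC threshold passed to [qcFilter()].
#' @return data.frame with one row per sample: ids, tissue, group (if known),
#'   template totals, unique rearrangement counts and `qc_pass`.
#' @export
cohortManifest <- function(cohort, minProductive = 100) {
    reps <- if (is(cohort, "TCRCohort")) repertoires(cohort) else cohort
    man <- if (is(cohort, "TCRCohort")) manifest(cohort) else NULL
    out <- data.frame(
        sample_id = unname(vapply(reps, sampleId, character(1))),
        tissue = vapply(reps, tissue, character(1)),
        total_templates = vapply(reps, totalTemplates, numeric(1)),
        productive_templates = vapply(reps, productiveTemplates, numeric(1)),
        unique_rearrangements = vapply(reps, function(r) nrow(clones(r)),
                                       numeric(1)),
        unique_productive = vapply(reps, function(r)
            sum(clones(r)$frame_type == "in_frame"), numeric(1)),
        stringsAsFactors = FALSE)
    out$qc_pass <- out$productive_templates > minProductive
    if (!is.null(man)) {
        out$patient_id <- man$patient_id[match(out$sample_id, man$sample_id)]
        out$group <- man$group[match(out$sample_id, man$sample_id)]
    }
    rownames(out) <- NULL
    out
}

#' Read a clinical table
#'
#' Expects a CSV with one row per patient: `patient_id`, `group` (one of
#' `HIV_neg`, `HIV_pos_ART_naive`, `HIV_pos_ART_exp`), `age`, `sex`,
#' `os_months`, `os_event`, `pfs_months`, `pfs_event`, plus any covariate
#' columns (LDH, ECOG, stage_gt2, ...). Checks the ART-duration consistency
#' rule (naive: at most 6 months of prior ART; experienced: more than 6) when
#' an `art_months` column is present, and that `pfs_months <= os_months`.
#'
#' @param path CSV path.
#' @return data.frame of clinical records.
#' @export
readClinicalTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "group", "age", "os_months", "os_event",
              "pfs_months", "pfs_event")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop(sprintf("clinical table '%s' is missing column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (!all(tab$group %in% .GROUP_LEVELS))
        stop("unknown group label(s) in clinical table", call. = FALSE)
    if (any(tab$pfs_months > tab$os_months + 1e-9))
        stop("pfs_months must not exceed os_months", call. = FALSE)
    if ("art_months" %in% names(tab)) {
        bad <- (tab$group == "HIV_pos_ART_exp" & tab$art_months <= 6) |
            (tab$group == "HIV_pos_ART_naive" & tab$art_months > 6)
        if (any(bad))
            stop("ART duration inconsistent with ART-naive/experienced labels",
                 call. = FALSE)
    }
    tab
}
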