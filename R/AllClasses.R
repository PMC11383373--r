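#' @import methods
NULL

.FRAME_LEVELS <- c("in_frame", "out_of_frame", "has_stop")
.TISSUE_LEVELS <- c("tumor", "blood")
.GROUP_LEVELS <- c("HIV_neg", "HIV_pos_ART_naive", "HIV_pos_ART_exp")

#' TCRRepertoire: one sample's clone table
#'
#' Container for a single bulk TCR-beta sequencing sample. Each row of the
#' clone table is one rearrangement (a unique CDR3 nucleotide sequence) with
#' its template count and frame status. Productive rearrangements are in-frame
#' with no stop codon; only those carry an amino-acid CDR3.
#'
#' @slot sampleId sample identifier, unique within a cohort.
#' @slot tissue `"tumor"` or `"blood"`.
#' @slot clones `data.frame` with columns `nucleotide_seq`, `amino_acid_seq`,
#'   `templates` (positive integer), `frame_type` (one of `in_frame`,
#'   `out_of_frame`, `has_stop`).
#'
#' @seealso [TCRRepertoire()], [productiveSubset()], [clonalityMetrics()]
#' @exportClass TCRRepertoire
setClass("TCRRepertoire",
    representation(sampleId = "character", tissue = "character",
                   clones = "data.frame"))

setValidity("TCRRepertoire", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-empty string")
    if (length(object@tissue) != 1L || !object@tissue %in% .TISSUE_LEVELS)
        msg <- c(msg, sprintf("tissue must be one of %s",
                              paste(.TISSUE_LEVELS, collapse = ", ")))
    cl <- object@clones
    need <- c("nucleotide_seq", "amino_acid_seq", "templates", "frame_type")
    if (!all(need %in% names(cl))) {
        msg <- c(msg, sprintf("clones must have columns %s",
                              paste(need, collapse = ", ")))
        return(msg)
    }
    if (nrow(cl)) {
        if (!is.numeric(cl$templates) || any(cl$templates < 1) ||
            any(cl$templates != round(cl$templates)))
            msg <- c(msg, "templates must be integers >= 1")
        if (!all(cl$frame_type %in% .FRAME_LEVELS))
            msg <- c(msg, "frame_type values must be in_frame, out_of_frame or has_stop")
        bad_aa <- (cl$frame_type == "in_frame") != nzchar(cl$amino_acid_seq)
        if (any(bad_aa))
            msg <- c(msg, "amino_acid_seq must be non-empty exactly for in_frame clones")
        if (anyDuplicated(cl$nucleotide_seq))
            msg <- c(msg, "nucleotide_seq must be unique (merge duplicates on construction)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TCRRepertoire
#'
#' Rows sharing a nucleotide sequence are merged by summing templates
#' (rearrangement-level identity); merging rows must agree on amino-acid
#' sequence and frame type. Rows with zero templates are dropped.
#'
#' @param sampleId sample identifier.
#' @param tissue `"tumor"` or `"blood"`.
#' @param clones data.frame with columns `nucleotide_seq`, `amino_acid_seq`,
#'   `templates`, `frame_type`.
#' @return A [TCRRepertoire-class] object.
#' @examples
#' rep <- TCRRepertoire("S1", "tumor", data.frame(
#'     nucleotide_seq = c("TGTGCC", "TGTGCA"),
#'     amino_acid_seq = c("CASSF", "CAIRF"),
#'     templates = c(5L, 3L),
#'     frame_type = "in_frame"))
#' productiveTemplates(rep)
#' @export
TCRRepertoire <- function(sampleId, tissue, clones) {
    clones <- as.data.frame(clones, stringsAsFactors = FALSE)
    if (nrow(clones)) {
        clones <- clones[clones$templates > 0, , drop = FALSE]
    }
    if (nrow(clones) && anyDuplicated(clones$nucleotide_seq)) {
        agg <- tapply(clones$templates, clones$nucleotide_seq, sum)
        first <- clones[!duplicated(clones$nucleotide_seq), , drop = FALSE]
        consistent <- tapply(paste(clones$amino_acid_seq, clones$frame_type),
                             clones$nucleotide_seq,
                             function(x) length(unique(x)) == 1L)
        if (!all(consistent))
            stop("duplicate nucleotide_seq rows disagree on amino_acid_seq/frame_type")
        first$templates <- as.numeric(agg[first$nucleotide_seq])
        clones <- first
    }
    rownames(clones) <- NULL
    clones$templates <- as.numeric(clones$templates)
    new("TCRRepertoire", sampleId = as.character(sampleId),
        tissue = as.character(tissue), clones = clones)
}

#' TCRCohort: a set of repertoires with sample manifest and clinical data
#'
#' @slot repertoires named list of [TCRRepertoire-class] objects (names are
#'   sample ids).
#' @slot manifest `data.frame` with columns `sample_id`, `patient_id`,
#'   `tissue`, `group` — one row per repertoire.
#' @slot clinical `data.frame`, one row per patient (see [generateClinical()]
#'   / [readClinicalTable()] for the expected columns).
#' @exportClass TCRCohort
setClass("TCRCohort",
    representation(repertoires = "list", manifest = "data.frame",
                   clinical = "data.frame"))

setValidity("TCRCohort", function(object) {
    msg <- character()
    reps <- object@repertoires
    if (length(reps)) {
        if (!all(vapply(reps, is, logical(1), "TCRRepertoire")))
            msg <- c(msg, "repertoires must all be TCRRepertoire objects")
        ids <- vapply(reps, sampleId, character(1))
        if (anyDuplicated(ids))
            msg <- c(msg, "sample ids must be unique within a cohort")
        if (!identical(unname(names(reps)), unname(ids)))
            msg <- c(msg, "repertoire list names must equal their sampleIds")
        man <- object@manifest
        need <- c("sample_id", "patient_id", "tissue", "group")
        if (!all(need %in% names(man)))
            msg <- c(msg, sprintf("manifest needs columns %s",
                                  paste(need, collapse = ", ")))
        else if (!setequal(man$sample_id, ids))
            msg <- c(msg, "manifest sample_ids must match repertoires")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TCRCohort
#' @param repertoires list of [TCRRepertoire-class] objects.
#' @param manifest data.frame with `sample_id`, `patient_id`, `tissue`, `group`.
#' @param clinical per-patient data.frame (may be empty).
#' @return A [TCRCohort-class] object.
#' @export
TCRCohort <- function(repertoires, manifest, clinical = data.frame()) {
    names(repertoires) <- vapply(repertoires, sampleId, character(1))
    manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
    manifest <- manifest[match(names(repertoires), manifest$sample_id), ,
                         drop = FALSE]
    rownames(manifest) <- NULL
    new("TCRCohort", repertoires = repertoires, manifest = manifest,
        clinical = as.data.frame(clinical, stringsAsFactors = FALSE))
}

#' EpitopeDB: CDR3-to-epitope lookup table
#'
#' Deduplicated table mapping CDR3 amino-acid sequences to antigen species and
#' epitopes, in the style of a VDJdb export.
#'
#' @slot entries `data.frame` with columns `cdr3_aa`, `species`, `epitope`,
#'   `mhc_class`; `(cdr3_aa, species, epitope)` triples are unique.
#' @exportClass EpitopeDB
setClass("EpitopeDB", representation(entries = "data.frame"))

setValidity("EpitopeDB", function(object) {
    e <- object@entries
    need <- c("cdr3_aa", "species", "epitope", "mhc_class")
    if (!all(need %in% names(e)))
        return(sprintf("entries needs columns %s", paste(need, collapse = ", ")))
    if (nrow(e) && anyDuplicated(e[c("cdr3_aa", "species", "epitope")]))
        return("(cdr3_aa, species, epitope) triples must be unique")
    TRUE
})

#' Construct an EpitopeDB
#' @param entries data.frame with columns `cdr3_aa`, `species`, `epitope` and
#'   optionally `mhc_class`; duplicate triples are collapsed.
#' @return An [EpitopeDB-class] object.
#' @export
EpitopeDB <- function(entries = data.frame(cdr3_aa = character(),
                                           species = character(),
                                           epitope = character(),
                                           mhc_class = character())) {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    if (is.null(entries$mhc_class)) entries$mhc_class <- rep("", nrow(entries))
    entries <- entries[!duplicated(entries[c("cdr3_aa", "species", "epitope")]), ,
                       drop = FALSE]
    rownames(entries) <- NULL
    new("EpitopeDB", entries = entries[c("cdr3_aa", "species", "epitope",
                                         "mhc_class")])
}
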