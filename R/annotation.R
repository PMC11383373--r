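# Epitope annotation against a VDJdb-style lookup table: exact CDR3
# amino-acid matching, matched fractions and per-species epitope proportions.

.VDJDB_MAP <- c(cdr3_aa = "cdr3", species = "antigen.species",
                epitope = "antigen.epitope", mhc_class = "mhc.class")

#' Read a VDJdb-style epitope table
#'
#' Loads a TSV export mapping CDR3 amino-acid sequences to antigen species
#' and epitopes; duplicate (cdr3, species, epitope) triples are collapsed.
#' The MHC-class column is optional.
#'
#' @param path TSV path.
#' @param columnMap named character vector mapping the internal names
#'   `cdr3_aa`, `species`, `epitope`, `mhc_class` to file columns; defaults to
#'   the VDJdb export names (`cdr3`, `antigen.species`, `antigen.epitope`,
#'   `mhc.class`).
#' @return an [EpitopeDB-class].
#' @export
readEpitopeDB <- function(path, columnMap = .VDJDB_MAP) {
    map <- .VDJDB_MAP
    map[names(columnMap)] <- columnMap
    tab <- .readTSV(path)
    for (f in c("cdr3_aa", "species", "epitope"))
        if (!map[[f]] %in% names(tab))
            stop(sprintf("epitope table '%s' is missing column '%s'",
                         path, map[[f]]), call. = FALSE)
    EpitopeDB(data.frame(
        cdr3_aa = tab[[map[["cdr3_aa"]]]],
        species = tab[[map[["species"]]]],
        epitope = tab[[map[["epitope"]]]],
        mhc_class = if (map[["mhc_class"]] %in% names(tab))
            tab[[map[["mhc_class"]]]] else rep("", nrow(tab)),
        stringsAsFactors = FALSE))
}

#' Write an epitope table in VDJdb-export style
#' @param db an [EpitopeDB-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEpitopeDB <- function(db, path) {
    e <- entries(db)
    names(e) <- .VDJDB_MAP[names(e)]
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Annotate a clone set against an epitope database
#'
#' Matching is exact equality of the CDR3 amino-acid sequence. The matched
#' fraction is the share of the sample's distinct clones found in the
#' database. The per-species epitope proportion divides the number of clones
#' predicted to target that species by either the total number of clones
#' (`denominatorMode = "all_tcrs"`, the default) or the number of matched
#' clones (`"matched_tcrs"`). A clone with entries for several species counts
#' once toward each species' numerator but once toward the matched fraction.
#' Counting is at unique-clone level, not template-weighted.
#'
#' @param keys character vector of clone keys (see [cloneSet()]), or a
#'   [TCRRepertoire-class]; must be non-empty.
#' @param db an [EpitopeDB-class].
#' @param denominatorMode `"all_tcrs"` or `"matched_tcrs"`.
#' @return list with `matched_fraction`, `species_proportions` (named
#'   numeric) and `denominator_mode`.
#' @export
annotateCloneSet <- function(keys, db,
                             denominatorMode = c("all_tcrs", "matched_tcrs")) {
    denominatorMode <- match.arg(denominatorMode)
    if (is(keys, "TCRRepertoire")) keys <- cloneSet(keys)
    keys <- unique(keys)
    if (!length(keys))
        stop("cannot annotate an empty clone set", call. = FALSE)
    e <- entries(db)
    matched <- keys %in% e$cdr3_aa
    nMatched <- sum(matched)
    denom <- if (denominatorMode == "all_tcrs") length(keys) else nMatched
    sp <- sort(unique(e$species))
    props <- if (denom == 0) stats::setNames(rep(0, length(sp)), sp) else
        vapply(sp, function(s)
            sum(keys %in% unique(e$cdr3_aa[e$species == s])) / denom,
            numeric(1))
    list(matched_fraction = nMatched / length(keys),
         species_proportions = props,
         denominator_mode = denominatorMode)
}

#' Per-sample annotation table for a cohort
#'
#' @param cohort a [TCRCohort-class] or list of repertoires.
#' @param db an [EpitopeDB-class].
#' @param denominatorMode see [annotateCloneSet()].
#' @param tissue optional tissue restriction.
#' @param species species for which per-sample proportion columns are
#'   reported (default: every species in the database).
#' @return data.frame with one row per sample: `sample_id`, `tissue`,
#'   `group` (when known), `n_clones`, `matched_fraction` and one
#'   `prop_<species>` column per requested species. Samples with an empty
#'   productive clone set are skipped with a warning.
#' @export
annotateCohort <- function(cohort, db, denominatorMode = "all_tcrs",
                           tissue = NULL, species = NULL) {
    reps <- .tissueReps(cohort, tissue)
    if (is.null(species)) species <- sort(unique(entries(db)$species))
    man <- if (is(cohort, "TCRCohort")) manifest(cohort) else NULL
    rows <- list()
    for (r in reps) {
        ks <- cloneSet(r)
        if (!length(ks)) {
            warning(sprintf("sample '%s' has no productive clones; skipped",
                            sampleId(r)))
            next
        }
        a <- annotateCloneSet(ks, db, denominatorMode)
        row <- data.frame(sample_id = sampleId(r), tissue = tissue(r),
                          n_clones = length(ks),
                          matched_fraction = a$matched_fraction,
                          stringsAsFactors = FALSE)
        for (s in species)
            row[[paste0("prop_", s)]] <-
                if (s %in% names(a$species_proportions))
                    a$species_proportions[[s]] else 0
        rows[[length(rows) + 1L]] <- row
    }
    out <- do.call(rbind, rows)
    if (!is.null(out) && !is.null(man))
        out$group <- man$group[match(out$sample_id, man$sample_id)]
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
}

#' Group contrasts of per-species epitope proportions
#'
#' Runs pairwise Wilcoxon rank-sum comparisons of per-sample species
#' proportions between groups, one table per species. Groups with fewer than
#' two samples are flagged and their comparisons skipped with a warning.
#'
#' @param annotation data.frame from [annotateCohort()] (must carry a
#'   `group` column).
#' @param species species to contrast; defaults to the `prop_` columns
#'   present, preferring HIV, InfluenzaA, CMV and EBV when available.
#' @return data.frame of pairwise comparisons with a `species` column.
#' @export
speciesContrast <- function(annotation, species = NULL) {
    stopifnot("group" %in% names(annotation))
    propCols <- grep("^prop_", names(annotation), value = TRUE)
    avail <- sub("^prop_", "", propCols)
    if (is.null(species)) {
        pref <- c("HIV", "InfluenzaA", "CMV", "EBV")
        species <- if (any(pref %in% avail)) intersect(pref, avail) else avail
    }
    out <- list()
    for (s in species) {
        col <- paste0("prop_", s)
        if (!col %in% names(annotation)) next
        vals <- split(annotation[[col]], annotation$group)
        small <- names(vals)[vapply(vals, length, integer(1)) < 2]
        if (length(small)) {
            warning(sprintf("species '%s': group(s) %s have <2 samples; skipped",
                            s, paste(small, collapse = ", ")))
            vals <- vals[!names(vals) %in% small]
        }
        if (length(vals) < 2) next
        tab <- pairwiseWilcoxon(vals, variable = col)
        tab$species <- s
        out[[length(out) + 1L]] <- tab
    }
    if (!length(out)) return(data.frame())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
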