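# Clone-sharing analyses. All sharing analyses identify clones by the CDR3
# amino-acid sequence (productive clones only), so nucleotide variants of one
# clonotype collapse; clonality metrics, by contrast, are nucleotide-level.

#' Productive amino-acid clone set
#'
#' Distinct productive CDR3 amino-acid sequences of a repertoire; nucleotide
#' variants of the same amino-acid clonotype collapse to one key.
#'
#' @param rep a [TCRRepertoire-class].
#' @return character vector of distinct keys (possibly empty).
#' @export
cloneSet <- function(rep) {
    cl <- clones(productiveSubset(rep))
    unique(cl$amino_acid_seq)
}

# per-sample amino-acid-level frequency table (templates of key / productive)
.aaFrequencies <- function(rep) {
    cl <- clones(productiveSubset(rep))
    tot <- sum(cl$templates)
    if (tot < 1) return(stats::setNames(numeric(0), character(0)))
    t <- tapply(cl$templates, cl$amino_acid_seq, sum) / tot
    stats::setNames(as.numeric(t), names(t))
}

#' Pairwise repertoire overlap
#'
#' Overlap of two clone sets: the size of the intersection divided by the
#' size of the smaller repertoire. Symmetric, in `[0, 1]`, and equal to 1
#' whenever one set contains the other.
#'
#' @param a,b character vectors of clone keys (see [cloneSet()]); both must be
#'   non-empty.
#' @return numeric scalar in `[0, 1]`.
#' @export
pairwiseOverlap <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) || !length(b))
        stop("overlap is undefined for an empty repertoire", call. = FALSE)
    length(intersect(a, b)) / min(length(a), length(b))
}

.tissueReps <- function(cohort, tissue = NULL) {
    reps <- if (is(cohort, "TCRCohort")) repertoires(cohort) else cohort
    if (!is.null(tissue))
        reps <- Filter(function(r) methods::slot(r, "tissue") == tissue, reps)
    reps
}

.cohortGroups <- function(cohort, reps, grouping) {
    if (is.null(grouping) && is(cohort, "TCRCohort")) {
        man <- manifest(cohort)
        grouping <- stats::setNames(man$group, man$sample_id)
    }
    if (is.null(grouping))
        stop("a grouping (sample_id -> group) is required", call. = FALSE)
    ids <- unname(vapply(reps, sampleId, character(1)))
    if (!all(ids %in% names(grouping)))
        stop("grouping is missing some sample ids", call. = FALSE)
    grouping[ids]
}

#' All-pairs overlap matrix
#'
#' @param cohort a [TCRCohort-class] or list of repertoires.
#' @param tissue optional tissue restriction (`"tumor"` or `"blood"`).
#' @return symmetric numeric matrix with unit diagonal, dimnames the sample
#'   ids.
#' @export
overlapMatrix <- function(cohort, tissue = NULL) {
    reps <- .tissueReps(cohort, tissue)
    sets <- lapply(reps, cloneSet)
    ids <- unname(vapply(reps, sampleId, character(1)))
    n <- length(sets)
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    if (n >= 2)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            m[i, j] <- m[j, i] <- pairwiseOverlap(sets[[i]], sets[[j]])
    m
}

#' Overlap distributions with reference to one group
#'
#' Extracts, from an overlap matrix, the pairwise overlaps of every sample of
#' a reference group with (a) other samples of the reference group
#' (self-pairs excluded, each unordered pair counted once) and (b) samples of
#' each other group.
#'
#' @param mat matrix from [overlapMatrix()].
#' @param grouping named character vector mapping sample id to group.
#' @param reference reference group label.
#' @return data.frame with columns `sample_a`, `sample_b`, `comparison`
#'   (`within_<reference>` or the other group's label) and `overlap`.
#' @export
referenceOverlap <- function(mat, grouping, reference) {
    ids <- rownames(mat)
    grp <- grouping[ids]
    if (!reference %in% grp)
        stop(sprintf("no samples in reference group '%s'", reference),
             call. = FALSE)
    refIds <- ids[grp == reference]
    rows <- list()
    for (a in refIds) for (b in ids) {
        if (a == b) next
        if (grouping[b] == reference && a > b) next  # unordered within-pairs
        rows[[length(rows) + 1L]] <- data.frame(
            sample_a = a, sample_b = b,
            comparison = if (grouping[b] == reference)
                paste0("within_", reference) else unname(grouping[b]),
            overlap = mat[a, b], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Venn partition of clone keys by group
#'
#' Assigns every distinct productive amino-acid clone of a tissue to exactly
#' one region of the group Venn diagram: the set of groups whose samples
#' carry it. Region labels are the sorted group names joined by `+`.
#'
#' @inheritParams overlapMatrix
#' @param grouping optional named vector sample_id -> group (taken from the
#'   cohort manifest when absent).
#' @return data.frame with columns `region`, `count`, `percent`; all
#'   non-empty group combinations are listed (zero counts included) and the
#'   counts sum to the number of distinct keys.
#' @export
vennPartition <- function(cohort, tissue = NULL, grouping = NULL) {
    reps <- .tissueReps(cohort, tissue)
    grp <- .cohortGroups(cohort, reps, grouping)
    levels <- sort(unique(unname(grp)))
    keyGroups <- list()
    for (i in seq_along(reps)) {
        ks <- cloneSet(reps[[i]])
        g <- grp[[i]]
        keyGroups[[g]] <- unique(c(keyGroups[[g]], ks))
    }
    allKeys <- unique(unlist(keyGroups, use.names = FALSE))
    member <- vapply(levels, function(g) allKeys %in% keyGroups[[g]],
                     logical(length(allKeys)))
    if (length(allKeys) == 1L) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1L, function(m)
        paste(levels[m], collapse = "+"))
    combos <- unlist(lapply(seq_along(levels), function(k)
        utils::combn(levels, k, paste, collapse = "+", simplify = FALSE)),
        use.names = FALSE)
    counts <- stats::setNames(integer(length(combos)), combos)
    tt <- table(pattern)
    counts[names(tt)] <- as.integer(tt)
    data.frame(region = names(counts), count = as.integer(counts),
               percent = if (length(allKeys))
                   100 * as.integer(counts) / length(allKeys) else
                   rep(0, length(counts)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Public (shared) clones
#'
#' Clones present in at least `minSamples` distinct samples of a tissue,
#' sorted by the number of carrying samples (descending) then key.
#'
#' @inheritParams vennPartition
#' @param minSamples publicity threshold (default 5).
#' @return data.frame with columns `key`, `sample_count`, `sample_ids`
#'   (comma-joined) and one `n_<group>` count column per group.
#' @export
publicity <- function(cohort, tissue = NULL, minSamples = 5,
                      grouping = NULL) {
    reps <- .tissueReps(cohort, tissue)
    grp <- .cohortGroups(cohort, reps, grouping)
    ids <- unname(vapply(reps, sampleId, character(1)))
    long <- do.call(rbind, lapply(seq_along(reps), function(i) {
        ks <- cloneSet(reps[[i]])
        if (!length(ks)) return(NULL)
        data.frame(key = ks, sample_id = ids[i], group = grp[[i]],
                   stringsAsFactors = FALSE)
    }))
    levels <- sort(unique(unname(grp)))
    empty <- data.frame(key = character(), sample_count = integer(),
                        sample_ids = character(), stringsAsFactors = FALSE)
    for (g in levels) empty[[paste0("n_", g)]] <- integer()
    if (is.null(long)) return(empty)
    cnt <- table(long$key)
    keep <- names(cnt)[cnt >= minSamples]
    if (!length(keep)) return(empty)
    long <- long[long$key %in% keep, , drop = FALSE]
    out <- data.frame(key = keep,
                      sample_count = as.integer(cnt[keep]),
                      sample_ids = unname(vapply(keep, function(k)
                          paste(sort(long$sample_id[long$key == k]),
                                collapse = ","), character(1))),
                      stringsAsFactors = FALSE)
    for (g in levels)
        out[[paste0("n_", g)]] <- unname(vapply(keep, function(k)
            sum(long$group[long$key == k] == g), integer(1)))
    out <- out[order(-out$sample_count, out$key), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Clones shared exclusively within a set of groups
#'
#' Finds clones carried by at least `minSamples` samples, all of which belong
#' to `inGroups` (e.g. the two HIV-positive groups), and partitions them by
#' their occupancy pattern over those groups (e.g. ART-naive only, ART-exp
#' only, both). Also reports, per sample in `inGroups`, the summed
#' within-sample frequency of the clones in each partition.
#'
#' @inheritParams vennPartition
#' @param inGroups character vector of group labels defining exclusivity.
#' @param minSamples minimum number of carrying samples (default 2).
#' @return list with `records` (key, occupancy, sample_count),
#'   `partitionSizes` (named counts over occupancy patterns) and
#'   `sampleFrequencies` (sample_id, group, occupancy, frequency).
#' @export
exclusiveShared <- function(cohort, tissue = NULL, inGroups,
                            minSamples = 2, grouping = NULL) {
    reps <- .tissueReps(cohort, tissue)
    grp <- .cohortGroups(cohort, reps, grouping)
    if (!length(inGroups))
        stop("inGroups must name at least one group", call. = FALSE)
    ids <- unname(vapply(reps, sampleId, character(1)))
    sets <- lapply(reps, cloneSet)
    long <- do.call(rbind, lapply(seq_along(reps), function(i)
        if (length(sets[[i]]))
            data.frame(key = sets[[i]], sample_id = ids[i], group = grp[[i]],
                       stringsAsFactors = FALSE) else NULL))
    patterns <- unlist(lapply(seq_along(inGroups), function(k)
        utils::combn(sort(inGroups), k, paste, collapse = "+",
                     simplify = FALSE)), use.names = FALSE)
    emptySizes <- stats::setNames(integer(length(patterns)), patterns)
    if (is.null(long))
        return(list(records = data.frame(key = character(),
                                         occupancy = character(),
                                         sample_count = integer()),
                    partitionSizes = emptySizes,
                    sampleFrequencies = data.frame()))
    nSamp <- table(long$key)
    outside <- unique(long$key[!long$group %in% inGroups])
    keep <- setdiff(names(nSamp)[nSamp >= minSamples], outside)
    emptyRecords <- data.frame(key = character(), occupancy = character(),
                               sample_count = integer(),
                               stringsAsFactors = FALSE)
    inLong <- long[long$key %in% keep, , drop = FALSE]
    records <- if (length(keep)) {
        occ <- tapply(inLong$group, inLong$key, function(g)
            paste(sort(unique(g)), collapse = "+"))
        data.frame(key = unname(names(occ)), occupancy = unname(occ),
                   sample_count = as.integer(nSamp[names(occ)]),
                   stringsAsFactors = FALSE, row.names = NULL)
    } else emptyRecords
    records <- records[order(-records$sample_count, records$key), ,
                       drop = FALSE]
    rownames(records) <- NULL
    sizes <- emptySizes
    tt <- table(records$occupancy)
    sizes[names(tt)] <- as.integer(tt)
    inSamples <- which(unname(grp) %in% inGroups)
    freqRows <- list()
    for (i in inSamples) {
        f <- .aaFrequencies(reps[[i]])
        for (p in patterns) {
            ks <- records$key[records$occupancy == p]
            freqRows[[length(freqRows) + 1L]] <- data.frame(
                sample_id = ids[i], group = grp[[i]], occupancy = p,
                frequency = sum(f[names(f) %in% ks]),
                stringsAsFactors = FALSE)
        }
    }
    list(records = records, partitionSizes = sizes,
         sampleFrequencies = if (length(freqRows))
             do.call(rbind, freqRows) else data.frame())
}

#' Tumor-blood repertoire overlap
#'
#' Fraction of a patient's distinct tumor clones that are also found in the
#' same patient's blood: `|tumor ∩ blood| / |tumor|`. Directional (not
#' symmetric) and unaffected by blood clones absent from tumor.
#'
#' @param tumorSet,bloodSet clone-key vectors from [cloneSet()]; the tumor set
#'   must be non-empty.
#' @return numeric scalar in `[0, 1]`.
#' @export
tumorBloodOverlap <- function(tumorSet, bloodSet) {
    tumorSet <- unique(tumorSet)
    if (!length(tumorSet))
        stop("tumor clone set is empty", call. = FALSE)
    length(intersect(tumorSet, bloodSet)) / length(tumorSet)
}

#' Per-patient tumor-blood overlap table
#'
#' Computes [tumorBloodOverlap()] for every patient of a cohort with both a
#' tumor and a blood sample. If a patient has several samples of a tissue the
#' first by sample id is used, with a warning.
#'
#' @param cohort a [TCRCohort-class].
#' @return data.frame with `patient_id`, `group`, `age` (when clinical data
#'   are present), `tumor_sample`, `blood_sample`, `overlap`.
#' @export
tumorBloodTable <- function(cohort) {
    man <- manifest(cohort)
    reps <- repertoires(cohort)
    rows <- list()
    for (pid in unique(man$patient_id)) {
        t_ids <- sort(man$sample_id[man$patient_id == pid &
                                    man$tissue == "tumor"])
        b_ids <- sort(man$sample_id[man$patient_id == pid &
                                    man$tissue == "blood"])
        if (!length(t_ids) || !length(b_ids)) next
        if (length(t_ids) > 1 || length(b_ids) > 1)
            warning(sprintf("patient '%s' has multiple samples per tissue; using the first by sample_id",
                            pid))
        ts <- cloneSet(reps[[t_ids[1]]])
        if (!length(ts)) next
        rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid,
            group = man$group[man$patient_id == pid][1],
            tumor_sample = t_ids[1], blood_sample = b_ids[1],
            overlap = tumorBloodOverlap(ts, cloneSet(reps[[b_ids[1]]])),
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(patient_id = character(), group = character(),
                   tumor_sample = character(), blood_sample = character(),
                   overlap = numeric(), stringsAsFactors = FALSE)
    cli <- clinical(cohort)
    if (nrow(out) && nrow(cli) && "age" %in% names(cli))
        out$age <- cli$age[match(out$patient_id, cli$patient_id)]
    rownames(out) <- NULL
    out
}
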