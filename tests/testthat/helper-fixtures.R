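# Fixtures are built in code: small hand-written repertoires, random
# repertoires for property tests, and naive reference oracles coded
# independently of the implementation (plain loops over sets).

makeRep <- function(id = "S1", tissue = "tumor",
                    nt, aa, templates, frame) {
    TCRRepertoire(id, tissue, data.frame(
        nucleotide_seq = nt, amino_acid_seq = aa, templates = templates,
        frame_type = frame, stringsAsFactors = FALSE))
}

# simple all-productive repertoire from template counts
countsRep <- function(counts, id = "S1", tissue = "tumor",
                      aa = NULL) {
    n <- length(counts)
    if (is.null(aa)) aa <- paste0("CASS", LETTERS[seq_len(n)], "F")
    makeRep(id, tissue,
            nt = paste0("TGT", sprintf("%04d", seq_len(n))),
            aa = aa, templates = counts, frame = rep("in_frame", n))
}

# random productive repertoire over a key alphabet (for oracle comparisons)
randomAaRep <- function(id, tissue = "tumor", nClones = 20,
                        keyPool = sprintf("CK%02dF", 1:50)) {
    keys <- sample(keyPool, nClones, replace = FALSE)
    countsRep(sample(1:20, nClones, replace = TRUE), id = id,
              tissue = tissue, aa = keys)
}

# small, fast synthetic-cohort configuration used where the full-size
# defaults are not the point of the test
tinyConfig <- function(masterSeed = 42, ...) {
    args <- list(
        tumorCounts = c(HIV_neg = 3, HIV_pos_ART_naive = 3,
                        HIV_pos_ART_exp = 3),
        bloodCounts = c(HIV_neg = 2, HIV_pos_ART_naive = 2,
                        HIV_pos_ART_exp = 2),
        pairedCounts = c(HIV_neg = 2, HIV_pos_ART_naive = 2,
                         HIV_pos_ART_exp = 2),
        clonePoolSize = 400, publicPoolSize = 100,
        nonproductivePoolSize = 50,
        depthMedian = c(tumor = 385, blood = 4000),
        masterSeed = masterSeed)
    override <- list(...)
    args[names(override)] <- override
    do.call(cohortConfig, args)
}

## ---- naive reference oracles (independent of the implementation) ----

naivePairwiseOverlap <- function(a, b) {
    a <- unique(a); b <- unique(b)
    inter <- 0
    for (k in a) if (k %in% b) inter <- inter + 1
    inter / min(length(a), length(b))
}

naiveTumorBlood <- function(tumor, blood) {
    tumor <- unique(tumor)
    hits <- 0
    for (k in tumor) if (k %in% blood) hits <- hits + 1
    hits / length(tumor)
}

# per-key region classification by looping over samples
naiveVennCounts <- function(sets, groups) {
    keys <- unique(unlist(sets))
    out <- list()
    for (k in keys) {
        gs <- character(0)
        for (i in seq_along(sets))
            if (k %in% sets[[i]]) gs <- c(gs, groups[i])
        region <- paste(sort(unique(gs)), collapse = "+")
        out[[region]] <- (out[[region]] %||% 0L) + 1L
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

naivePublicity <- function(sets, ids, minSamples) {
    keys <- unique(unlist(sets))
    res <- list()
    for (k in keys) {
        carriers <- ids[vapply(sets, function(s) k %in% s, logical(1))]
        if (length(carriers) >= minSamples)
            res[[k]] <- sort(carriers)
    }
    res
}

naiveExclusive <- function(sets, ids, groups, inGroups, minSamples) {
    keys <- unique(unlist(sets))
    res <- list()
    for (k in keys) {
        idx <- which(vapply(sets, function(s) k %in% s, logical(1)))
        if (length(idx) < minSamples) next
        if (!all(groups[idx] %in% inGroups)) next
        res[[k]] <- paste(sort(unique(groups[idx])), collapse = "+")
    }
    res
}

# hand-coded Benjamini-Hochberg step-up
stepUpBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    prev <- 1
    for (i in n:1) {
        val <- min(prev, p[o[i]] * n / i)
        adj[o[i]] <- val
        prev <- val
    }
    adj
}
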