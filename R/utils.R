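# internal helpers: deterministic per-sample RNG streams and seed hygiene

.MOD31 <- 2147483647  # 2^31 - 1

#' Derive a deterministic per-sample seed
#'
#' Hashes a string label together with a master seed into a 31-bit integer, so
#' every sample gets its own reproducible RNG stream and adding samples to a
#' cohort never perturbs the draws of existing ones.
#'
#' @param masterSeed integer master seed.
#' @param label character label (typically a sample id).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(masterSeed, label) {
    stopifnot(length(label) == 1L, is.character(label))
    h <- 0
    for (v in utf8ToInt(label)) h <- (h * 131 + v) %% .MOD31
    s <- (h * 48271 + (as.numeric(masterSeed) %% .MOD31) * 69621 + 1) %% .MOD31
    as.integer(if (s == 0) 1 else s)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# md5 of an arbitrary R object, via a temporary serialized file
objectHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

# random CDR3-like amino-acid keys: "C" + core + "F"
.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randomStrings <- function(n, alphabet, len) {
    if (n == 0L) return(character(0))
    m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = n)
    do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

randomCDR3 <- function(n, coreLen = 9L) {
    if (n == 0L) return(character(0))
    paste0("C", .randomStrings(n, .AA_LETTERS, coreLen), "F")
}

randomDNA <- function(n, len = 39L) {
    .randomStrings(n, c("A", "C", "G", "T"), len)
}
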