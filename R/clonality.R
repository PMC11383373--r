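# Bulk clonality/diversity metrics: productive Simpson clonality, maximum
# productive frequency, unique productive rearrangements; the
# downsample-and-average scheme; clonal-expansion size profiles.

#' Productive clone frequencies
#'
#' Frequencies of the unique productive nucleotide rearrangements of a
#' repertoire: p_i = templates_i / productive_templates, computed on the
#' productive subset. Names are nucleotide sequences.
#'
#' @param rep a [TCRRepertoire-class].
#' @return named numeric vector summing to 1.
#' @export
cloneFrequencies <- function(rep) {
    cl <- clones(productiveSubset(rep))
    tot <- sum(cl$templates)
    if (tot < 1)
        stop(sprintf("repertoire '%s' has no productive templates",
                     sampleId(rep)), call. = FALSE)
    stats::setNames(cl$templates / tot, cl$nucleotide_seq)
}

.checkFreqs <- function(freqs) {
    if (!length(freqs))
        stop("empty frequency vector", call. = FALSE)
    if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6)
        stop("frequencies must be positive and sum to 1", call. = FALSE)
}

#' Productive Simpson clonality
#'
#' The square root of Simpson's index, `sqrt(sum(p_i^2))`, over productive
#' clone frequencies. Ranges over (0, 1]; equals 1 exactly for a monoclonal
#' repertoire and `1/sqrt(R)` for R equally frequent clones.
#'
#' @param freqs frequency vector from [cloneFrequencies()].
#' @return numeric scalar in (0, 1].
#' @export
simpsonClonality <- function(freqs) {
    .checkFreqs(freqs)
    sqrt(sum(freqs^2))
}

#' Maximum productive frequency
#'
#' Frequency of the most expanded productive clone.
#'
#' @inheritParams simpsonClonality
#' @return numeric scalar in (0, 1].
#' @export
maxProductiveFrequency <- function(freqs) {
    .checkFreqs(freqs)
    max(freqs)
}

#' Number of unique productive rearrangements
#'
#' Distinct productive nucleotide rearrangements in a sample; higher values
#' indicate greater diversity. Nucleotide-level: two rearrangements encoding
#' the same amino-acid CDR3 count separately.
#'
#' @param rep a [TCRRepertoire-class].
#' @return integer count.
#' @export
uniqueProductiveRearrangements <- function(rep) {
    sum(clones(rep)$frame_type == "in_frame")
}

.metricsRow <- function(simpson, maxfreq, unique, totalProd, downsampled,
                        depth = NA, iterations = NA, seed = NA) {
    data.frame(simpson_clonality = simpson, max_productive_frequency = maxfreq,
               unique_productive_rearrangements = unique,
               total_productive_templates = totalProd,
               downsampled = downsampled, depth = depth,
               iterations = iterations, seed = seed)
}

#' Plain (non-downsampled) clonality metrics
#'
#' @param rep a [TCRRepertoire-class] with at least one productive template.
#' @return one-row data.frame with `simpson_clonality`,
#'   `max_productive_frequency`, `unique_productive_rearrangements`,
#'   `total_productive_templates` and downsampling provenance fields.
#' @seealso [downsampledMetrics()]
#' @export
clonalityMetrics <- function(rep) {
    p <- cloneFrequencies(rep)
    .metricsRow(simpsonClonality(p), maxProductiveFrequency(p),
                as.numeric(uniqueProductiveRearrangements(rep)),
                productiveTemplates(rep), FALSE)
}

#' Downsampling-averaged clonality metrics
#'
#' Rarefies a repertoire to a common productive-template depth so clonality
#' metrics are comparable across samples with very different T cell input.
#' Each iteration draws `depth` productive templates uniformly without
#' replacement from the template multiset, recomputes the three metrics on
#' the draw, and the arithmetic mean over iterations is reported. With
#' `depth` equal to the full productive count every draw is the whole
#' repertoire and the averaged metrics equal the plain ones exactly.
#' Averaged unique-rearrangement counts are reported as reals, not rounded.
#'
#' @param rep a [TCRRepertoire-class] with `productiveTemplates(rep) >= depth`.
#' @param depth number of productive templates per draw (default 108, the
#'   usual lowest passing count just above a 100-template QC threshold; see
#'   [autoDepth()]).
#' @param iterations number of downsampling iterations (default 100).
#' @param seed optional integer making the whole procedure reproducible.
#' @return one-row data.frame as [clonalityMetrics()], with
#'   `downsampled = TRUE` and the depth/iterations/seed used.
#' @export
downsampledMetrics <- function(rep, depth = 108, iterations = 100,
                               seed = NULL) {
    stopifnot(iterations >= 1, depth >= 1)
    cl <- clones(productiveSubset(rep))
    tot <- sum(cl$templates)
    if (tot < depth)
        stop(sprintf(paste0("repertoire '%s' has %d productive templates, ",
                            "fewer than the downsampling depth %d"),
                     sampleId(rep), tot, depth), call. = FALSE)
    counts <- cl$templates
    idx <- rep.int(seq_along(counts), counts)
    sims <- withSeed(seed, {
        vapply(seq_len(iterations), function(i) {
            tab <- tabulate(if (tot == depth) idx else sample(idx, depth),
                            nbins = length(counts))
            p <- tab[tab > 0] / depth
            c(sqrt(sum(p^2)), max(p), length(p))
        }, numeric(3))
    })
    m <- rowMeans(sims)
    .metricsRow(m[1], m[2], m[3], tot, TRUE, depth, iterations,
                if (is.null(seed)) NA else seed)
}

#' Automatic downsampling depth
#'
#' The lowest productive-template count among QC-passing samples: every
#' passing sample can be rarefied to this depth, and no passing sample is
#' dropped.
#'
#' @param passed list of QC-passing [TCRRepertoire-class] objects.
#' @return integer depth.
#' @export
autoDepth <- function(passed) {
    if (!length(passed)) stop("no QC-passing samples", call. = FALSE)
    min(vapply(passed, productiveTemplates, numeric(1)))
}

.EXPANSION_BINS <- c(small = 1e-4, medium = 1e-3, large = 1e-2,
                     hyperexpanded = 1)

#' Clonal-expansion size profile
#'
#' Classifies every productive clone by the proportion of repertoire it
#' occupies — small (0, 1e-4], medium (1e-4, 1e-3], large (1e-3, 1e-2],
#' hyperexpanded (1e-2, 1] — and reports, per bin, the summed proportion of
#' repertoire occupied by its clones. Bins are left-open/right-closed, so a
#' clone at exactly 0.01 is "large" and one at exactly 1e-4 is "small";
#' the four proportions always sum to 1.
#'
#' @inheritParams simpsonClonality
#' @param edges upper bin edges (ascending, last must be 1).
#' @return named numeric vector of per-bin proportions.
#' @export
expansionProfile <- function(freqs, edges = .EXPANSION_BINS) {
    .checkFreqs(freqs)
    stopifnot(all(diff(edges) > 0), edges[length(edges)] == 1)
    bin <- cut(freqs, breaks = c(0, edges), labels = names(edges),
               right = TRUE)
    prop <- vapply(names(edges), function(b) sum(freqs[bin == b]), numeric(1))
    prop
}

#' Per-sample clonality table for a cohort
#'
#' Applies QC, recomputes the downsampling depth (`depth = "auto"` uses
#' [autoDepth()] on the passing samples), computes downsampled metrics for
#' each passing sample and the non-downsampled expansion profile, and
#' returns one row per passing sample. Per-sample RNG streams are derived
#' from `(masterSeed, sample_id)` via [deriveSeed()].
#'
#' @param cohort a [TCRCohort-class] or list of repertoires.
#' @param minProductive QC threshold (strict; default 100).
#' @param depth `"auto"` or an integer downsampling depth.
#' @param iterations downsampling iterations per sample.
#' @param masterSeed integer master seed.
#' @return data.frame, one row per QC-passing sample, with sample metadata,
#'   the downsampled metrics and the four expansion-bin proportions.
#' @export
cohortClonality <- function(cohort, minProductive = 100, depth = "auto",
                            iterations = 100, masterSeed = 1L) {
    qc <- qcFilter(cohort, minProductive)
    if (!length(qc$passed)) stop("no samples pass QC", call. = FALSE)
    if (identical(depth, "auto")) depth <- autoDepth(qc$passed)
    rows <- lapply(qc$passed, function(r) {
        m <- downsampledMetrics(r, depth = depth, iterations = iterations,
                                seed = deriveSeed(masterSeed, sampleId(r)))
        prof <- expansionProfile(cloneFrequencies(r))
        cbind(data.frame(sample_id = sampleId(r), tissue = tissue(r),
                         stringsAsFactors = FALSE),
              m, as.data.frame(as.list(prof)))
    })
    out <- do.call(rbind, rows)
    if (is(cohort, "TCRCohort")) {
        man <- manifest(cohort)
        out$group <- man$group[match(out$sample_id, man$sample_id)]
        out$patient_id <- man$patient_id[match(out$sample_id, man$sample_id)]
    }
    rownames(out) <- NULL
    out
}
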