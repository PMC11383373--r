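# Group comparisons, correlation, multiple-testing correction, median
# fold-changes and survival analysis. Standard tests are delegated to the
# stats and survival packages; this module fixes the conventions (exactness
# thresholds, tie handling, fold-change orientation, median-cutoff rule) and
# returns tidy one-row-per-comparison tables.

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test. The exact null distribution is used when both groups have
#' at most `exactThreshold` observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exactThreshold maximum per-group size for exact enumeration
#'   (default 10).
#' @param variable optional label stored in the result.
#' @return one-row data.frame: `variable`, `test`, `statistic` (rank-sum W),
#'   `p_value`, `exact`.
#' @export
wilcoxonRankSum <- function(x, y, exactThreshold = 10, variable = NA_character_) {
    if (!length(x) || !length(y))
        stop("both groups must be non-empty", call. = FALSE)
    exact <- length(x) <= exactThreshold && length(y) <= exactThreshold &&
        !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(variable = variable, test = "wilcoxon",
               statistic = unname(ht$statistic), p_value = ht$p.value,
               exact = exact, stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon comparisons with median fold-changes
#'
#' Tests every unordered pair of groups and attaches the median fold-change
#' `median(A) / median(B)` with the orientation given in `group_a` /
#' `group_b`. When the denominator median is zero the fold-change is `NA`
#' and the row is flagged.
#'
#' @param values named list mapping group label to a numeric sample.
#' @param variable optional label stored in the results.
#' @param adjust if `TRUE`, add Benjamini-Hochberg adjusted p-values across
#'   the returned pairs (default `FALSE`: pairwise p-values are reported
#'   unadjusted unless a correction is explicitly requested).
#' @param exactThreshold passed to [wilcoxonRankSum()].
#' @return data.frame, one row per pair: `variable`, `group_a`, `group_b`,
#'   `test`, `statistic`, `p_value`, (`p_adjusted`), `fold_change`,
#'   `fold_change_flag`.
#' @export
pairwiseWilcoxon <- function(values, variable = NA_character_, adjust = FALSE,
                             exactThreshold = 10) {
    stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
    gs <- names(values)
    rows <- list()
    for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs)) {
        a <- gs[i]; b <- gs[j]
        w <- wilcoxonRankSum(values[[a]], values[[b]], exactThreshold,
                             variable)
        mb <- stats::median(values[[b]])
        fc <- if (mb == 0) NA_real_ else stats::median(values[[a]]) / mb
        w$group_a <- a; w$group_b <- b
        w$fold_change <- fc
        w$fold_change_flag <- if (mb == 0) "denominator_median_zero" else ""
        rows[[length(rows) + 1L]] <- w
    }
    out <- do.call(rbind, rows)
    if (adjust) out$p_adjusted <- bhAdjust(out$p_value)
    cols <- c("variable", "group_a", "group_b", "test", "statistic",
              "p_value", if (adjust) "p_adjusted", "exact", "fold_change",
              "fold_change_flag")
    out <- out[cols]
    rownames(out) <- NULL
    out
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom.
#'
#' @inheritParams pairwiseWilcoxon
#' @return one-row data.frame: `variable`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
kruskalWallis <- function(values, variable = NA_character_) {
    values <- values[vapply(values, length, integer(1)) > 0]
    if (length(values) < 2)
        stop("need at least two non-empty groups", call. = FALSE)
    if (length(unique(unlist(values))) == 1L)
        return(data.frame(variable = variable, test = "kruskal_wallis",
                          statistic = 0, df = length(values) - 1L,
                          p_value = 1, stringsAsFactors = FALSE))
    ht <- stats::kruskal.test(values)
    data.frame(variable = variable, test = "kruskal_wallis",
               statistic = unname(ht$statistic),
               df = unname(ht$parameter), p_value = ht$p.value,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, with the
#' original order restored.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || !is.numeric(p))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling and a two-sided p-value
#' (t approximation, as appropriate in the presence of ties).
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param variable optional label.
#' @return one-row data.frame: `variable`, `test`, `statistic` (rho),
#'   `p_value`, `n`.
#' @export
spearmanCor <- function(x, y, variable = NA_character_) {
    if (length(x) != length(y) || length(x) < 3)
        stop("need paired vectors with n >= 3", call. = FALSE)
    ht <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(variable = variable, test = "spearman",
               statistic = unname(ht$estimate), p_value = ht$p.value,
               n = length(x), stringsAsFactors = FALSE)
}

#' Median-cutoff dichotomization
#'
#' Splits values at their median: strictly above the median is `"high"`, at
#' or below it is `"low"` (values tied with the median go to `"low"`).
#'
#' @param values named numeric vector (names are ids).
#' @return named character vector of `"high"` / `"low"`.
#' @export
medianDichotomize <- function(values) {
    if (length(unique(values)) < 2)
        stop("all values identical: median split is degenerate", call. = FALSE)
    m <- stats::median(values)
    stats::setNames(ifelse(values > m, "high", "low"), names(values))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling) of one variable of
#' interest, optionally adjusted for covariates. Non-convergence or a
#' monotone likelihood (complete separation, recognisable by an exploding
#' standard error) is flagged rather than silently reported.
#'
#' @param data data.frame containing the time, event, variable and covariate
#'   columns.
#' @param time,event column names of the follow-up time and event indicator
#'   (0/1 or logical).
#' @param variable column name of the covariate of interest (numeric or
#'   two-level).
#' @param adjustFor character vector of adjustment covariate columns.
#' @param endpoint label stored in the result (e.g. `"OS"`, `"PFS"`).
#' @return one-row data.frame: `endpoint`, `variable`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `n_events`, `adjusted_for`, `flagged`.
#' @export
coxFit <- function(data, time, event, variable, adjustFor = character(),
                   endpoint = NA_character_) {
    ev <- as.numeric(data[[event]])
    if (sum(ev) < 2)
        stop("need at least 2 events for a Cox fit", call. = FALSE)
    v <- data[[variable]]
    if (length(unique(v[!is.na(v)])) < 2)
        stop(sprintf("variable '%s' does not vary", variable), call. = FALSE)
    rhs <- paste(c(sprintf("`%s`", variable),
                   sprintf("`%s`", adjustFor)), collapse = " + ")
    f <- stats::as.formula(sprintf("survival::Surv(`%s`, `%s`) ~ %s",
                                   time, event, rhs))
    flagged <- ""
    fit <- withCallingHandlers(
        survival::coxph(f, data = data, ties = "efron"),
        warning = function(w) {
            flagged <<- paste(flagged, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    s <- summary(fit)
    co <- s$coefficients[1, , drop = TRUE]
    se <- co[["se(coef)"]]
    if (!is.finite(se) || se > 50)
        flagged <- paste(flagged, "monotone likelihood / unstable estimate")
    data.frame(endpoint = endpoint, variable = variable,
               hr = unname(exp(co[["coef"]])),
               ci_low = unname(exp(co[["coef"]] - 1.96 * se)),
               ci_high = unname(exp(co[["coef"]] + 1.96 * se)),
               p_value = unname(co[["Pr(>|z|)"]]),
               n = s$n, n_events = s$nevent,
               adjusted_for = paste(adjustFor, collapse = ","),
               flagged = trimws(flagged), stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves with per-stratum median survival
#'
#' Product-limit survival estimates, optionally stratified. The median
#' survival of a stratum is the first time at which the estimated survival
#' drops to 0.5 or below, `NA` when never reached. Empty strata are skipped
#' with a warning.
#'
#' @inheritParams coxFit
#' @param strata optional column name to stratify by.
#' @return list with `points` (stratum, time, n_risk, n_event, n_censor,
#'   surv) and `median` (stratum, n, events, median).
#' @export
kmCurve <- function(data, time, event, strata = NULL,
                    endpoint = NA_character_) {
    if (!is.null(strata)) {
        empty <- names(which(table(data[[strata]]) == 0))
        if (length(empty))
            warning(sprintf("empty stratum(s) skipped: %s",
                            paste(empty, collapse = ", ")))
        f <- stats::as.formula(sprintf(
            "survival::Surv(`%s`, `%s`) ~ `%s`", time, event, strata))
    } else {
        f <- stats::as.formula(sprintf(
            "survival::Surv(`%s`, `%s`) ~ 1", time, event))
    }
    fit <- survival::survfit(f, data = data)
    sm <- summary(fit, censored = TRUE)
    strat <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
        sub("^.*=", "", as.character(sm$strata))
    points <- data.frame(stratum = strat, time = sm$time,
                         n_risk = sm$n.risk, n_event = sm$n.event,
                         n_censor = sm$n.censor, surv = sm$surv,
                         stringsAsFactors = FALSE)
    med <- do.call(rbind, lapply(split(points, points$stratum), function(d) {
        hit <- d$time[d$surv <= 0.5]
        data.frame(stratum = d$stratum[1], n = max(d$n_risk),
                   events = sum(d$n_event),
                   median = if (length(hit)) min(hit) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    rownames(med) <- NULL
    list(points = points, median = med, endpoint = endpoint)
}
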