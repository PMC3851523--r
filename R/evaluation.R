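# Validation protocol: top-K overlap with gold-standard subsets at
# increasing evidence-support thresholds, reported absolutely and relative
# to the spectral-count-ranking baseline.

#' Top-K validation curves against a gold standard
#'
#' For each support threshold `k`, counts how many of the top-`K` ranked
#' predictions (descending score, ties broken by `(a, b)` ascending byte
#' order) fall in the gold subset of pairs supported by at least `k`
#' distinct sources. Predicted pairs absent from every gold source count as
#' non-validated; matching is orientation-insensitive; bait-prey and
#' prey-prey predictions are pooled.
#'
#' @param ranked a non-empty [PairScoreTable-class].
#' @param gold a [GoldStandard-class].
#' @param cutoffs strictly increasing positive rank cutoffs `K`.
#' @param thresholds positive integer support thresholds `k`.
#' @return data.frame with one row per (threshold, cutoff): columns
#'   `threshold`, `cutoff`, `validated`, `truncated` (`TRUE` when the
#'   ranked list is shorter than the cutoff, in which case the full list
#'   was used).
#' @examples
#' tab <- PairScoreTable(c("A","A"), c("B","C"), c(2, 1), "demo")
#' gs <- GoldStandard("A", "C", 2L)
#' evaluateTopK(tab, gs, cutoffs = c(1, 2), thresholds = 1:2)
#' @export
evaluateTopK <- function(ranked, gold, cutoffs, thresholds) {
    stopifnot(is(ranked, "PairScoreTable"), is(gold, "GoldStandard"))
    if (!nrow(ranked@scores)) stop("ranked table is empty")
    cutoffs <- as.integer(cutoffs)
    if (any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE))
        stop("cutoffs must be strictly increasing and positive")
    thresholds <- as.integer(thresholds)
    if (any(thresholds < 1)) stop("thresholds must be positive integers")
    df <- rankedPairs(ranked)
    keys <- pairKeys(df$a, df$b)
    out <- do.call(rbind, lapply(thresholds, function(k) {
        goldK <- goldSubset(gold, k)
        hit <- cumsum(keys %in% goldK)
        kk <- pmin(cutoffs, length(keys))
        data.frame(threshold = k, cutoff = cutoffs,
                   validated = hit[kk],
                   truncated = cutoffs > length(keys))
    }))
    rownames(out) <- NULL
    out
}

#' Validated counts relative to a baseline method
#'
#' Elementwise difference (method minus baseline) of validated counts on a
#' matching (threshold, cutoff) grid.
#'
#' @param curves evaluation table of the method (from [evaluateTopK()]).
#' @param baseline evaluation table of the baseline on the same grid.
#' @return the `curves` table with extra columns `baseline_validated` and
#'   `difference`.
#' @export
relativeToBaseline <- function(curves, baseline) {
    key <- function(d) paste(d$threshold, d$cutoff)
    if (nrow(curves) != nrow(baseline) ||
        !all(key(curves) == key(baseline)))
        stop("curves and baseline must share the same (threshold, cutoff) grid")
    curves$baseline_validated <- baseline$validated
    curves$difference <- curves$validated - baseline$validated
    curves
}

#' Average precision of a ranking against a reference pair set
#'
#' Mean of the precision at the rank of each reference pair retrieved
#' (AP with the standard convention of averaging over all reference pairs,
#' so unretrieved reference pairs contribute 0).
#'
#' @param ranked a [PairScoreTable-class].
#' @param truePairs character vector of pair keys ([pairKeys()]) or a
#'   [GoldStandard-class] (all its pairs).
#' @return average precision in \[0, 1\].
#' @export
averagePrecision <- function(ranked, truePairs) {
    if (is(truePairs, "GoldStandard")) truePairs <- goldSubset(truePairs, 1L)
    if (!length(truePairs)) return(NA_real_)
    df <- rankedPairs(ranked)
    if (!nrow(df)) return(0)
    keys <- pairKeys(df$a, df$b)
    rel <- keys %in% truePairs
    if (!any(rel)) return(0)
    prec <- cumsum(rel) / seq_along(rel)
    sum(prec[rel]) / length(truePairs)
}

#' Improvement of the sampling ensemble over direct binarization, by p
#'
#' For each reliability value `p`, runs the ensemble, evaluates validated
#' counts at the given cutoff/threshold, and reports the improvement over
#' the same scorer applied to the direct binarization (the ensemble's
#' exact `p = 1` limit). At `p = 1` the improvement is 0 by construction.
#'
#' @param x a [SpectralCountMatrix-class].
#' @param scorer a [ScorerSpec-class] or scorer name.
#' @param pValues numeric vector of reliabilities in (0, 1].
#' @param gold a [GoldStandard-class].
#' @param cutoff single rank cutoff K.
#' @param threshold single support threshold k.
#' @param trials ensemble size per p.
#' @param seed base seed.
#' @param clampFloor per-realization floor (`NULL` = scorer default).
#' @return data.frame with columns `p`, `validated`,
#'   `binarization_validated`, `improvement`.
#' @export
sweepP <- function(x, scorer, pValues, gold, cutoff, threshold = 1L,
                   trials = 120L, seed = 1L, clampFloor = NULL) {
    if (is.character(scorer)) scorer <- scorerSpec(scorer)
    if (any(pValues <= 0 | pValues > 1)) stop("p values must lie in (0, 1]")
    binTab <- ensembleScore(x, ensembleConfig(p = 1, trials = 1L,
                                              seed = seed, scorer = scorer,
                                              clampFloor = clampFloor))
    binVal <- evaluateTopK(binTab, gold, cutoffs = cutoff,
                           thresholds = threshold)$validated
    rows <- lapply(pValues, function(p) {
        tab <- ensembleScore(x, ensembleConfig(p = p, trials = trials,
                                               seed = seed, scorer = scorer,
                                               clampFloor = clampFloor))
        val <- evaluateTopK(tab, gold, cutoffs = cutoff,
                            thresholds = threshold)$validated
        data.frame(p = p, validated = val, binarization_validated = binVal,
                   improvement = val - binVal)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
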