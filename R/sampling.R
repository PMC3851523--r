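# The sampling framework: counts -> probabilities -> ensemble of Bernoulli
# binary realizations -> per-realization scores -> mean aggregation.

#' Convert a spectral count to an observation probability
#'
#' `1 - (1 - p)^n`: the probability that at least one of `n` spectral
#' counts is a true observation, each count independently being real with
#' probability `p`. Strictly increasing in `n` for `p < 1`; 0 at `n = 0`.
#'
#' @param n non-negative integer spectral count (vectorized).
#' @param p per-count reliability in (0, 1].
#' @return probability in \[0, 1\].
#' @examples
#' countToProbability(2, 0.3)  # 0.51
#' @export
countToProbability <- function(n, p) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        stop("p must lie in (0, 1]")
    if (any(n < 0) || any(n != round(n)))
        stop("counts must be non-negative integers")
    1 - (1 - p)^n
}

#' Elementwise probability conversion of a count matrix
#'
#' Applies [countToProbability()] to every cell, preserving shape and
#' identifiers. Cells are zero exactly where the count is zero.
#'
#' @param x a [SpectralCountMatrix-class].
#' @param p per-count reliability in (0, 1].
#' @return a [ProbabilityMatrix-class].
#' @export
buildProbabilityMatrix <- function(x, p) {
    stopifnot(is(x, "SpectralCountMatrix"))
    cts <- spectralCounts(x)
    probs <- countToProbability(cts, p)
    dim(probs) <- dim(cts)
    dimnames(probs) <- dimnames(cts)
    new("ProbabilityMatrix", probs = probs)
}

# Seed of the substream for one (base seed, trial) combination, kept below
# 2^31 - 1. Distinct trials of one run map to distinct substream seeds.
.trialSeed <- function(seed, trial) {
    as.integer((abs(as.numeric(seed)) %% 100000) * 20011 +
               as.numeric(trial) * 7919 + 13) %% 2147483647L
}

#' Sample one binary realization of a probability matrix
#'
#' Every cell is an independent Bernoulli draw of its probability. The draw
#' stream is a pure function of `(seed, trialIndex)` with cells filled in a
#' fixed (column-major) order, so any trial can be regenerated in isolation
#' and serial and trial-parallel runs agree bit for bit.
#'
#' @param probs a [ProbabilityMatrix-class].
#' @param seed integer base seed of the ensemble.
#' @param trialIndex non-negative integer trial number.
#' @return a [BinaryRealization-class]; cells with probability 0 are always
#'   0 and cells with probability 1 always 1.
#' @export
sampleRealization <- function(probs, seed, trialIndex = 0L) {
    stopifnot(is(probs, "ProbabilityMatrix"))
    pm <- probabilities(probs)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(.trialSeed(seed, trialIndex))
    u <- runif(length(pm))
    cells <- (u < pm) + 0L
    dim(cells) <- dim(pm)
    dimnames(cells) <- dimnames(pm)
    new("BinaryRealization", cells = cells,
        trialIndex = as.integer(trialIndex))
}

#' Deterministic binarization of a count matrix
#'
#' Replaces every positive spectral count by 1 — the common single-matrix
#' approach that the sampling ensemble generalizes, and the ensemble's
#' exact limit at `p = 1`.
#'
#' @param x a [SpectralCountMatrix-class].
#' @return a [BinaryRealization-class] with `trialIndex = 0`.
#' @export
directBinarization <- function(x) {
    stopifnot(is(x, "SpectralCountMatrix"))
    cts <- spectralCounts(x)
    new("BinaryRealization", cells = (cts > 0) + 0L, trialIndex = 0L)
}

#' Ensemble-aggregated pair scores
#'
#' The core of the framework. For each of `config@trials` trials, a binary
#' realization of the count matrix is sampled from the cellwise
#' probabilities `1 - (1 - p)^n` and scored with the configured binary
#' scorer; per-pair scores are then averaged over the ensemble.
#'
#' The candidate pair universe is fixed up front from the deterministic
#' binarization of the raw counts (a superset of every realization's
#' co-occurrences), so the mean is taken over a constant pair set; a pair
#' absent from one realization's score table contributes 0 for that trial.
#' When `config@clampFloor` is set (default 0 for SAI), each
#' per-realization score is floored there before averaging, preventing a
#' single realization's unbounded negative score from dominating the mean.
#'
#' With `p = 1` every realization equals the direct binarization and the
#' ensemble score reduces exactly to the single-matrix score.
#'
#' @param x a [SpectralCountMatrix-class].
#' @param config an [EnsembleConfig-class] (see [ensembleConfig()]).
#' @param useControls include control columns (default `FALSE`).
#' @param includeBait include baits in presence sets (default: when bait
#'   metadata exists).
#' @param progress optional `function(trial, trials)` invoked every 10
#'   trials (used by the command-line front end for progress logging).
#' @return a [PairScoreTable-class]; deterministic given `(x, config)`.
#' @examples
#' m <- matrix(c(4L, 1L, 0L, 2L, 3L, 1L), 3,
#'             dimnames = list(c("A", "B", "C"), c("e1", "e2")))
#' scm <- SpectralCountMatrix(m)
#' ensembleScore(scm, ensembleConfig(p = 0.3, trials = 20, seed = 7))
#' @export
ensembleScore <- function(x, config, useControls = FALSE,
                          includeBait = NULL, progress = NULL) {
    stopifnot(is(x, "SpectralCountMatrix"), is(config, "EnsembleConfig"))
    validObject(config)
    bait <- baitOf(x); ctl <- isControl(x)
    binCells <- realizationCells(directBinarization(x))
    pm0 <- .presenceMatrix(binCells, bait = bait, isControl = ctl,
                           includeBait = includeBait,
                           useControls = useControls)
    spoke <- config@scorer@name %in% c("sai", "pe")
    idx <- .candidatePairs(pm0, spoke = spoke)
    if (!nrow(idx))
        return(new("PairScoreTable",
                   scores = data.frame(a = character(), b = character(),
                                       score = numeric()),
                   scorer = paste0("ensemble_", config@scorer@name),
                   params = c(config@scorer@params,
                              list(p = config@p, trials = config@trials,
                                   seed = config@seed))))
    probs <- buildProbabilityMatrix(x, config@p)
    acc <- numeric(nrow(idx))
    for (t in seq_len(config@trials) - 1L) {
        real <- sampleRealization(probs, config@seed, t)
        pmT <- .presenceMatrix(realizationCells(real), bait = bait,
                               isControl = ctl,
                               includeBait = pm0$includeBait,
                               useControls = useControls)
        S <- .scoreMatrixFor(pmT, config@scorer)
        sc <- S[idx]
        if (!is.na(config@clampFloor))
            sc <- pmax(sc, config@clampFloor)
        # pairs outside this realization's candidate universe contribute 0
        sc[!.universeMask(pmT, spoke = spoke)[idx]] <- 0
        acc <- acc + sc
        if (!is.null(progress) && (t + 1L) %% 10L == 0L)
            progress(t + 1L, config@trials)
    }
    new("PairScoreTable",
        scores = data.frame(a = pm0$proteins[idx[, 1L]],
                            b = pm0$proteins[idx[, 2L]],
                            score = acc / config@trials,
                            stringsAsFactors = FALSE),
        scorer = paste0("ensemble_", config@scorer@name),
        params = c(config@scorer@params,
                   list(p = config@p, trials = config@trials,
                        seed = config@seed,
                        clampFloor = config@clampFloor)))
}

#' Rank stability of the ensemble under a larger ensemble size
#'
#' Spearman rank correlation, over the shared candidate universe, between
#' ensemble scores at `config@trials` trials and at `factor` times as many
#' trials drawn from a disjoint seed stream. Values near 1 indicate the
#' ensemble size suffices to average out sampling stochasticity (at
#' `p = 1` the correlation is exactly 1).
#'
#' @param x a [SpectralCountMatrix-class].
#' @param config an [EnsembleConfig-class].
#' @param factor integer >= 2 enlargement of the ensemble.
#' @return Spearman correlation in \[-1, 1\].
#' @export
ensembleStability <- function(x, config, factor = 4L) {
    stopifnot(factor >= 2L)
    s1 <- ensembleScore(x, config)
    cfg2 <- ensembleConfig(p = config@p,
                           trials = as.integer(factor * config@trials),
                           seed = config@seed + 99991L,
                           scorer = config@scorer,
                           clampFloor = config@clampFloor)
    s2 <- ensembleScore(x, cfg2)
    k1 <- pairKeys(s1@scores$a, s1@scores$b)
    k2 <- pairKeys(s2@scores$a, s2@scores$b)
    shared <- intersect(k1, k2)
    v1 <- s1@scores$score[match(shared, k1)]
    v2 <- s2@scores$score[match(shared, k2)]
    if (length(shared) < 2L) return(1)
    if (isTRUE(all.equal(v1, v2))) return(1)
    cor(v1, v2, method = "spearman")
}
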