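# Binary-matrix PPI scorers applied to one 0/1 realization.
#
# All scorers consume the internal presence representation (proteins x
# experiments) so that an ensemble run and a single-realization run go
# through exactly the same code path. Scores are natural-log based; tail
# probabilities are floored at .TAIL_FLOOR before -log so scores stay
# finite.

.scoreCap <- function() -log(.TAIL_FLOOR)

.poisTailScore <- function(X, lambda, tail = "gt") {
    # -log P[Pois(lambda) > X] ("gt", the printed -log(1 - CDF(X)) form)
    # or -log P[Pois(lambda) >= X] ("ge"); 0 when lambda == 0.
    q <- if (tail == "gt") X else X - 1
    logp <- ppois(q, lambda, lower.tail = FALSE, log.p = TRUE)
    out <- pmin(-logp, .scoreCap())
    out[lambda == 0] <- 0
    out
}

.hyperTailScore <- function(X, m, k, N, tail = "gt") {
    # -log P[H > X] / P[H >= X] for H ~ Hypergeometric(population N,
    # m marked, k drawn); symmetric in (m, k).
    if (any(m > N) || any(k > N))
        stop("hypergeometric marginals exceed the population size")
    q <- if (tail == "gt") X else X - 1
    logp <- phyper(q, m, N - m, k, lower.tail = FALSE, log.p = TRUE)
    pmin(-logp, .scoreCap())
}

#' Hart-style Poisson null-model score
#'
#' Scores a pair by how surprising its co-purification count is under a
#' rank-one null in which partners co-occur at rate
#' `lambda = nOf[A] * nOf[B] / nTotal`:
#' `score = -log(1 - PoissonCDF(X_AB; lambda))` (the strictly-greater tail;
#' `tail = "ge"` uses `P[X >= X_AB]`). Returns 0 when `lambda` is 0.
#'
#' @param stats a [CooccurrenceStats-class].
#' @param a,b protein identifier vectors (pairs scored elementwise).
#' @param tail `"gt"` (default, as printed) or `"ge"`.
#' @return non-negative numeric scores, symmetric in `a`, `b`.
#' @export
hartPoissonScore <- function(stats, a, b, tail = "gt") {
    lambda <- lambdaOf(stats, a, b)
    X <- cooccurrenceOf(stats, a, b)
    .poisTailScore(X, lambda, tail)
}

#' Hart-style hypergeometric null-model score
#'
#' The exact-null counterpart of [hartPoissonScore()]: the co-purification
#' count of a pair is referred to a hypergeometric distribution with
#' population `nTotal`, `nOf[A]` marked items and `nOf[B]` draws (a
#' parameterization symmetric in the two proteins). For a shared `(X,
#' lambda)` the Poisson score converges to this one as the population
#' grows.
#'
#' @inheritParams hartPoissonScore
#' @return non-negative numeric scores, symmetric in `a`, `b`.
#' @export
hartHypergeometricScore <- function(stats, a, b, tail = "gt") {
    if (stats@nTotal < 1) stop("hypergeometric score needs nTotal >= 1")
    miss <- setdiff(c(a, b), names(stats@nOf))
    if (length(miss))
        stop("unknown protein(s): ", paste(miss, collapse = ", "))
    m <- unname(stats@nOf[a]); k <- unname(stats@nOf[b])
    X <- cooccurrenceOf(stats, a, b)
    .hyperTailScore(X, m, k, stats@nTotal, tail)
}

# Full score matrix over all observed proteins for the null-model scorers.
.hartScoreMatrix <- function(stats, type = c("poisson", "hypergeometric"),
                             tail = "gt") {
    type <- match.arg(type)
    n <- length(stats@nOf)
    if (n == 0L) return(stats@X)
    if (stats@nTotal == 0) {
        S <- matrix(0, n, n, dimnames = dimnames(stats@X))
        return(S)
    }
    L <- outer(stats@nOf, stats@nOf) / stats@nTotal
    S <- if (type == "poisson") .poisTailScore(stats@X, L, tail)
         else .hyperTailScore(stats@X, outer(stats@nOf, rep(1, n)),
                              outer(rep(1, n), stats@nOf), stats@nTotal,
                              tail)
    dim(S) <- c(n, n)
    dimnames(S) <- dimnames(stats@X)
    diag(S) <- 0
    S
}

# Spoke/matrix building blocks shared by SAI and PE. From a presence
# representation, derive: B (bait indicator), R (prey retrievals, bait
# excluded), n_spoke[i,j] = experiments with bait i retrieving prey j,
# n_mat[i,j] = co-retrievals as preys (bait experiments of i or j excluded
# automatically since R zeroes the bait row).
.spokeMatrixParts <- function(pm) {
    P <- pm$P
    proteins <- pm$proteins
    nE <- length(pm$experiments)
    B <- matrix(0L, nrow(P), nE, dimnames = dimnames(P))
    hasB <- which(!is.na(pm$bait))
    if (!length(hasB)) stop("bait metadata is required for this scorer")
    B[cbind(match(pm$bait[hasB], proteins), hasB)] <- 1L
    R <- P * (1L - B)
    nspoke <- tcrossprod(B, R)    # [i, j] = sum_e B[i,e] R[j,e]
    nmat <- tcrossprod(R)
    diag(nmat) <- 0
    list(B = B, R = R, nspoke = nspoke, nmat = nmat,
         rbait = rowSums(B), mprey = rowSums(R), nE = nE)
}

# Socio-affinity index over all protein pairs. Observed/expected log-ratio
# form with additive (+1) smoothing: two directed spoke terms plus a
# prey-prey matrix term. Can be negative; finite by construction.
.saiScoreMatrix <- function(pm) {
    pr <- .spokeMatrixParts(pm)
    if (pr$nE == 0L)
        return(matrix(0, length(pm$proteins), length(pm$proteins),
                      dimnames = list(pm$proteins, pm$proteins)))
    Espoke <- outer(pr$rbait, pr$mprey) / pr$nE   # expected n_spoke[i,j]
    S <- log((pr$nspoke + 1) / (Espoke + 1))
    Emat <- outer(pr$mprey, pr$mprey) / pr$nE     # expected co-retrievals
    M <- log((pr$nmat + 1) / (Emat + 1))
    out <- S + t(S) + M
    diag(out) <- 0
    out
}

# Purification-enrichment score over all protein pairs: per-experiment
# log-likelihood ratios of the observation under "interacting" (detection
# probability r) vs "background" (prey-specific frequency f_j, regularized
# with n_pseudo pseudocounts at the average prey frequency), summed over
# spoke (bait i -> prey j, both directions) and matrix (co-retrieval as
# preys) evidence.
.peScoreMatrix <- function(pm, r = 0.3, n_pseudo = 10) {
    if (r <= 0 || r >= 1) stop("pe: r must lie strictly in (0, 1)")
    if (n_pseudo < 0) stop("pe: n_pseudo must be >= 0")
    pr <- .spokeMatrixParts(pm)
    n <- length(pm$proteins)
    if (pr$nE == 0L)
        return(matrix(0, n, n, dimnames = list(pm$proteins, pm$proteins)))
    f0 <- sum(pr$mprey) / (pr$nE * max(n, 1L))
    f <- (pr$mprey + n_pseudo * f0) / (pr$nE + n_pseudo)
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
    # spoke: bait i's r_i experiments; prey j seen in n_spoke[i,j] of them
    lposj <- log(r / f); lnegj <- log((1 - r) / (1 - f))
    S <- sweep(pr$nspoke, 2L, lposj, `*`) +
         sweep(outer(pr$rbait, rep(1, n)) - pr$nspoke, 2L, lnegj, `*`)
    spoke <- S + t(S)
    # matrix: experiments where neither protein is bait and at least one is
    # retrieved; both retrieved = nmat, exactly one derived by counting
    ff <- outer(f, f)
    one <- outer(pr$mprey, rep(1, n)) - t(pr$nspoke) +
           outer(rep(1, n), pr$mprey) - pr$nspoke - 2 * pr$nmat
    M <- pr$nmat * log(r / ff) + one * log((1 - r) / (1 - ff))
    out <- spoke + M
    diag(out) <- 0
    out
}

#' Socio-affinity index (SAI) scores
#'
#' Log-odds-style association score combining, for each unordered pair, two
#' directed spoke terms (how often each protein retrieves the other when it
#' is the bait, relative to chance) and a matrix term (how often the two are
#' co-retrieved as preys, relative to chance). Scores may be negative; the
#' ensemble aggregator, not this function, applies the lower bound at 0.
#'
#' @param sets per-experiment protein sets from [presenceSets()] (or the
#'   internal presence representation).
#' @param bait named character vector experiment -> bait protein (required).
#' @return a [PairScoreTable-class] over the candidate pair universe (pairs
#'   that co-occur, plus bait-prey pairs).
#' @export
saiScore <- function(sets, bait) {
    pm <- .setsToPm(sets, bait)
    .pairTableFromMatrix(.saiScoreMatrix(pm), pm, spoke = TRUE,
                         scorer = "sai")
}

#' Purification enrichment (PE) scores
#'
#' Bayesian-style combined spoke/matrix score: each experiment contributes
#' the log-likelihood ratio of the observed presence pattern under an
#' interacting model (detection probability `r`) versus a background model
#' (prey-specific retrieval frequency regularized by `n_pseudo`
#' pseudocounts at the average prey frequency). Defaults are 0.3 for `r`
#' and 10 for `n_pseudo`.
#'
#' @inheritParams saiScore
#' @param r probability of detecting a true association in a purification,
#'   strictly in (0, 1).
#' @param n_pseudo pseudocounts added for each prey (>= 0).
#' @return a [PairScoreTable-class] over the candidate pair universe.
#' @export
peScore <- function(sets, bait, r = 0.3, n_pseudo = 10) {
    pm <- .setsToPm(sets, bait)
    .pairTableFromMatrix(.peScoreMatrix(pm, r = r, n_pseudo = n_pseudo),
                         pm, spoke = TRUE, scorer = "pe",
                         params = list(r = r, n_pseudo = n_pseudo))
}

# Coerce public presence sets (list of protein vectors) into the internal
# representation, attaching bait metadata.
.setsToPm <- function(sets, bait = NULL) {
    if (is.list(sets) && !is.null(sets$P)) {
        pm <- sets
    } else {
        proteins <- .C_sort(unique(c(unlist(sets, use.names = FALSE),
                                     unname(bait[!is.na(bait)]))))
        P <- matrix(0L, length(proteins), length(sets),
                    dimnames = list(proteins, names(sets)))
        for (j in seq_along(sets))
            P[match(unique(sets[[j]]), proteins), j] <- 1L
        pm <- list(P = P, proteins = proteins, experiments = names(sets))
    }
    if (!is.null(bait) && (is.null(pm$bait) || all(is.na(pm$bait))))
        pm$bait <- unname(bait[pm$experiments])
    if (is.null(pm$bait)) pm$bait <- rep(NA_character_, length(pm$experiments))
    if (all(is.na(pm$bait)))
        stop("bait metadata is required for this scorer")
    pm
}

# Candidate pair universe of a presence representation: all unordered pairs
# with co-occurrence X >= 1; for spoke-aware scorers additionally every
# bait-prey retrieval pair. Returns a 2-column index matrix (i < j) into
# pm$proteins.
.candidatePairs <- function(pm, spoke = FALSE) {
    sel <- .universeMask(pm, spoke = spoke)
    sel[lower.tri(sel, diag = TRUE)] <- FALSE
    which(sel, arr.ind = TRUE, useNames = FALSE)
}

# Assemble a PairScoreTable by indexing a full score matrix at the
# candidate universe. Proteins are byte-sorted, so (i < j) is already the
# canonical orientation.
.pairTableFromMatrix <- function(S, pm, spoke = FALSE, scorer = "unknown",
                                 params = list(), idx = NULL) {
    if (is.null(idx)) idx <- .candidatePairs(pm, spoke = spoke)
    if (!nrow(idx))
        return(new("PairScoreTable",
                   scores = data.frame(a = character(), b = character(),
                                       score = numeric()),
                   scorer = scorer, params = params))
    new("PairScoreTable",
        scores = data.frame(a = pm$proteins[idx[, 1L]],
                            b = pm$proteins[idx[, 2L]],
                            score = S[idx], stringsAsFactors = FALSE),
        scorer = scorer, params = params)
}

#' Spectral-count-ranking baseline
#'
#' The comparator used throughout the evaluation module: each bait-prey
#' pair observed with a positive count is scored by the sum of that prey's
#' spectral counts over all of the bait's non-control experiments, and
#' pairs are ranked in decreasing order of this sum. Prey rows equal to the
#' bait are skipped; when two purifications pull the pair in both
#' directions the contributions accumulate on the one canonical pair.
#'
#' @param x a [SpectralCountMatrix-class] with bait metadata.
#' @return a [PairScoreTable-class].
#' @export
spectralSumBaseline <- function(x) {
    stopifnot(is(x, "SpectralCountMatrix"))
    if (!hasBaits(x)) stop("bait metadata is required for the baseline")
    cts <- spectralCounts(x)
    bait <- baitOf(x); ctl <- isControl(x)
    keep <- which(!ctl & !is.na(bait))
    pa <- character(); pb <- character(); val <- numeric()
    for (j in keep) {
        pos <- which(cts[, j] > 0)
        pos <- pos[rownames(cts)[pos] != bait[j]]
        if (!length(pos)) next
        pa <- c(pa, rep(bait[j], length(pos)))
        pb <- c(pb, rownames(cts)[pos])
        val <- c(val, cts[pos, j])
    }
    if (!length(pa))
        return(new("PairScoreTable",
                   scores = data.frame(a = character(), b = character(),
                                       score = numeric()),
                   scorer = "spectral_sum_baseline", params = list()))
    key <- pairKeys(pa, pb)
    agg <- tapply(val, key, sum)
    parts <- strsplit(names(agg), "\t", fixed = TRUE)
    new("PairScoreTable",
        scores = data.frame(a = vapply(parts, `[`, character(1), 1L),
                            b = vapply(parts, `[`, character(1), 2L),
                            score = as.numeric(agg),
                            stringsAsFactors = FALSE),
        scorer = "spectral_sum_baseline", params = list())
}

# Full score matrix of one presence representation under a ScorerSpec.
.scoreMatrixFor <- function(pm, spec) {
    name <- spec@name
    if (name %in% c("sai", "pe") && all(is.na(pm$bait)))
        stop("scorer '", name, "' requires bait metadata")
    switch(name,
        hart_poisson = ,
        hart_hypergeometric = {
            stats <- cooccurrenceStats(pm)
            type <- if (name == "hart_poisson") "poisson" else "hypergeometric"
            .hartScoreMatrix(stats, type, tail = spec@params$tail)
        },
        sai = .saiScoreMatrix(pm),
        pe = .peScoreMatrix(pm, r = spec@params$r,
                            n_pseudo = spec@params$n_pseudo),
        cooccurrence_count = {
            X <- tcrossprod(pm$P); diag(X) <- 0; X
        })
}

# Logical membership matrix of the candidate universe of one presence
# representation (pairs with X >= 1, plus bait-prey retrieval pairs for
# spoke-aware scorers).
.universeMask <- function(pm, spoke = FALSE) {
    X <- tcrossprod(pm$P)
    diag(X) <- 0L
    sel <- X >= 1
    if (spoke && any(!is.na(pm$bait))) {
        pr <- .spokeMatrixParts(pm)
        sel <- sel | (pr$nspoke + t(pr$nspoke)) >= 1
    }
    sel
}

# Core dispatch shared by scoreRealization and the ensemble loop: score one
# presence representation with a ScorerSpec over its candidate universe.
.scorePresence <- function(pm, spec) {
    S <- .scoreMatrixFor(pm, spec)
    .pairTableFromMatrix(S, pm, spoke = spec@name %in% c("sai", "pe"),
                         scorer = spec@name, params = spec@params)
}

#' Score one binary realization with a named scorer
#'
#' Dispatches to the scorer named in `spec` over the candidate pair
#' universe of the realization: all pairs that co-purify at least once
#' (plus bait-prey retrieval pairs for the spoke-aware SAI and PE scorers).
#' Deterministic for fixed input.
#'
#' @param realization a [BinaryRealization-class] or 0/1 matrix with
#'   dimnames.
#' @param spec a [ScorerSpec-class] or scorer name.
#' @param bait named character vector experiment -> bait (required for
#'   `sai`, `pe`); see [baitOf()].
#' @param isControl named logical control flags; control columns are
#'   excluded unless `useControls`.
#' @param includeBait include baits in presence sets (default: when bait
#'   metadata exists).
#' @param useControls include control columns (default `FALSE`).
#' @return a [PairScoreTable-class].
#' @examples
#' cells <- matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "e1"))
#' scoreRealization(cells, "hart_poisson")
#' @export
scoreRealization <- function(realization, spec, bait = NULL,
                             isControl = NULL, includeBait = NULL,
                             useControls = FALSE) {
    if (is.character(spec)) spec <- scorerSpec(spec)
    cells <- if (is(realization, "BinaryRealization"))
        realizationCells(realization) else realization
    pm <- .presenceMatrix(cells, bait = bait, isControl = isControl,
                          includeBait = includeBait,
                          useControls = useControls)
    .scorePresence(pm, spec)
}
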