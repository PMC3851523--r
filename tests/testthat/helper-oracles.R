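# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation (loops, direct series
# summation, exhaustive enumeration) kept free of the package's vectorized
# code paths.

# -- fixtures ----------------------------------------------------------------

# A tiny deterministic count matrix with bait metadata.
toyCounts <- function() {
    m <- matrix(c(4L, 1L, 0L,
                  2L, 3L, 1L,
                  0L, 2L, 5L), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("e1", "e2", "e3")))
    SpectralCountMatrix(m, bait = c(e1 = "X", e2 = "Y", e3 = "X"))
}

# Random valid SpectralCountMatrix (counts concentrated at small values).
randomCounts <- function(npreys, nexps, seed, baits = TRUE,
                         maxCount = 6L) {
    set.seed(seed)
    m <- matrix(rbinom(npreys * nexps, maxCount, 0.25), npreys,
                dimnames = list(sprintf("p%02d", seq_len(npreys)),
                                sprintf("e%02d", seq_len(nexps))))
    storage.mode(m) <- "integer"
    b <- if (baits) sprintf("b%02d", sample.int(max(2L, npreys %/% 2L),
                                                nexps, replace = TRUE))
         else NULL
    SpectralCountMatrix(m, bait = b)
}

# Random presence-set list over a small protein alphabet.
randomSets <- function(nProteins, nExps, seed) {
    set.seed(seed)
    prots <- LETTERS[seq_len(nProteins)]
    sets <- lapply(seq_len(nExps), function(i)
        sort(sample(prots, sample.int(nProteins, 1L))))
    names(sets) <- sprintf("e%d", seq_len(nExps))
    sets
}

# -- co-occurrence oracle ----------------------------------------------------

# Naive per-pair co-occurrence statistics by explicit loops over
# experiments; returns list(X = function(a,b), nOf = named, nTotal).
naiveStats <- function(sets) {
    prots <- sort(unique(unlist(sets)))
    nOf <- setNames(numeric(length(prots)), prots)
    nTotal <- 0
    for (s in sets) {
        s <- unique(s)
        k <- length(s)
        nTotal <- nTotal + choose(k, 2)
        for (p in s) nOf[p] <- nOf[p] + (k - 1)
    }
    Xfun <- function(a, b) sum(vapply(sets, function(s)
        a %in% s && b %in% s, logical(1)))
    list(X = Xfun, nOf = nOf, nTotal = nTotal, proteins = prots)
}

# -- tail-probability oracles ------------------------------------------------

# Poisson upper tail P[X > q] (or >= q) by direct series summation of the
# pmf, term by term, avoiding ppois.
poisTailOracle <- function(q, lambda, tail = "gt") {
    if (lambda == 0) return(if (tail == "gt" || q > 0) 0 else 1)
    kmin <- if (tail == "gt") q + 1 else q
    if (kmin <= 0) return(1)
    # sum the upper tail directly, term by term, until terms vanish
    # relative to the accumulated sum (no 1 - lower cancellation)
    total <- 0
    for (k in kmin:(kmin + 500)) {
        term <- exp(-lambda + k * log(lambda) - lfactorial(k))
        total <- total + term
        if (term < total * 1e-17 && k > kmin + 5) break
    }
    total
}

# Hypergeometric upper tail by exhaustive enumeration of the support with
# choose(); population N, m marked, k draws.
hyperTailOracle <- function(X, m, k, N, tail = "gt") {
    lo <- max(0, k - (N - m))
    hi <- min(m, k)
    kmin <- if (tail == "gt") X + 1 else X
    ks <- seq(lo, hi)
    pmf <- choose(m, ks) * choose(N - m, k - ks) / choose(N, k)
    sum(pmf[ks >= kmin])
}

# -- SAI / PE reference implementations --------------------------------------

# Straight-loop socio-affinity index for one pair: two directed spoke
# observed/expected log-ratios (additively smoothed) plus a matrix term.
naiveSai <- function(sets, bait, i, j) {
    exps <- names(sets)
    nE <- length(exps)
    retrieved <- function(p, e) p %in% sets[[e]] && !identical(bait[[e]], p)
    m <- function(p) sum(vapply(exps, function(e) retrieved(p, e), logical(1)))
    nspoke <- function(bi, pj) sum(vapply(exps, function(e)
        identical(bait[[e]], bi) && retrieved(pj, e), logical(1)))
    rbait <- function(p) sum(vapply(exps, function(e)
        identical(bait[[e]], p), logical(1)))
    nmat <- sum(vapply(exps, function(e)
        retrieved(i, e) && retrieved(j, e), logical(1)))
    S <- function(bi, pj)
        log((nspoke(bi, pj) + 1) / (rbait(bi) * m(pj) / nE + 1))
    M <- log((nmat + 1) / (m(i) * m(j) / nE + 1))
    S(i, j) + S(j, i) + M
}

# Straight-loop purification-enrichment score for one pair.
naivePe <- function(sets, bait, i, j, r = 0.3, n_pseudo = 10) {
    exps <- names(sets)
    nE <- length(exps)
    prots <- sort(unique(c(unlist(sets), unname(bait[!is.na(bait)]))))
    retrieved <- function(p, e) p %in% sets[[e]] && !identical(bait[[e]], p)
    m <- setNames(vapply(prots, function(p)
        sum(vapply(exps, function(e) retrieved(p, e), logical(1))),
        numeric(1)), prots)
    f0 <- sum(m) / (nE * length(prots))
    f <- (m + n_pseudo * f0) / (nE + n_pseudo)
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
    spoke <- function(bi, pj) {
        tot <- 0
        for (e in exps) {
            if (!identical(bait[[e]], bi)) next
            tot <- tot + if (retrieved(pj, e)) log(r / f[[pj]])
                         else log((1 - r) / (1 - f[[pj]]))
        }
        tot
    }
    mat <- 0
    for (e in exps) {
        if (identical(bait[[e]], i) || identical(bait[[e]], j)) next
        ri <- retrieved(i, e); rj <- retrieved(j, e)
        if (ri && rj) mat <- mat + log(r / (f[[i]] * f[[j]]))
        else if (ri || rj) mat <- mat + log((1 - r) / (1 - f[[i]] * f[[j]]))
    }
    spoke(i, j) + spoke(j, i) + mat
}

# Look up one pair's score in a PairScoreTable (NA if absent).
pairScoreOf <- function(tab, a, b) {
    df <- scoreTable(tab)
    key <- pairKeys(df$a, df$b)
    hit <- match(pairKeys(a, b), key)
    df$score[hit]
}
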