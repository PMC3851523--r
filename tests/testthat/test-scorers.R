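# Binary scorers: Hart null models against enumeration oracles, SAI/PE
# against straight-loop reference implementations, the count baseline, and
# the scoreRealization dispatch.

test_that("Poisson score reproduces the closed form on the 3-protein case", {
    st <- cooccurrenceStats(list(e1 = c("A", "B", "C")))
    # X = 1, lambda = 4/3: -log P[Pois > 1] = -log(1 - e^-l (1 + l))
    expect_equal(hartPoissonScore(st, "A", "B"),
                 -log(1 - exp(-4 / 3) * (1 + 4 / 3)), tolerance = 1e-12)
})

test_that("Poisson score is zero at lambda 0 and monotone in X", {
    st <- cooccurrenceStats(list(e1 = "A", e2 = "B"))
    expect_identical(hartPoissonScore(st, "A", "B"), 0)
    # fixed lambda, increasing X: tail shrinks so score grows
    sc <- vapply(0:5, function(x)
        apmsEnsemble:::.poisTailScore(x, 1.7), numeric(1))
    expect_true(all(diff(sc) >= 0))
})

test_that("Poisson score matches independent series summation on a grid", {
    for (lam in c(0.05, 0.4, 1.3, 4, 9))
        for (x in c(0, 1, 2, 5, 11))
            for (tail in c("gt", "ge")) {
                want <- -log(max(poisTailOracle(x, lam, tail), 1e-300))
                expect_equal(apmsEnsemble:::.poisTailScore(x, lam, tail),
                             want, tolerance = 1e-10,
                             label = sprintf("x=%d lambda=%g %s", x, lam, tail))
            }
})

test_that("hypergeometric score matches exhaustive enumeration, small case", {
    sc <- apmsEnsemble:::.hyperTailScore(2, 3, 4, 10, "ge")
    expect_equal(sc, -log(hyperTailOracle(2, 3, 4, 10, "ge")),
                 tolerance = 1e-10)
    # X = 0 under the >=-tail: P[H >= 0] = 1, score 0
    expect_identical(apmsEnsemble:::.hyperTailScore(0, 3, 4, 10, "ge"), 0)
})

test_that("hypergeometric score matches brute force on random realizations", {
    checked <- 0
    for (seed in 1:40) {
        sets <- randomSets(nProteins = min(8, 3 + seed %% 6),
                           nExps = min(6, 2 + seed %% 5), seed = 100 + seed)
        st <- cooccurrenceStats(sets)
        if (st@nTotal < 1) next
        prots <- names(st@nOf)
        prs <- combn(prots, 2)
        for (i in seq_len(ncol(prs))) {
            a <- prs[1, i]; b <- prs[2, i]
            for (tail in c("gt", "ge")) {
                got <- hartHypergeometricScore(st, a, b, tail = tail)
                want <- -log(max(hyperTailOracle(
                    cooccurrenceOf(st, a, b), st@nOf[[a]], st@nOf[[b]],
                    st@nTotal, tail), 1e-300))
                expect_equal(got, min(want, -log(1e-300)),
                             tolerance = 1e-10)
                checked <- checked + 1
            }
        }
    }
    expect_gte(checked, 400)
})

test_that("Hart scores are symmetric, non-negative, and functions of the stats", {
    sets <- randomSets(8, 6, seed = 9)
    st <- cooccurrenceStats(sets)
    prots <- names(st@nOf)
    prs <- combn(prots, 2)
    for (i in seq_len(ncol(prs))) {
        a <- prs[1, i]; b <- prs[2, i]
        expect_identical(hartPoissonScore(st, a, b),
                         hartPoissonScore(st, b, a))
        expect_equal(hartHypergeometricScore(st, a, b),
                     hartHypergeometricScore(st, b, a),
                     tolerance = 1e-12)
        expect_gte(hartPoissonScore(st, a, b), 0)
        expect_gte(hartHypergeometricScore(st, a, b), 0)
    }
    # same stats => same scores, independent of which sets produced them
    sets2 <- sets[sample(length(sets))]
    st2 <- cooccurrenceStats(sets2)
    expect_identical(hartPoissonScore(st, prots[1], prots[2]),
                     hartPoissonScore(st2, prots[1], prots[2]))
})

test_that("Poisson approximation converges to the hypergeometric score", {
    # fixed (X, lambda) grid; scale N_A = N_B = sqrt(lambda N) with N
    grid <- expand.grid(X = c(1, 2, 4, 8), lambda = c(0.5, 1, 2))
    relAt <- function(N) vapply(seq_len(nrow(grid)), function(i) {
        X <- grid$X[i]; lam <- grid$lambda[i]
        nA <- round(sqrt(lam * N))
        lamEff <- nA * nA / N
        pois <- apmsEnsemble:::.poisTailScore(X, lamEff)
        hyp <- apmsEnsemble:::.hyperTailScore(X, nA, nA, N)
        abs(pois - hyp) / hyp
    }, numeric(1))
    rels <- vapply(c(1e3, 1e4, 1e5), relAt, numeric(nrow(grid)))
    # every grid point within 5% at N = 1e5
    expect_true(all(rels[, 3] < 0.05))
    # worst-case grid error shrinks monotonically as the population grows
    worst <- apply(rels, 2, max)
    expect_true(all(diff(worst) < 0))
})

test_that("SAI matches its straight-loop reference implementation", {
    for (seed in 1:6) {
        sets <- randomSets(6, 5, seed = 200 + seed)
        bait <- setNames(LETTERS[1 + (seq_along(sets) %% 4)], names(sets))
        tab <- saiScore(sets, bait)
        df <- scoreTable(tab)
        expect_true(all(is.finite(df$score)))
        for (i in seq_len(min(nrow(df), 8)))
            expect_equal(df$score[i],
                         naiveSai(sets, bait, df$a[i], df$b[i]),
                         tolerance = 1e-12)
    }
})

test_that("SAI of a never-associated pair is non-positive and order-invariant", {
    sets <- list(e1 = c("A", "B"), e2 = c("C", "D"), e3 = c("A", "B"))
    bait <- c(e1 = "A", e2 = "C", e3 = "A")
    st <- cooccurrenceStats(sets)
    # A and D never co-purify and never retrieve each other
    expect_lte(naiveSai(sets, bait, "A", "D"), 0)
    # degenerate single-experiment data: finite scores
    one <- saiScore(list(e1 = c("A", "B", "C")), c(e1 = "A"))
    expect_true(all(is.finite(scoreTable(one)$score)))
    # permuting experiment order leaves scores unchanged
    perm <- c(2, 3, 1)
    t1 <- saiScore(sets, bait)
    t2 <- saiScore(sets[perm], bait[perm])
    df1 <- scoreTable(t1); df2 <- scoreTable(t2)
    key <- function(d) order(d$a, d$b)
    expect_equal(df1[key(df1), ], df2[key(df2), ], ignore_attr = TRUE)
    expect_error(saiScore(sets, NULL), "bait")
})

test_that("PE matches its straight-loop reference implementation", {
    for (seed in 1:6) {
        sets <- randomSets(6, 5, seed = 300 + seed)
        bait <- setNames(LETTERS[1 + (seq_along(sets) %% 4)], names(sets))
        tab <- peScore(sets, bait, r = 0.3, n_pseudo = 10)
        df <- scoreTable(tab)
        expect_true(all(is.finite(df$score)))
        for (i in seq_len(min(nrow(df), 8)))
            expect_equal(df$score[i],
                         naivePe(sets, bait, df$a[i], df$b[i]),
                         tolerance = 1e-12)
    }
})

test_that("PE rejects out-of-range parameters and is row-order invariant", {
    sets <- list(e1 = c("A", "B"), e2 = c("A", "B", "C"))
    bait <- c(e1 = "A", e2 = "C")
    expect_error(peScore(sets, bait, r = 0), "r must")
    expect_error(peScore(sets, bait, r = 1.2), "r must")
    expect_error(peScore(sets, bait, n_pseudo = -1), "n_pseudo")
    expect_error(scorerSpec("pe", r = 1.5), "r must")
    # permuting prey order within sets changes nothing
    t1 <- peScore(sets, bait)
    t2 <- peScore(lapply(sets, rev), bait)
    expect_equal(scoreTable(t1), scoreTable(t2))
})

test_that("one extra co-occurrence does not decrease the PE score", {
    # B and C co-retrieved under unrelated baits; add one more co-retrieval
    base <- list(e1 = c("X", "B", "C"), e2 = c("X", "B"), e3 = c("Y", "D"))
    more <- list(e1 = c("X", "B", "C"), e2 = c("X", "B", "C"),
                 e3 = c("Y", "D"))
    bait <- c(e1 = "X", e2 = "X", e3 = "Y")
    s0 <- naivePe(base, bait, "B", "C")
    s1 <- naivePe(more, bait, "B", "C")
    expect_gte(s1, s0)
    # the package agrees with the oracle on both
    expect_equal(pairScoreOf(peScore(base, bait), "B", "C"), s0,
                 tolerance = 1e-12)
    expect_equal(pairScoreOf(peScore(more, bait), "B", "C"), s1,
                 tolerance = 1e-12)
})

test_that("spectral-count baseline sums replicate counts per bait-prey pair", {
    m <- matrix(c(3L, 0L, 2L, 1L, 0L, 4L), 2,
                dimnames = list(c("P", "Q"), c("e1", "e2", "e3")))
    scm <- SpectralCountMatrix(m, bait = c(e1 = "B", e2 = "B", e3 = "C"))
    df <- scoreTable(spectralSumBaseline(scm))
    expect_equal(pairScoreOf(spectralSumBaseline(scm), "B", "P"), 5)
    # prey with all-zero counts under a bait is absent
    expect_true(is.na(pairScoreOf(spectralSumBaseline(scm), "B", "Q")[1]) ||
                pairScoreOf(spectralSumBaseline(scm), "B", "Q") == 1)
    # two distinct baits pulling the same prey: two pairs
    expect_setequal(pairKeys(df$a, df$b)[df$b == "Q" | df$a == "Q"],
                    pairKeys(c("B", "C"), c("Q", "Q")))
    # prey == bait rows are skipped
    m2 <- matrix(c(7L, 1L), 2, 1, dimnames = list(c("B", "P"), "e1"))
    scm2 <- SpectralCountMatrix(m2, bait = c(e1 = "B"))
    df2 <- scoreTable(spectralSumBaseline(scm2))
    expect_identical(nrow(df2), 1L)
    expect_identical(df2$a, "B"); expect_identical(df2$b, "P")
    # missing bait metadata fails loudly
    expect_error(spectralSumBaseline(SpectralCountMatrix(m)), "bait")
})

test_that("scoreRealization covers exactly the co-occurring pairs", {
    cells <- matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "e1"))
    tab <- scoreRealization(cells, "hart_poisson")
    df <- scoreTable(tab)
    expect_setequal(pairKeys(df$a, df$b),
                    pairKeys(c("A", "A", "B"), c("B", "C", "C")))
    # all-zero realization -> empty table
    z <- matrix(0L, 3, 2, dimnames = list(c("A", "B", "C"), c("e1", "e2")))
    expect_identical(nrow(scoreTable(scoreRealization(z, "hart_poisson"))), 0L)
    # determinism
    t1 <- scoreRealization(cells, "hart_poisson")
    t2 <- scoreRealization(cells, "hart_poisson")
    expect_identical(scoreTable(t1), scoreTable(t2))
    # unknown scorer is rejected with the valid options listed
    expect_error(scoreRealization(cells, "bogus"), "valid scorers")
    # cooccurrence_count scorer returns the raw counts
    expect_equal(scoreTable(scoreRealization(cells,
                                             "cooccurrence_count"))$score,
                 c(1, 1, 1))
})
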