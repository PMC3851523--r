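# Count -> probability conversion, Bernoulli realizations, ensemble
# aggregation and its degeneracy/reproducibility contracts.

test_that("count-to-probability formula and its edge cases", {
    expect_identical(countToProbability(0, 0.3), 0)
    expect_equal(countToProbability(1, 0.42), 0.42)
    expect_equal(countToProbability(2, 0.3), 0.51)
    expect_identical(countToProbability(5, 1.0), 1)
    expect_error(countToProbability(1, 0), "0, 1")
    expect_error(countToProbability(1, 1.5), "0, 1")
    expect_error(countToProbability(-1, 0.3), "non-negative")
    # strictly monotone in n for p < 1
    expect_true(all(diff(countToProbability(0:20, 0.3)) > 0))
    # weakly monotone in p, elementwise on a matrix
    scm <- toyCounts()
    p1 <- probabilities(buildProbabilityMatrix(scm, 0.2))
    p2 <- probabilities(buildProbabilityMatrix(scm, 0.6))
    expect_true(all(p2 >= p1))
})

test_that("probability matrix preserves shape and zero pattern", {
    scm <- toyCounts()
    pm <- buildProbabilityMatrix(scm, 0.3)
    expect_identical(dimnames(probabilities(pm)),
                     dimnames(spectralCounts(scm)))
    expect_identical(probabilities(pm) == 0, spectralCounts(scm) == 0)
    expect_equal(probabilities(pm)[["A", "e2"]], 1 - 0.7^2)
    # p = 1 gives the positivity indicator
    expect_identical(probabilities(buildProbabilityMatrix(scm, 1)),
                     (spectralCounts(scm) > 0) + 0)
})

test_that("realizations honour degenerate probabilities and the seed contract", {
    scm <- toyCounts()
    pm <- buildProbabilityMatrix(scm, 0.3)
    r1 <- sampleRealization(pm, seed = 5, trialIndex = 3)
    r2 <- sampleRealization(pm, seed = 5, trialIndex = 3)
    expect_identical(realizationCells(r1), realizationCells(r2))
    r3 <- sampleRealization(pm, seed = 5, trialIndex = 4)
    expect_false(identical(realizationCells(r1), realizationCells(r3)))
    # zero cells never fire; probability-1 cells always fire
    zero <- spectralCounts(scm) == 0
    expect_true(all(realizationCells(r1)[zero] == 0))
    one <- buildProbabilityMatrix(scm, 1)
    expect_identical(realizationCells(sampleRealization(one, 1, 0)),
                     (spectralCounts(scm) > 0) + 0L)
    # sampling does not disturb the caller's RNG stream
    set.seed(99); before <- runif(1)
    set.seed(99); invisible(sampleRealization(pm, 2, 0)); after <- runif(1)
    expect_identical(before, after)
})

test_that("per-cell sampling frequencies match their probabilities", {
    probs <- new("ProbabilityMatrix",
                 probs = matrix(c(0, 0.3, 0.51, 0.9, 1, 0.12), 2, 3,
                                dimnames = list(c("A", "B"),
                                                c("e1", "e2", "e3"))))
    n <- 4000L
    freq <- matrix(0, 2, 3)
    for (t in seq_len(n) - 1L)
        freq <- freq + realizationCells(sampleRealization(probs, 71, t))
    freq <- freq / n
    p <- probabilities(probs)
    # central 99.7% binomial interval around each cell probability
    half <- 3 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(freq - p) <= half + 1e-12))
    expect_identical(freq[1, 1], 0)   # p = 0 cell
    expect_identical(freq[1, 3], 1)   # p = 1 cell
})

test_that("ensemble at p = 1 equals the scorer on the direct binarization", {
    scm <- toyCounts()
    bin <- directBinarization(scm)
    for (name in c("hart_poisson", "hart_hypergeometric", "pe",
                   "cooccurrence_count")) {
        ens <- ensembleScore(scm, ensembleConfig(p = 1, trials = 4,
                                                 seed = 11, scorer = name))
        direct <- scoreRealization(bin, name, bait = baitOf(scm),
                                   isControl = isControl(scm))
        expect_equal(rankedPairs(ens)[c("a", "b", "score")],
                     rankedPairs(direct)[c("a", "b", "score")],
                     label = name)
    }
    # SAI: identical up to the default per-realization clamp at 0
    ensSai <- ensembleScore(scm, ensembleConfig(p = 1, trials = 2,
                                                seed = 3, scorer = "sai"))
    rawSai <- scoreRealization(bin, "sai", bait = baitOf(scm),
                               isControl = isControl(scm))
    expect_equal(scoreTable(ensSai)$score,
                 pmax(scoreTable(rawSai)$score, 0))
    noClamp <- ensembleScore(scm, ensembleConfig(p = 1, trials = 2,
                                                 seed = 3, scorer = "sai",
                                                 clampFloor = NA))
    expect_equal(scoreTable(noClamp)$score, scoreTable(rawSai)$score)
})

test_that("ensemble mean replays the per-trial draw stream exactly", {
    m <- matrix(c(2L, 1L, 0L, 1L, 3L, 2L), 3,
                dimnames = list(c("A", "B", "C"), c("e1", "e2")))
    scm <- SpectralCountMatrix(m)
    cfg <- ensembleConfig(p = 0.3, trials = 2L, seed = 17)
    ens <- ensembleScore(scm, cfg)
    # replay: same realizations scored one at a time, universe fixed from
    # the binarization, absent pairs contributing zero
    probs <- buildProbabilityMatrix(scm, 0.3)
    uni <- scoreTable(scoreRealization(directBinarization(scm),
                                       "hart_poisson"))
    keys <- pairKeys(uni$a, uni$b)
    acc <- setNames(numeric(length(keys)), keys)
    for (t in 0:1) {
        r <- sampleRealization(probs, 17, t)
        tab <- scoreTable(scoreRealization(r, "hart_poisson"))
        if (nrow(tab)) {
            k <- pairKeys(tab$a, tab$b)
            acc[k[k %in% keys]] <- acc[k[k %in% keys]] +
                tab$score[k %in% keys]
        }
    }
    want <- unname(acc / 2)
    got <- scoreTable(ens)
    expect_equal(got$score[match(keys, pairKeys(got$a, got$b))], want)
})

test_that("ensemble scores are reproducible and clamp respects the floor", {
    scm <- toyCounts()
    cfg <- ensembleConfig(p = 0.4, trials = 15, seed = 23, scorer = "sai")
    t1 <- ensembleScore(scm, cfg)
    t2 <- ensembleScore(scm, cfg)
    expect_identical(scoreTable(t1), scoreTable(t2))
    expect_true(all(scoreTable(t1)$score >= 0))
    expect_error(ensembleConfig(trials = 0), "trials")
    expect_error(ensembleConfig(p = 0), "p must")
})

test_that("ensemble standard error scales roughly as 1/sqrt(trials)", {
    scm <- toyCounts()
    spread <- function(trials) {
        reps <- vapply(1:8, function(s) {
            tab <- ensembleScore(scm, ensembleConfig(p = 0.3,
                                                     trials = trials,
                                                     seed = 1000 + s))
            mean(scoreTable(tab)$score)
        }, numeric(1))
        sd(reps)
    }
    s30 <- spread(30); s480 <- spread(480)
    ratio <- s30 / s480           # expected sqrt(480/30) = 4
    expect_gt(ratio, 2)
    expect_lt(ratio, 8)
})

test_that("stability correlation is exactly 1 without stochasticity", {
    scm <- toyCounts()
    expect_identical(ensembleStability(scm,
        ensembleConfig(p = 1, trials = 2, seed = 1), factor = 2), 1)
})
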