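# Synthetic AP-MS generator: planted disjoint complexes pulled down by
# their baits, over a sticky-contaminant background whose positive counts
# concentrate at 1-2. Gives every pipeline stage a ground truth to be
# tested against without external data.

#' Parameters of the synthetic AP-MS generator
#'
#' The default preset emulates two qualitative features of real bait-prey
#' spectral-count matrices: most positive background counts are 1 or 2
#' (contaminant counts are geometric with mean 1/`contaminant_geom_p`),
#' and contaminants hit experiments in proportion to protein-specific
#' stickiness (an approximately rank-one background), while true
#' co-complex preys come down reproducibly with larger counts.
#'
#' @param n_proteins total protein universe size.
#' @param n_complexes number of disjoint planted complexes.
#' @param complex_size members per complex.
#' @param n_experiments number of purification experiments.
#' @param baits_per_complex distinct baits drawn from each complex;
#'   experiments are assigned to baits round-robin, so some baits get
#'   replicate purifications.
#' @param p_detect_true probability a true co-complex partner of the bait
#'   is pulled down in one experiment.
#' @param mu_true mean of the true-interactor count distribution; counts
#'   are drawn as `1 + Poisson(mu_true - 1)` (so `mu_true >= 1`).
#' @param stickiness_dirichlet_alpha Dirichlet concentration of the
#'   protein-specific contaminant propensities (small alpha = a few very
#'   sticky proteins).
#' @param contaminant_rate expected number of contaminant preys per
#'   experiment.
#' @param contaminant_geom_p success parameter of the geometric
#'   (support >= 1) contaminant count distribution; mean count
#'   `1 / contaminant_geom_p`.
#' @param seed integer seed; the whole generation is deterministic given
#'   the parameter set.
#' @return a validated named list of class `apmsSimParams`.
#' @export
syntheticParams <- function(n_proteins = 300L, n_complexes = 40L,
                            complex_size = 5L, n_experiments = 150L,
                            baits_per_complex = 3L, p_detect_true = 0.7,
                            mu_true = 6, stickiness_dirichlet_alpha = 0.5,
                            contaminant_rate = 8, contaminant_geom_p = 0.6,
                            seed = 1L) {
    params <- list(n_proteins = as.integer(n_proteins),
                   n_complexes = as.integer(n_complexes),
                   complex_size = as.integer(complex_size),
                   n_experiments = as.integer(n_experiments),
                   baits_per_complex = as.integer(baits_per_complex),
                   p_detect_true = p_detect_true, mu_true = mu_true,
                   stickiness_dirichlet_alpha = stickiness_dirichlet_alpha,
                   contaminant_rate = contaminant_rate,
                   contaminant_geom_p = contaminant_geom_p,
                   seed = as.integer(seed))
    with(params, {
        if (n_complexes * complex_size > n_proteins)
            stop("complexes do not fit in the protein universe")
        if (baits_per_complex > complex_size)
            stop("baits_per_complex cannot exceed complex_size")
        stopifnot(p_detect_true > 0, p_detect_true <= 1, mu_true >= 1,
                  stickiness_dirichlet_alpha > 0, contaminant_rate >= 0,
                  contaminant_geom_p > 0, contaminant_geom_p <= 1,
                  n_experiments >= 1)
    })
    class(params) <- "apmsSimParams"
    params
}

#' Generate planted ground truth
#'
#' Partitions a seeded random subset of the protein universe into disjoint
#' complexes of the requested size (remaining proteins are background
#' only), marks the first `baits_per_complex` members of each complex as
#' baits, and assigns experiments to baits round-robin.
#'
#' @param params an `apmsSimParams` list from [syntheticParams()].
#' @return list with elements `proteins`, `complex_of` (named integer, NA
#'   for background proteins), `true_pairs` (data.frame `a`, `b`: all
#'   within-complex pairs, canonical), `baits` (character), and
#'   `experiment_baits` (bait per experiment).
#' @export
generateTruth <- function(params) {
    stopifnot(inherits(params, "apmsSimParams"))
    w <- nchar(as.character(params$n_proteins))
    proteins <- paste0("P", .zeroPad(seq_len(params$n_proteins), w))
    member <- .withSeed(params$seed * 3L + 1L,
                        sample(proteins,
                               params$n_complexes * params$complex_size))
    complex_of <- setNames(rep(NA_integer_, params$n_proteins), proteins)
    complex_of[member] <- rep(seq_len(params$n_complexes),
                              each = params$complex_size)
    pa <- character(); pb <- character()
    for (cx in seq_len(params$n_complexes)) {
        mem <- member[(cx - 1L) * params$complex_size +
                      seq_len(params$complex_size)]
        cmb <- utils::combn(mem, 2L)
        pa <- c(pa, cmb[1L, ]); pb <- c(pb, cmb[2L, ])
    }
    true_pairs <- canonicalPairs(pa, pb)
    baits <- unlist(lapply(seq_len(params$n_complexes), function(cx)
        member[(cx - 1L) * params$complex_size +
               seq_len(params$baits_per_complex)]))
    experiment_baits <- rep_len(baits, params$n_experiments)
    list(proteins = proteins, complex_of = complex_of,
         true_pairs = true_pairs, baits = baits,
         experiment_baits = experiment_baits)
}

#' Simulate a spectral-count matrix from a planted truth
#'
#' For each experiment with bait `b`: every co-complex partner of `b` is
#' detected with probability `p_detect_true` and, when detected, receives
#' a count `1 + Poisson(mu_true - 1)`; independently, a
#' `Poisson(contaminant_rate)` number of contaminant preys is drawn
#' without replacement with protein-specific Dirichlet-distributed
#' propensities, each receiving a geometric (support >= 1) count with
#' success `contaminant_geom_p`; contaminant counts add to any true count
#' already in the cell. The bait itself never appears as a prey of its own
#' experiment. Deterministic given `params$seed`.
#'
#' @param truth output of [generateTruth()].
#' @param params the same `apmsSimParams`.
#' @return a [SpectralCountMatrix-class] with bait metadata and replicate
#'   groups (experiments sharing a bait share a group).
#' @export
simulateCounts <- function(truth, params) {
    stopifnot(inherits(params, "apmsSimParams"))
    np <- params$n_proteins; ne <- params$n_experiments
    counts <- matrix(0L, np, ne,
                     dimnames = list(truth$proteins,
                                     paste0("e", .zeroPad(seq_len(ne),
                                                          nchar(as.character(ne))))))
    .withSeed(params$seed * 3L + 2L, {
        stick <- rgamma(np, shape = params$stickiness_dirichlet_alpha)
        stick <- stick / sum(stick)
        for (j in seq_len(ne)) {
            b <- truth$experiment_baits[j]
            cx <- truth$complex_of[b]
            partners <- names(truth$complex_of)[
                !is.na(truth$complex_of) & truth$complex_of == cx]
            partners <- setdiff(partners, b)
            det <- partners[runif(length(partners)) < params$p_detect_true]
            if (length(det))
                counts[det, j] <- 1L + rpois(length(det),
                                             params$mu_true - 1)
            ncont <- rpois(1L, params$contaminant_rate)
            if (ncont > 0) {
                pool <- setdiff(truth$proteins, b)
                wts <- stick[match(pool, truth$proteins)]
                cont <- pool[.weightedSampleNoReplace(wts,
                                                      min(ncont,
                                                          length(pool)))]
                cc <- rgeom(length(cont), params$contaminant_geom_p) + 1L
                counts[cont, j] <- counts[cont, j] + cc
            }
        }
    })
    rg <- truth$experiment_baits
    SpectralCountMatrix(counts, bait = truth$experiment_baits,
                        replicateGroup = paste0("rg_", rg))
}

# Index sample of size k without replacement, probability proportional to
# w at each draw (sequential sampling, as sample() does for prob=).
.weightedSampleNoReplace <- function(w, k) {
    sample.int(length(w), size = k, replace = FALSE, prob = w)
}

#' Synthetic truth as a single-source gold standard
#'
#' Every planted within-complex pair gets support 1, so [evaluateTopK()]
#' can run on synthetic data unchanged.
#'
#' @param truth output of [generateTruth()].
#' @return a [GoldStandard-class].
#' @export
labelsAsGold <- function(truth) {
    tp <- truth$true_pairs
    if (!nrow(tp)) return(GoldStandard())
    GoldStandard(a = tp$a, b = tp$b, support = rep(1L, nrow(tp)))
}

#' One-call synthetic scenario
#'
#' @param params an `apmsSimParams` (default [syntheticParams()]).
#' @return list with `truth`, `counts` (a [SpectralCountMatrix-class]) and
#'   `gold` (a [GoldStandard-class]).
#' @examples
#' sim <- simulateApms(syntheticParams(n_proteins = 30, n_complexes = 4,
#'                                     n_experiments = 20, seed = 3))
#' sim$counts
#' @export
simulateApms <- function(params = syntheticParams()) {
    truth <- generateTruth(params)
    list(truth = truth, counts = simulateCounts(truth, params),
         gold = labelsAsGold(truth))
}
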