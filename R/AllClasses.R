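#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats ppois phyper runif rpois rgeom rgamma cor setNames
#' @importFrom utils head read.delim write.table
NULL

.SCORER_NAMES <- c("hart_poisson", "hart_hypergeometric", "sai", "pe",
                   "cooccurrence_count")

.TAIL_FLOOR <- 1e-300  # tail probabilities floored before -log

#' SpectralCountMatrix: prey x experiment spectral counts
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"counts"` assay of non-negative integer spectral counts, with rows
#' indexed by prey protein identifiers and columns by purification-experiment
#' identifiers. Per-experiment metadata lives in `colData`: `bait` (the tagged
#' protein driving each purification, `NA` when unknown), `replicate_group`
#' and `is_control`.
#'
#' Identifiers are opaque case-sensitive strings compared exactly; zero is a
#' stored count, not a missing value.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [SpectralCountMatrix()] (constructor), [readCountMatrix()],
#'   [spectralCounts()], [baitOf()], [isControl()]
#' @export
setClass("SpectralCountMatrix", contains = "SummarizedExperiment")

.validSpectralCountMatrix <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (length(cts) && (anyNA(cts) || any(!is.finite(cts))))
            msg <- c(msg, "counts must be finite and non-missing")
        else if (length(cts) && any(cts < 0))
            msg <- c(msg, "counts must be non-negative")
        else if (length(cts) && any(cts != round(cts)))
            msg <- c(msg, "counts must be integral")
    }
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) && nrow(object) > 0) msg <- c(msg, "prey ids (rownames) required")
    if (is.null(cn) && ncol(object) > 0) msg <- c(msg, "experiment ids (colnames) required")
    if (anyDuplicated(rn)) msg <- c(msg, "duplicate prey identifiers")
    if (anyDuplicated(cn)) msg <- c(msg, "duplicate experiment identifiers")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("bait", "replicate_group", "is_control"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("is_control" %in% colnames(cd) && ncol(object) &&
        (!is.logical(cd$is_control) || anyNA(cd$is_control)))
        msg <- c(msg, "is_control must be logical and non-missing")
    if (length(msg)) msg else TRUE
}
setValidity("SpectralCountMatrix", .validSpectralCountMatrix)

#' Construct a SpectralCountMatrix
#'
#' @param counts integer matrix of spectral counts with unique `rownames`
#'   (prey ids) and `colnames` (experiment ids).
#' @param bait optional character vector (or named map experiment -> protein)
#'   giving the bait of each experiment; `NA` where unknown.
#' @param replicateGroup optional character vector of replicate-group labels;
#'   defaults to the experiment id (every column its own group).
#' @param isControl optional logical vector flagging control purifications;
#'   defaults to `FALSE`.
#' @return a validated [SpectralCountMatrix-class] object.
#' @examples
#' m <- matrix(c(0L, 3L, 1L, 0L), 2, dimnames = list(c("P1","P2"), c("e1","e2")))
#' scm <- SpectralCountMatrix(m, bait = c(e1 = "B1", e2 = "B2"))
#' spectralCounts(scm)
#' @export
SpectralCountMatrix <- function(counts, bait = NULL, replicateGroup = NULL,
                                isControl = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    ne <- ncol(counts)
    cn <- colnames(counts)
    expand <- function(x, default, what) {
        if (is.null(x)) return(rep(default, ne))
        if (!is.null(names(x))) {
            unknown <- setdiff(names(x), cn)
            if (length(unknown))
                stop("metadata references unknown experiment(s): ",
                     paste(unknown, collapse = ", "))
            out <- rep(default, ne)
            names(out) <- cn
            out[names(x)] <- x
            return(unname(out))
        }
        if (length(x) != ne)
            stop(what, " must have one entry per experiment")
        x
    }
    bait <- expand(bait, NA_character_, "bait")
    rg <- expand(replicateGroup, NA_character_, "replicateGroup")
    if (all(is.na(rg))) rg <- if (is.null(cn)) character(ne) else cn
    ctl <- as.logical(expand(isControl, FALSE, "isControl"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(bait = as.character(bait),
                                       replicate_group = as.character(rg),
                                       is_control = ctl,
                                       row.names = cn))
    new("SpectralCountMatrix", se)
}

#' PairScoreTable: confidence scores on unordered protein pairs
#'
#' Holds one finite real score per canonical (lexicographically ordered,
#' non-self) protein pair, together with the name and parameters of the
#' scorer that produced it.
#'
#' @slot scores data.frame with columns `a`, `b`, `score` (one row per pair,
#'   `a < b` bytewise, no duplicates, all scores finite).
#' @slot scorer character scorer name.
#' @slot params list of scorer parameters.
#' @seealso [PairScoreTable()], [rankedPairs()], [writeRankedPairs()]
#' @export
setClass("PairScoreTable",
         representation(scores = "data.frame", scorer = "character",
                        params = "list"))

setValidity("PairScoreTable", function(object) {
    df <- object@scores
    if (!all(c("a", "b", "score") %in% colnames(df)))
        return("scores needs columns a, b, score")
    if (nrow(df)) {
        if (any(!is.finite(df$score))) return("all scores must be finite")
        if (any(df$a >= df$b)) return("pairs must be canonical (a < b, a != b)")
        if (anyDuplicated(paste0(df$a, "\r", df$b)))
            return("each pair may appear at most once")
    }
    TRUE
})

#' @rdname PairScoreTable-class
#' @param a,b character vectors of protein ids (any orientation; canonicalized).
#' @param score numeric vector of finite scores.
#' @param scorer scorer name recorded as metadata.
#' @param params parameter record list.
#' @return a `PairScoreTable`.
#' @export
PairScoreTable <- function(a = character(), b = character(),
                           score = numeric(), scorer = "unknown",
                           params = list()) {
    cp <- canonicalPairs(a, b)
    df <- data.frame(a = cp$a, b = cp$b, score = as.numeric(score),
                     stringsAsFactors = FALSE)
    new("PairScoreTable", scores = df, scorer = scorer, params = params)
}

#' GoldStandard: reference interactions with evidence-source support
#'
#' Maps canonical protein pairs to the number of distinct curated sources
#' supporting them, enabling validation subsets at increasingly stringent
#' support thresholds (the subsets are nested by construction).
#'
#' @slot support data.frame with columns `a`, `b`, `support` (integer >= 1).
#' @seealso [readGoldStandard()], [goldSubset()]
#' @export
setClass("GoldStandard", representation(support = "data.frame"))

setValidity("GoldStandard", function(object) {
    df <- object@support
    if (!all(c("a", "b", "support") %in% colnames(df)))
        return("support needs columns a, b, support")
    if (nrow(df)) {
        if (any(df$support < 1) || any(df$support != round(df$support)))
            return("support values must be positive integers")
        if (any(df$a >= df$b)) return("pairs must be canonical")
        if (anyDuplicated(paste0(df$a, "\r", df$b)))
            return("each pair may appear at most once")
    }
    TRUE
})

#' @rdname GoldStandard-class
#' @param a,b character vectors of protein ids (canonicalized on input).
#' @param support integer vector of source counts (>= 1).
#' @return a `GoldStandard`.
#' @export
GoldStandard <- function(a = character(), b = character(),
                         support = integer()) {
    cp <- canonicalPairs(a, b)
    new("GoldStandard",
        support = data.frame(a = cp$a, b = cp$b,
                             support = as.integer(support),
                             stringsAsFactors = FALSE))
}

#' ProbabilityMatrix: per-cell true-observation probabilities
#'
#' Same shape and dimnames as the source count matrix; each cell holds the
#' probability `1 - (1 - p)^n` that the observation is real. Cells are zero
#' exactly where the source count is zero.
#'
#' @slot probs numeric matrix in \[0, 1\].
#' @seealso [buildProbabilityMatrix()]
#' @export
setClass("ProbabilityMatrix", representation(probs = "matrix"))

setValidity("ProbabilityMatrix", function(object) {
    p <- object@probs
    if (length(p) && (anyNA(p) || any(p < 0) || any(p > 1)))
        return("probabilities must lie in [0, 1]")
    TRUE
})

#' BinaryRealization: one sampled 0/1 matrix from the ensemble
#'
#' @slot cells 0/1 integer matrix, same shape/dimnames as the source counts;
#'   zero wherever the source count is zero.
#' @slot trialIndex non-negative integer index of the trial within the
#'   ensemble.
#' @seealso [sampleRealization()]
#' @export
setClass("BinaryRealization",
         representation(cells = "matrix", trialIndex = "integer"))

setValidity("BinaryRealization", function(object) {
    x <- object@cells
    if (length(x) && !all(x %in% c(0L, 1L))) return("cells must be 0/1")
    if (length(object@trialIndex) != 1L || is.na(object@trialIndex) ||
        object@trialIndex < 0L)
        return("trialIndex must be a single non-negative integer")
    TRUE
})

#' CooccurrenceStats: sufficient statistics of the co-purification null model
#'
#' For a set of per-experiment protein presence sets, stores the pairwise
#' co-purification counts `X[A,B]` (number of experiments in which A and B
#' appear together), the per-protein co-purifying-pair incidences
#' `nOf[A] = sum over experiments containing A of (s_e - 1)`, and the total
#' number of co-purifying pairs `nTotal = sum over experiments of
#' choose(s_e, 2)`, where `s_e` is the number of proteins present in
#' experiment `e`. The null expectation for any observed pair is
#' `lambda(A,B) = nOf[A] * nOf[B] / nTotal` (0 when `nTotal` is 0), the
#' rank-one factorization underlying the Hart-style null-model scores.
#'
#' @slot X symmetric integer matrix of co-purification counts over observed
#'   proteins (diagonal unused).
#' @slot nOf named numeric vector of per-protein pair incidences.
#' @slot nTotal total co-purifying pairs.
#' @seealso [cooccurrenceStats()], [lambdaOf()]
#' @export
setClass("CooccurrenceStats",
         representation(X = "matrix", nOf = "numeric", nTotal = "numeric"))

setValidity("CooccurrenceStats", function(object) {
    if (nrow(object@X) != ncol(object@X)) return("X must be square")
    if (length(object@nOf) != nrow(object@X))
        return("nOf must match X dimension")
    if (object@nTotal < 0) return("nTotal must be non-negative")
    TRUE
})

#' ScorerSpec: a named binary scorer plus its parameters
#'
#' @slot name one of `"hart_poisson"`, `"hart_hypergeometric"`, `"sai"`,
#'   `"pe"`, `"cooccurrence_count"`.
#' @slot params list; for `"pe"`: `r` in (0,1) (probability of detecting a
#'   true association in a purification) and `n_pseudo >= 0` (pseudocounts
#'   added for each prey); for the Hart scorers: `tail` = `"gt"` (default,
#'   the strictly-greater-than tail as in `-log(1 - CDF(X))`) or `"ge"`.
#' @seealso [scorerSpec()], [scoreRealization()]
#' @export
setClass("ScorerSpec", representation(name = "character", params = "list"))

#' Create a scorer specification
#'
#' @param name scorer name; one of `hart_poisson`, `hart_hypergeometric`,
#'   `sai`, `pe`, `cooccurrence_count`.
#' @param ... parameter overrides (PE: `r`, `n_pseudo`; Hart: `tail`).
#' @return a validated [ScorerSpec-class].
#' @examples
#' scorerSpec("pe", r = 0.3, n_pseudo = 10)
#' @export
scorerSpec <- function(name, ...) {
    name <- as.character(name)[1]
    if (!name %in% .SCORER_NAMES)
        stop("unknown scorer '", name, "'; valid scorers: ",
             paste(.SCORER_NAMES, collapse = ", "))
    params <- list(...)
    defaults <- switch(name,
        pe = list(r = 0.3, n_pseudo = 10),
        hart_poisson = list(tail = "gt"),
        hart_hypergeometric = list(tail = "gt"),
        list())
    for (nm in names(defaults))
        if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
    if (name == "pe") {
        if (!is.numeric(params$r) || params$r <= 0 || params$r >= 1)
            stop("pe: r must lie strictly in (0, 1)")
        if (!is.numeric(params$n_pseudo) || params$n_pseudo < 0)
            stop("pe: n_pseudo must be >= 0")
    }
    if (name %in% c("hart_poisson", "hart_hypergeometric") &&
        !params$tail %in% c("gt", "ge"))
        stop("tail must be 'gt' or 'ge'")
    new("ScorerSpec", name = name, params = params)
}

#' EnsembleConfig: parameters of the sampling ensemble
#'
#' @slot p per-count reliability in (0, 1]: the probability that a single
#'   spectral count is the result of a true observation (default 0.3).
#' @slot trials positive ensemble size (default 120).
#' @slot seed integer base seed.
#' @slot scorer a [ScorerSpec-class].
#' @slot clampFloor numeric(1) lower bound applied to each per-realization
#'   score before averaging, or `NA` for none. Defaults to 0 for the SAI
#'   scorer (whose raw scores can be unboundedly negative) and none otherwise.
#' @seealso [ensembleConfig()], [ensembleScore()]
#' @export
setClass("EnsembleConfig",
         representation(p = "numeric", trials = "integer", seed = "integer",
                        scorer = "ScorerSpec", clampFloor = "numeric"))

setValidity("EnsembleConfig", function(object) {
    if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
    if (object@trials < 1L) return("trials must be >= 1")
    TRUE
})

#' Create an ensemble configuration
#'
#' @param p reliability of a single spectral count, in (0, 1].
#' @param trials ensemble size.
#' @param seed base seed for the per-trial draw streams.
#' @param scorer a [ScorerSpec-class] or scorer name.
#' @param clampFloor per-realization score floor; `NULL` selects the default
#'   (0 for `"sai"`, none otherwise), `NA` forces none.
#' @return an [EnsembleConfig-class].
#' @export
ensembleConfig <- function(p = 0.3, trials = 120L, seed = 1L,
                           scorer = scorerSpec("hart_poisson"),
                           clampFloor = NULL) {
    if (is.character(scorer)) scorer <- scorerSpec(scorer)
    if (is.null(clampFloor))
        clampFloor <- if (scorer@name == "sai") 0 else NA_real_
    new("EnsembleConfig", p = as.numeric(p), trials = as.integer(trials),
        seed = as.integer(seed), scorer = scorer,
        clampFloor = as.numeric(clampFloor))
}

setMethod("show", "SpectralCountMatrix", function(object) {
    cat(sprintf("SpectralCountMatrix: %d preys x %d experiments\n",
                nrow(object), ncol(object)))
    nb <- sum(!is.na(SummarizedExperiment::colData(object)$bait))
    nc <- sum(SummarizedExperiment::colData(object)$is_control)
    cat(sprintf("  baits known for %d experiment(s); %d control column(s)\n",
                nb, nc))
    cts <- SummarizedExperiment::assay(object, "counts")
    if (length(cts))
        cat(sprintf("  %d positive cells; max count %d\n",
                    sum(cts > 0), max(cts)))
})

setMethod("show", "PairScoreTable", function(object) {
    cat(sprintf("PairScoreTable: %d pair(s), scorer '%s'\n",
                nrow(object@scores), object@scorer))
    if (nrow(object@scores)) {
        top <- head(rankedPairs(object), 3L)
        cat("  top pairs:\n")
        for (i in seq_len(nrow(top)))
            cat(sprintf("    %s -- %s  %.4g\n",
                        top$a[i], top$b[i], top$score[i]))
    }
})

setMethod("show", "GoldStandard", function(object) {
    df <- object@support
    cat(sprintf("GoldStandard: %d pair(s), max support %s\n", nrow(df),
                if (nrow(df)) max(df$support) else "0"))
})

setMethod("show", "ScorerSpec", function(object) {
    ps <- if (length(object@params))
        paste(names(object@params),
              vapply(object@params, function(x) paste(format(x), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", ") else "none"
    cat(sprintf("ScorerSpec '%s' (params: %s)\n", object@name, ps))
})

setMethod("show", "EnsembleConfig", function(object) {
    cat(sprintf("EnsembleConfig: p=%g, trials=%d, seed=%d, scorer=%s, clamp=%s\n",
                object@p, object@trials, object@seed, object@scorer@name,
                if (is.na(object@clampFloor)) "none"
                else format(object@clampFloor)))
})
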