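#' Extract the spectral-count assay
#' @param x a [SpectralCountMatrix-class].
#' @return integer matrix of counts.
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname spectralCounts
#' @export
setMethod("spectralCounts", "SpectralCountMatrix", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Per-experiment bait proteins
#' @param x a [SpectralCountMatrix-class].
#' @return named character vector (experiment -> bait id, `NA` if unknown).
#' @export
setGeneric("baitOf", function(x) standardGeneric("baitOf"))

#' @rdname baitOf
#' @export
setMethod("baitOf", "SpectralCountMatrix", function(x)
    setNames(SummarizedExperiment::colData(x)$bait, colnames(x)))

#' Control flags of the experiments
#' @param x a [SpectralCountMatrix-class].
#' @return named logical vector.
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname isControl
#' @export
setMethod("isControl", "SpectralCountMatrix", function(x)
    setNames(SummarizedExperiment::colData(x)$is_control, colnames(x)))

#' Replicate-group labels of the experiments
#' @param x a [SpectralCountMatrix-class].
#' @return named character vector.
#' @export
setGeneric("replicateGroup", function(x) standardGeneric("replicateGroup"))

#' @rdname replicateGroup
#' @export
setMethod("replicateGroup", "SpectralCountMatrix", function(x)
    setNames(SummarizedExperiment::colData(x)$replicate_group, colnames(x)))

#' Prey / experiment identifiers
#' @param x a [SpectralCountMatrix-class].
#' @return character vector of identifiers.
#' @export
preyIds <- function(x) rownames(x)

#' @rdname preyIds
#' @export
experimentIds <- function(x) colnames(x)

#' Whether bait metadata is available
#' @param x a [SpectralCountMatrix-class].
#' @return `TRUE` if at least one experiment has a known bait.
#' @export
hasBaits <- function(x) any(!is.na(baitOf(x)))

#' Score table of a PairScoreTable
#' @param x a [PairScoreTable-class].
#' @return data.frame with columns `a`, `b`, `score`.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "PairScoreTable", function(x) x@scores)

#' Ranked view of a PairScoreTable
#'
#' Pairs sorted by descending score, ties broken by `(a, b)` lexicographic
#' ascending order (bytewise, locale-independent), with a `rank` column.
#'
#' @param x a [PairScoreTable-class].
#' @return data.frame with columns `a`, `b`, `score`, `rank`.
#' @export
setGeneric("rankedPairs", function(x) standardGeneric("rankedPairs"))

#' @rdname rankedPairs
#' @export
setMethod("rankedPairs", "PairScoreTable", function(x) {
    df <- x@scores
    ord <- order(-df$score, .byteRank(df$a), .byteRank(df$b))
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
})

#' Support table of a GoldStandard
#' @param x a [GoldStandard-class].
#' @return data.frame with columns `a`, `b`, `support`.
#' @export
setGeneric("goldSupport", function(x) standardGeneric("goldSupport"))

#' @rdname goldSupport
#' @export
setMethod("goldSupport", "GoldStandard", function(x) x@support)

#' Gold-standard subset at a support threshold
#'
#' Pairs supported by at least `k` distinct evidence sources. Subsets at
#' larger `k` are nested inside subsets at smaller `k`.
#'
#' @param gold a [GoldStandard-class].
#' @param k minimum number of supporting sources.
#' @return character vector of pair keys (see [pairKeys()]).
#' @export
goldSubset <- function(gold, k) {
    df <- goldSupport(gold)
    keep <- df$support >= k
    pairKeys(df$a[keep], df$b[keep])
}

#' Realization cells / trial index accessors
#' @param x a [BinaryRealization-class].
#' @return 0/1 integer matrix, or the trial index.
#' @export
realizationCells <- function(x) x@cells

#' @rdname realizationCells
#' @export
trialIndex <- function(x) x@trialIndex

#' Probability matrix accessor
#' @param x a [ProbabilityMatrix-class].
#' @return numeric matrix of per-cell probabilities.
#' @export
probabilities <- function(x) x@probs
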