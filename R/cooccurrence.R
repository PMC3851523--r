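# Co-purification bookkeeping shared by all binary scorers.
#
# The internal currency is a presence matrix: proteins x experiments 0/1,
# where a protein is "present" in an experiment if it has a 1 in the
# realization (as prey) or is the experiment's bait. Public presenceSets()
# exposes the same information as per-experiment protein sets.

# Build the internal presence representation from a 0/1 cell matrix plus
# experiment metadata. Returns list(P = presence matrix, bait = bait vector
# aligned to kept experiments, proteins, experiments).
.presenceMatrix <- function(cells, bait = NULL, isControl = NULL,
                            includeBait = NULL, useControls = FALSE) {
    expIds <- colnames(cells)
    if (is.null(isControl)) isControl <- setNames(rep(FALSE, ncol(cells)), expIds)
    keep <- if (useControls) rep(TRUE, ncol(cells)) else !isControl[expIds]
    cells <- cells[, keep, drop = FALSE]
    expIds <- colnames(cells)
    haveBaits <- !is.null(bait) && any(!is.na(bait[expIds]))
    if (is.null(includeBait)) includeBait <- haveBaits
    if (includeBait && !haveBaits)
        stop("includeBait requested but no bait metadata is available")
    baits <- if (!is.null(bait)) unname(bait[expIds]) else rep(NA_character_, length(expIds))
    proteins <- rownames(cells)
    if (includeBait)
        proteins <- union(proteins, baits[!is.na(baits)])
    proteins <- .C_sort(proteins)
    P <- matrix(0L, nrow = length(proteins), ncol = length(expIds),
                dimnames = list(proteins, expIds))
    if (nrow(cells))
        P[rownames(cells), ] <- (cells > 0) + 0L
    if (includeBait) {
        hasB <- which(!is.na(baits))
        P[cbind(match(baits[hasB], proteins), hasB)] <- 1L
    }
    list(P = P, bait = baits, proteins = proteins, experiments = expIds,
         includeBait = includeBait)
}

#' Per-experiment protein presence sets
#'
#' Maps each (non-control, unless `useControls`) experiment to the set of
#' proteins present in it: preys with a 1 in the realization column, plus
#' the experiment's bait when bait metadata exists and `includeBait` is
#' `TRUE` (set semantics: a bait that also appears as a prey row is not
#' double-counted). These sets are the input to the co-occurrence null
#' model.
#'
#' @param realization a [BinaryRealization-class] (or 0/1 matrix with
#'   dimnames).
#' @param bait named character vector experiment -> bait, as from
#'   [baitOf()]; `NULL` if unknown.
#' @param isControl named logical vector as from [isControl()].
#' @param includeBait logical; default (`NULL`) includes baits exactly when
#'   bait metadata exists. Explicit `TRUE` without metadata is an error.
#' @param useControls keep control columns (default `FALSE`: controls are
#'   excluded from all scorers in this package).
#' @return named list of character vectors (sorted), one per experiment.
#' @export
presenceSets <- function(realization, bait = NULL, isControl = NULL,
                         includeBait = NULL, useControls = FALSE) {
    cells <- if (is(realization, "BinaryRealization"))
        realizationCells(realization) else realization
    pm <- .presenceMatrix(cells, bait = bait, isControl = isControl,
                          includeBait = includeBait,
                          useControls = useControls)
    sets <- lapply(seq_along(pm$experiments), function(j)
        pm$proteins[pm$P[, j] == 1L])
    names(sets) <- pm$experiments
    sets
}

#' Co-occurrence statistics of presence sets
#'
#' Computes the sufficient statistics of the co-purification null model
#' (see [CooccurrenceStats-class]): pair co-purification counts `X`,
#' per-protein pair incidences `nOf` and the total co-purifying pair count
#' `nTotal`. Empty input yields all-zero statistics.
#'
#' @param sets a list of per-experiment protein sets (from
#'   [presenceSets()]), or the internal presence-matrix representation.
#' @return a [CooccurrenceStats-class].
#' @examples
#' st <- cooccurrenceStats(list(e1 = c("A", "B", "C")))
#' lambdaOf(st, "A", "B")  # 2*2/3
#' @export
cooccurrenceStats <- function(sets) {
    if (is.list(sets) && !is.null(sets$P)) {
        P <- sets$P
    } else {
        proteins <- .C_sort(unique(unlist(sets, use.names = FALSE)))
        P <- matrix(0L, length(proteins), length(sets),
                    dimnames = list(proteins, names(sets)))
        for (j in seq_along(sets))
            P[match(unique(sets[[j]]), proteins), j] <- 1L
    }
    s <- colSums(P)
    X <- tcrossprod(P)            # X[A,B] = experiments containing both
    diag(X) <- 0L
    nOf <- as.numeric(P %*% (s - 1))
    names(nOf) <- rownames(P)
    nTotal <- sum(s * (s - 1) / 2)
    new("CooccurrenceStats", X = X, nOf = nOf, nTotal = nTotal)
}

#' Null expectation lambda for a protein pair
#'
#' `lambda(A, B) = nOf[A] * nOf[B] / nTotal` (0 when `nTotal` is 0).
#' Computable on demand for any pair of observed proteins, whether or not
#' they ever co-purified.
#'
#' @param stats a [CooccurrenceStats-class].
#' @param a,b protein identifiers (must be observed proteins).
#' @return numeric null expectation.
#' @export
lambdaOf <- function(stats, a, b) {
    if (stats@nTotal == 0) return(rep(0, length(a)))
    miss <- setdiff(c(a, b), names(stats@nOf))
    if (length(miss))
        stop("unknown protein(s): ", paste(miss, collapse = ", "))
    unname(stats@nOf[a] * stats@nOf[b] / stats@nTotal)
}

#' Observed co-purification count for a pair
#' @param stats a [CooccurrenceStats-class].
#' @param a,b protein identifiers; unobserved proteins have count 0.
#' @return integer vector of co-purification counts `X`.
#' @export
cooccurrenceOf <- function(stats, a, b) {
    ia <- match(a, rownames(stats@X)); ib <- match(b, rownames(stats@X))
    out <- numeric(length(ia))
    ok <- !is.na(ia) & !is.na(ib)
    out[ok] <- stats@X[cbind(ia[ok], ib[ok])]
    out
}
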