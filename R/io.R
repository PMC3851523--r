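# Readers and writers for the package's plain-text exchange formats.
# All files are TSV, UTF-8, LF line endings; writers emit deterministic
# bytes (stored order, fixed numeric formatting) so reruns are comparable
# with diff.

.fmtScore <- function(x) sprintf("%.12g", x)

.writeLines <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Read a spectral-count matrix from TSV
#'
#' The file's first row holds experiment identifiers (first cell is a corner
#' label and is ignored), the first column prey identifiers, and the body
#' non-negative integer spectral counts. Zero is a stored value, not a
#' missing-data token: every cell must be present. An optional metadata
#' table maps experiments to baits, replicate groups and control flags.
#'
#' @param path count-matrix TSV path.
#' @param metadataPath optional experiment-metadata TSV with columns
#'   `experiment_id`, `bait_id`, `replicate_group`, `is_control` (0/1).
#'   When absent, baits are unknown and no column is a control; scorers that
#'   need baits then fail loudly rather than guess.
#' @return a validated [SpectralCountMatrix-class].
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, metadataPath = NULL) {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty count-matrix file: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    expIds <- header[-1L]
    if (anyDuplicated(expIds))
        stop("duplicate experiment identifier(s): ",
             paste(unique(expIds[duplicated(expIds)]), collapse = ", "))
    body <- lines[-1L]
    body <- body[nzchar(body)]
    preyIds <- character(length(body))
    counts <- matrix(0L, nrow = length(body), ncol = length(expIds))
    for (i in seq_along(body)) {
        fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != length(expIds) + 1L)
            stop(sprintf("line %d: expected %d cells, found %d (missing cells are an error, not zero)",
                         i + 1L, length(expIds) + 1L, length(fields) - 1L))
        preyIds[i] <- fields[1L]
        vals <- fields[-1L]
        bad <- !grepl("^[0-9]+$", vals)
        if (any(bad)) {
            j <- which(bad)[1L]
            stop(sprintf("invalid count '%s' at row '%s', column '%s'",
                         vals[j], fields[1L], expIds[j]))
        }
        counts[i, ] <- as.integer(vals)
    }
    if (anyDuplicated(preyIds))
        stop("duplicate prey identifier(s): ",
             paste(unique(preyIds[duplicated(preyIds)]), collapse = ", "))
    dimnames(counts) <- list(preyIds, expIds)
    bait <- NULL; rg <- NULL; ctl <- NULL
    if (!is.null(metadataPath)) {
        md <- read.delim(metadataPath, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
        need <- c("experiment_id", "bait_id", "replicate_group", "is_control")
        missing <- setdiff(need, colnames(md))
        if (length(missing))
            stop("metadata is missing column(s): ",
                 paste(missing, collapse = ", "))
        unknown <- setdiff(md$experiment_id, expIds)
        if (length(unknown))
            stop("metadata references unknown experiment(s): ",
                 paste(unknown, collapse = ", "))
        bait <- setNames(md$bait_id, md$experiment_id)
        bait[!nzchar(bait)] <- NA_character_
        rg <- setNames(md$replicate_group, md$experiment_id)
        ctl <- setNames(md$is_control %in% c("1", "TRUE", "true"),
                        md$experiment_id)
    }
    SpectralCountMatrix(counts, bait = bait, replicateGroup = rg,
                        isControl = ctl)
}

#' Write a spectral-count matrix to TSV
#'
#' Deterministic byte output: rows and columns in stored order,
#' tab-separated, LF endings. `readCountMatrix(writeCountMatrix(x))`
#' returns an identical matrix.
#'
#' @param x a [SpectralCountMatrix-class].
#' @param path output path.
#' @param metadataPath optional path for the experiment-metadata sidecar.
#' @return invisibly, `path`.
#' @export
writeCountMatrix <- function(x, path, metadataPath = NULL) {
    stopifnot(is(x, "SpectralCountMatrix"))
    cts <- spectralCounts(x)
    lines <- c(paste(c("prey_id", colnames(cts)), collapse = "\t"),
               vapply(seq_len(nrow(cts)), function(i)
                   paste(c(rownames(cts)[i], cts[i, ]), collapse = "\t"),
                   character(1)))
    .writeLines(lines, path)
    if (!is.null(metadataPath)) {
        bait <- baitOf(x)
        bait[is.na(bait)] <- ""
        md <- c("experiment_id\tbait_id\treplicate_group\tis_control",
                paste(colnames(cts), bait, replicateGroup(x),
                      as.integer(isControl(x)), sep = "\t"))
        .writeLines(md, metadataPath)
    }
    invisible(path)
}

#' Read gold-standard interaction lists
#'
#' Each file is a tab-separated edge list: two columns of protein
#' identifiers (the whole file is one evidence source), or three columns
#' whose third field is a source label (a pre-merged multi-source file).
#' Pairs are canonicalized so orientation does not matter; duplicate rows
#' within one source count once; self-pairs are dropped with a warning.
#' The support of a pair is the number of distinct sources containing it.
#'
#' @param paths character vector of file paths.
#' @return a [GoldStandard-class].
#' @export
readGoldStandard <- function(paths) {
    src <- character(); pa <- character(); pb <- character()
    for (f in seq_along(paths)) {
        lines <- readLines(paths[[f]], encoding = "UTF-8")
        lines <- lines[nzchar(lines)]
        for (i in seq_along(lines)) {
            fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
            if (!length(fields) %in% c(2L, 3L) || any(!nzchar(fields)))
                stop(sprintf("%s line %d: expected 2 or 3 tab-separated fields",
                             paths[[f]], i))
            if (fields[1L] == fields[2L]) {
                warning(sprintf("%s line %d: self-pair (%s) dropped",
                                paths[[f]], i, fields[1L]))
                next
            }
            pa <- c(pa, fields[1L]); pb <- c(pb, fields[2L])
            src <- c(src, if (length(fields) == 3L)
                paste0("label:", fields[3L]) else paste0("file:", f))
        }
    }
    if (!length(pa)) return(GoldStandard())
    key <- pairKeys(pa, pb)
    uniq <- !duplicated(paste0(src, "\r", key))
    key <- key[uniq]; src <- src[uniq]
    support <- tapply(src, key, function(s) length(unique(s)))
    parts <- strsplit(names(support), "\t", fixed = TRUE)
    GoldStandard(a = vapply(parts, `[`, character(1), 1L),
                 b = vapply(parts, `[`, character(1), 2L),
                 support = as.integer(support))
}

#' Write a gold standard as a three-column edge list
#'
#' Emits one line per (pair, pseudo-source) so that
#' [readGoldStandard()] on the output reconstructs the same support map.
#'
#' @param gold a [GoldStandard-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGoldStandard <- function(gold, path) {
    df <- goldSupport(gold)
    ord <- order(.byteRank(df$a), .byteRank(df$b))
    df <- df[ord, , drop = FALSE]
    lines <- character()
    for (i in seq_len(nrow(df)))
        lines <- c(lines, paste(df$a[i], df$b[i],
                                paste0("s", seq_len(df$support[i])),
                                sep = "\t"))
    .writeLines(lines, path)
    invisible(path)
}

#' Write ranked pair predictions to TSV
#'
#' Columns `protein_a`, `protein_b`, `score`, `rank`; sorted by descending
#' score with ties broken by `(a, b)` lexicographic ascending byte order.
#' Output bytes are deterministic for a given table.
#'
#' @param table a [PairScoreTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRankedPairs <- function(table, path) {
    stopifnot(is(table, "PairScoreTable"))
    df <- rankedPairs(table)
    lines <- c("protein_a\tprotein_b\tscore\trank",
               if (nrow(df)) paste(df$a, df$b, .fmtScore(df$score), df$rank,
                                   sep = "\t"))
    .writeLines(lines, path)
    invisible(path)
}

#' Read a ranked-pair TSV back into a PairScoreTable
#'
#' @param path a file written by [writeRankedPairs()].
#' @param scorer scorer name to record.
#' @return a [PairScoreTable-class].
#' @export
readRankedPairs <- function(path, scorer = "file") {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "character", "numeric",
                                    "integer"),
                     check.names = FALSE)
    PairScoreTable(a = df$protein_a, b = df$protein_b, score = df$score,
                   scorer = scorer)
}
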