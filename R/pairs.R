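# Canonical unordered protein pairs: a < b under lexicographic byte order.
# All pair bookkeeping in the package goes through these helpers so that
# orientation never matters and self-pairs are rejected in one place.

#' Byte-order rank of character vectors
#'
#' Locale-independent ordering key: ranks strings by raw byte comparison
#' (via the C locale), so canonicalization and tie-breaking do not depend on
#' the session locale.
#' @param x character vector.
#' @return integer-compatible key usable inside `order()`.
#' @keywords internal
.byteRank <- function(x) {
    # xtfrm on a factor with C-sorted levels gives a stable byte-order key
    lev <- .C_sort(unique(x))
    match(x, lev)
}

.C_sort <- function(x) {
    if (!length(x)) return(character())
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
    sort(x, method = "radix")
}

.byteLess <- function(a, b) {
    # elementwise a < b in byte order; radix sort machinery via rank
    r <- .byteRank(c(a, b))
    n <- length(a)
    r[seq_len(n)] < r[n + seq_len(n)]
}

#' Canonicalize unordered protein pairs
#'
#' Orders each pair so that `a < b` under lexicographic byte order.
#' Canonicalization is idempotent and orientation-invariant:
#' `canonicalPairs(a, b)` equals `canonicalPairs(b, a)`.
#'
#' @param a,b character vectors of protein identifiers (recycled to common
#'   length).
#' @return data.frame with columns `a`, `b` in canonical orientation.
#' @examples
#' canonicalPairs(c("Q", "A"), c("B", "B"))
#' @export
canonicalPairs <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    if (length(a) != length(b)) {
        n <- max(length(a), length(b))
        a <- rep_len(a, n); b <- rep_len(b, n)
    }
    if (any(a == b))
        stop("self-pairs are not allowed: ",
             paste(unique(a[a == b]), collapse = ", "))
    swap <- !.byteLess(a, b)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Canonical string keys for unordered pairs
#'
#' @param a,b character vectors of protein identifiers.
#' @return character vector `"a\\tb"` in canonical orientation; useful for
#'   set operations on pairs.
#' @export
pairKeys <- function(a, b) {
    if (!length(a)) return(character())
    cp <- canonicalPairs(a, b)
    paste(cp$a, cp$b, sep = "\t")
}
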