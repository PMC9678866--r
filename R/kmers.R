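#' K-mer catalogs
#'
#' A `kmer_catalog` is an ordered set of distinct uppercase DNA k-mers of a
#' common length `k`. Lexicographic order (A < C < G < T) is the canonical
#' order for a full enumeration.
#'
#' @param sequences character vector of distinct DNA strings of equal length.
#' @param k k-mer length; inferred from `sequences` when missing.
#' @return A `kmer_catalog`: a character vector with attribute `k`.
#' @export
kmer_catalog <- function(sequences, k = NULL) {
  sequences <- toupper(as.character(sequences))
  if (anyNA(sequences)) stop("invalid catalog: NA sequence", call. = FALSE)
  if (length(sequences)) {
    lens <- unique(nchar(sequences))
    if (length(lens) != 1L)
      stop("invalid catalog: sequences of mixed length", call. = FALSE)
    if (is.null(k)) k <- lens
    if (k != lens)
      stop(sprintf("invalid catalog: sequences have length %d, not k = %d",
                   lens, k), call. = FALSE)
    if (anyDuplicated(sequences))
      stop("invalid catalog: duplicate sequences", call. = FALSE)
    if (any(grepl("[^ACGT]", sequences)))
      stop("invalid catalog: non-ACGT sequence", call. = FALSE)
  } else if (is.null(k)) k <- 0L
  structure(sequences, k = as.integer(k), class = "kmer_catalog")
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat(sprintf("kmer_catalog: %d sequences of length %d\n",
              length(x), attr(x, "k")))
  if (length(x)) cat(" ", paste(head(unclass(x), 6L), collapse = " "),
                     if (length(x) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Enumerate all DNA k-mers
#'
#' Generates every k-mer over {A,C,G,T} in lexicographic order, the first
#' step of the arbitrary-primer design cascade (4^10 = 1,048,576 candidates
#' at the default design length of 10).
#'
#' @param k k-mer length, between 1 and 16.
#' @return A [kmer_catalog] of all 4^k sequences.
#' @examples
#' enumerate_kmers(3)
#' @export
enumerate_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1L || k > 16L)
    stop("invalid-parameter: k must be a single integer in [1, 16]",
         call. = FALSE)
  kmer_catalog(Biostrings::mkAllStrings(c("A", "C", "G", "T"), as.integer(k)),
               k = as.integer(k))
}

#' Derive short primers by 3'-end truncation
#'
#' Short (m-mer) priming sequences are obtained from a longer k-mer catalog by
#' keeping the first m bases of each sequence (equivalently, removing k - m
#' bases at the 3' end) and deduplicating.
#'
#' @param catalog a [kmer_catalog].
#' @param m target primer length, strictly less than the catalog's `k`.
#' @return A deduplicated [kmer_catalog] of m-mers, in first-occurrence order.
#' @export
derive_short_primers <- function(catalog, m) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  k <- attr(catalog, "k")
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m >= k)
    stop(sprintf("invalid-parameter: m must satisfy 1 <= m < k = %d", k),
         call. = FALSE)
  kmer_catalog(unique(substr(unclass(catalog), 1L, as.integer(m))),
               k = as.integer(m))
}
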