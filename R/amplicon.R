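#' Assemble a full primer construct sequence
#'
#' A MAAS primer consists of a partial Illumina adapter, a spacer of N bases,
#' and a short 3' priming target; only the target participates in
#' priming-site search.
#'
#' @param adapter adapter sequence (A/C/G/T, nonempty).
#' @param spacer_len number of N bases (>= 0).
#' @param target priming sequence (A/C/G/T, nonempty).
#' @return The full construct string `adapter + N*spacer_len + target`.
#' @examples
#' assemble_construct("CGCTCTTCCGATCT", 7, "GTCGCCC")
#' @export
assemble_construct <- function(adapter, spacer_len, target) {
  adapter <- assert_dna(adapter, "adapter")
  target <- assert_dna(target, "target")
  if (!is.numeric(spacer_len) || length(spacer_len) != 1L || spacer_len < 0L)
    stop("invalid-parameter: spacer_len must be >= 0", call. = FALSE)
  paste0(adapter, strrep("N", as.integer(spacer_len)), target)
}

#' Primer constructs and cocktail specifications
#'
#' `primer_construct` describes one primer (name, adapter, spacer length,
#' priming target); `cocktail_spec` bundles the constructs of a primer
#' cocktail with the amplifiable product-size window and the allowed number
#' of target mismatches. Every construct is usable as both forward and
#' reverse primer, as in a one-pot arbitrary-priming PCR.
#'
#' @param name primer name.
#' @param adapter adapter sequence.
#' @param spacer_len N-spacer length (default 7).
#' @param target 3' priming sequence.
#' @return `primer_construct`: a `primer_construct` list;
#'   `cocktail_spec`: a `cocktail_spec` list.
#' @export
primer_construct <- function(name, adapter = "CGCTCTTCCGATCT", spacer_len = 7L,
                             target) {
  structure(list(name = as.character(name),
                 adapter = assert_dna(adapter, "adapter"),
                 spacer_len = as.integer(spacer_len),
                 target = assert_dna(target, "target")),
            class = "primer_construct")
}

#' @rdname primer_construct
#' @param constructs list of `primer_construct` objects (nonempty).
#' @param min_len,max_len product-size window in bp (defaults 500-2000, the
#'   smear window selected on gels; the tighter 600-1000 bp bead-selection
#'   window is available via `sizes = "library"`).
#' @param max_mismatch allowed substitutions in a priming-site match
#'   (default 0, exact matching).
#' @param sizes `"gel"` (500-2000) or `"library"` (600-1000) preset,
#'   overridden by explicit `min_len`/`max_len`.
#' @export
cocktail_spec <- function(constructs, min_len = NULL, max_len = NULL,
                          max_mismatch = 0L, sizes = c("gel", "library")) {
  sizes <- match.arg(sizes)
  preset <- if (sizes == "gel") c(500L, 2000L) else c(600L, 1000L)
  if (is.null(min_len)) min_len <- preset[1L]
  if (is.null(max_len)) max_len <- preset[2L]
  if (inherits(constructs, "primer_construct")) constructs <- list(constructs)
  if (!length(constructs) ||
      !all(vapply(constructs, inherits, TRUE, "primer_construct")))
    stop("constructs must be a nonempty list of primer_construct",
         call. = FALSE)
  if (!(min_len > 0L && min_len <= max_len))
    stop("require 0 < min_len <= max_len", call. = FALSE)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  nms <- vapply(constructs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate construct names", call. = FALSE)
  structure(list(constructs = setNames(constructs, nms),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_mismatch = as.integer(max_mismatch)),
            class = "cocktail_spec")
}

#' Read a cocktail TSV (name, adapter, spacer, target)
#'
#' @param path TSV with columns name, adapter, spacer, target (header
#'   optional).
#' @param ... passed to [cocktail_spec()].
#' @return A [cocktail_spec()].
#' @export
read_cocktail <- function(path, ...) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("name", "adapter", "spacer", "target"))
  if (identical(tolower(df$name[1L]), "name")) df <- df[-1L, , drop = FALSE]
  cocktail_spec(lapply(seq_len(nrow(df)), function(i)
    primer_construct(df$name[i], df$adapter[i], as.integer(df$spacer[i]),
                     df$target[i])), ...)
}

#' Find priming sites on a genome
#'
#' Locates every position where a cocktail construct's target matches the
#' genome exactly (or within `max_mismatch` substitutions) on the plus
#' strand, and every position whose segment equals the target's reverse
#' complement (minus strand). Overlapping and repeated matches are all
#' reported. Coordinates are 0-based half-open.
#'
#' @param genome FASTA path, `DNAStringSet`, named character vector, or a
#'   `synthetic_genome`.
#' @param cocktail a [cocktail_spec()].
#' @return data.frame (`priming_sites`) with columns `seq_id`, `start`,
#'   `end`, `strand`, `primer`, sorted by (seq_id, start, strand, primer).
#' @export
find_priming_sites <- function(genome, cocktail) {
  stopifnot(inherits(cocktail, "cocktail_spec"))
  dna <- as_dnastringset(genome)
  out <- list()
  for (con in cocktail$constructs) {
    tgt <- Biostrings::DNAString(con$target)
    rct <- Biostrings::reverseComplement(tgt)
    for (i in seq_along(dna)) {
      sid <- names(dna)[i]
      plus <- Biostrings::matchPattern(tgt, dna[[i]],
                                       max.mismatch = cocktail$max_mismatch)
      minus <- Biostrings::matchPattern(rct, dna[[i]],
                                        max.mismatch = cocktail$max_mismatch)
      if (length(plus))
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, start = BiocGenerics::start(plus) - 1L,
          end = BiocGenerics::end(plus), strand = "+", primer = con$name,
          stringsAsFactors = FALSE)
      if (length(minus))
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, start = BiocGenerics::start(minus) - 1L,
          end = BiocGenerics::end(minus), strand = "-", primer = con$name,
          stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), primer = character(0),
               stringsAsFactors = FALSE)
  sites <- sites[order(sites$seq_id, sites$start, sites$strand, sites$primer), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("priming_sites", "data.frame")
  sites
}

#' Predict amplicons from priming sites
#'
#' Emits one amplicon for every ordered (plus site, minus site) pair on the
#' same sequence whose product -- the interval from the 5' end of the plus
#' site to the 5' end of the minus site, including both priming sites -- has
#' a length within the cocktail's size window. All qualifying pairs are
#' enumerated; no competition model is applied.
#'
#' @param sites a `priming_sites` data.frame from [find_priming_sites()].
#' @param spec the [cocktail_spec()] providing `min_len`/`max_len`.
#' @return data.frame (`amplicons`) with columns `seq_id`, `start`, `end`,
#'   `length`, `forward_primer`, `reverse_primer`, sorted by
#'   (seq_id, start, end).
#' @export
predict_amplicons <- function(sites, spec) {
  stopifnot(is.data.frame(sites), inherits(spec, "cocktail_spec"))
  out <- list()
  for (sid in unique(sites$seq_id)) {
    s <- sites[sites$seq_id == sid, , drop = FALSE]
    fw <- s[s$strand == "+", , drop = FALSE]
    rv <- s[s$strand == "-", , drop = FALSE]
    if (!nrow(fw) || !nrow(rv)) next
    idx <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
    len <- rv$end[idx$r] - fw$start[idx$f]
    ok <- len >= spec$min_len & len <= spec$max_len
    if (!any(ok)) next
    idx <- idx[ok, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, start = fw$start[idx$f], end = rv$end[idx$r],
      length = rv$end[idx$r] - fw$start[idx$f],
      forward_primer = fw$primer[idx$f], reverse_primer = rv$primer[idx$r],
      stringsAsFactors = FALSE)
  }
  amp <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), forward_primer = character(0),
               reverse_primer = character(0), stringsAsFactors = FALSE)
  amp <- amp[order(amp$seq_id, amp$start, amp$end), , drop = FALSE]
  rownames(amp) <- NULL
  class(amp) <- c("amplicons", "data.frame")
  amp
}

#' Summarize predicted amplicons
#'
#' @param amplicons an `amplicons` data.frame.
#' @param breaks histogram breaks for the length distribution (bp).
#' @return List with `total`, `per_pair` (data.frame forward, reverse, n) and
#'   `length_hist` (data.frame bin, n). Pair counts sum to the total.
#' @export
amplicon_summary <- function(amplicons,
                             breaks = seq(0L, 2500L, by = 250L)) {
  stopifnot(is.data.frame(amplicons))
  if (!nrow(amplicons))
    return(list(total = 0L,
                per_pair = data.frame(forward_primer = character(0),
                                      reverse_primer = character(0),
                                      n = integer(0)),
                length_hist = data.frame(bin = character(0), n = integer(0))))
  per <- aggregate(list(n = amplicons$start),
                   by = list(forward_primer = amplicons$forward_primer,
                             reverse_primer = amplicons$reverse_primer),
                   FUN = length)
  brk <- unique(c(breaks[breaks < max(amplicons$length)],
                  max(breaks, max(amplicons$length))))
  h <- cut(amplicons$length, breaks = brk, include.lowest = TRUE)
  list(total = nrow(amplicons), per_pair = per,
       length_hist = data.frame(bin = levels(h),
                                n = as.integer(table(h)),
                                stringsAsFactors = FALSE))
}

#' Write amplicons as BED6
#'
#' Name is `<forward>|<reverse>`, score the product length, strand `+`
#' (the product is reported on the plus strand). Coordinates stay 0-based
#' half-open.
#'
#' @param amplicons an `amplicons` data.frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_amplicons_bed <- function(amplicons, path) {
  bed <- data.frame(amplicons$seq_id, amplicons$start, amplicons$end,
                    paste0(amplicons$forward_primer, "|",
                           amplicons$reverse_primer),
                    amplicons$length, "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Extract amplicon sequences
#'
#' @param genome genome input as in [find_priming_sites()].
#' @param amplicons an `amplicons` data.frame.
#' @return A `Biostrings::DNAStringSet` of product sequences, named
#'   `seq_id:start-end|pair`.
#' @export
amplicon_sequences <- function(genome, amplicons) {
  dna <- as_dnastringset(genome)
  if (!nrow(amplicons)) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(amplicons)),
    function(i) as.character(Biostrings::subseq(dna[[amplicons$seq_id[i]]],
      start = amplicons$start[i] + 1L, end = amplicons$end[i])), ""))
  names(seqs) <- sprintf("%s:%d-%d|%s|%s", amplicons$seq_id, amplicons$start,
                         amplicons$end, amplicons$forward_primer,
                         amplicons$reverse_primer)
  seqs
}
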