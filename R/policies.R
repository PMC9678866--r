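#' Simple-sequence-repeat exclusion policy
#'
#' Controls the SSR filter of the design cascade. A candidate is excluded when
#' it contains a mononucleotide run longer than `max_mono_run`, a tandem
#' repeat of a primitive unit of length 2-4 reaching the unit-length-specific
#' repeat count, or any explicitly listed repeat motif (either strand). The
#' defaults are deliberately permissive at 5 identical bases so that short
#' AT-rich priming sequences (such as a published T5-containing 7-mer) are not
#' excluded, while canonical ISSR di-/tri-nucleotide units are.
#'
#' @param max_mono_run longest allowed mononucleotide run (fail when longer).
#' @param min_repeats_by_unit named integer vector mapping unit lengths
#'   `"2"`, `"3"`, `"4"` to the tandem repeat count that triggers exclusion.
#' @param extra_motifs optional character vector of repeat motifs to exclude
#'   as substrings on either strand (e.g. ISSR units used by MIG-seq primers).
#' @return An `ssr_policy` object.
#' @export
ssr_policy <- function(max_mono_run = 5L,
                       min_repeats_by_unit = c(`2` = 3L, `3` = 3L, `4` = 2L),
                       extra_motifs = character()) {
  if (max_mono_run < 1L) stop("max_mono_run must be >= 1", call. = FALSE)
  u <- as.integer(names(min_repeats_by_unit))
  if (length(min_repeats_by_unit) == 0L || anyNA(u) || !all(u %in% 2:4))
    stop("min_repeats_by_unit must be named by unit lengths in {2,3,4}",
         call. = FALSE)
  if (any(min_repeats_by_unit < 2L))
    stop("all repeat-count thresholds must be >= 2", call. = FALSE)
  extra_motifs <- vapply(extra_motifs, assert_dna, "", what = "extra motif",
                         USE.NAMES = FALSE)
  structure(list(max_mono_run = as.integer(max_mono_run),
                 min_repeats_by_unit = setNames(as.integer(min_repeats_by_unit),
                                                names(min_repeats_by_unit)),
                 extra_motifs = extra_motifs),
            class = "ssr_policy")
}

#' K-mer frequency grade boundaries
#'
#' Occurrence counts of a k-mer in a reference genome are stratified into
#' three grades: LOW (count < `low_upper`), MID (`low_upper` <= count <=
#' `high_lower`) and HIGH (count > `high_lower`). Defaults follow the
#' 10^2 / 10^3 stratification used to screen taxon-dependent repeats.
#' Boundary counts (exactly 100 or 1000) fall in MID, so the grades partition
#' the non-negative integers.
#'
#' @param low_upper counts strictly below this are LOW.
#' @param high_lower counts strictly above this are HIGH.
#' @return A `grade_boundaries` object.
#' @export
grade_boundaries <- function(low_upper = 100L, high_lower = 1000L) {
  if (!(low_upper > 0L && low_upper <= high_lower))
    stop("require 0 < low_upper <= high_lower", call. = FALSE)
  structure(list(low_upper = as.numeric(low_upper),
                 high_lower = as.numeric(high_lower)),
            class = "grade_boundaries")
}

#' Self-complementarity screening policy
#'
#' Governs the primer-dimer screen. Each candidate target is assembled into
#' its full constructs (Illumina adapter + N spacer + target); the screen then
#' fails a candidate when (i) the construct's 3'-terminal dinucleotide is
#' reverse-complementary to the 3'-terminal dinucleotide of an evaluated
#' partner construct (two annealed, extendable 3' ends -- under `self_only`
#' scope the partner is the construct itself, so palindromic terminal
#' dinucleotides AT/TA/GC/CG fail), or (ii) a window of `window_check_len`
#' bases of the priming target has its reverse complement at a non-overlapping
#' position of the same target (hairpin/self-dimer geometry), or -- under
#' `pairwise_cocktail` scope -- anywhere in another construct of the cocktail.
#' Spacer N bases never pair and are excluded from all matching.
#'
#' @param adapter_forward,adapter_reverse partial Illumina adapters placed 5'
#'   of the spacer in the forward and reverse constructs.
#' @param spacer_len number of N bases between adapter and target.
#' @param end_dinucleotide_check enable rule (i).
#' @param window_check_len window length for rule (ii); >= 2.
#' @param scope `"self_only"` (default) or `"pairwise_cocktail"`.
#' @return A `self_comp_policy` object.
#' @export
self_comp_policy <- function(adapter_forward = "CGCTCTTCCGATCT",
                             adapter_reverse = "TGCTCTTCCGATCT",
                             spacer_len = 7L,
                             end_dinucleotide_check = TRUE,
                             window_check_len = 3L,
                             scope = c("self_only", "pairwise_cocktail")) {
  scope <- match.arg(scope)
  adapter_forward <- assert_dna(adapter_forward, "adapter_forward")
  adapter_reverse <- assert_dna(adapter_reverse, "adapter_reverse")
  if (window_check_len < 2L) stop("window_check_len must be >= 2", call. = FALSE)
  if (spacer_len < 0L) stop("spacer_len must be >= 0", call. = FALSE)
  structure(list(adapter_forward = adapter_forward,
                 adapter_reverse = adapter_reverse,
                 spacer_len = as.integer(spacer_len),
                 end_dinucleotide_check = isTRUE(end_dinucleotide_check),
                 window_check_len = as.integer(window_check_len),
                 scope = scope),
            class = "self_comp_policy")
}

#' Motif catalogs
#'
#' A catalog of functional motifs (e.g. transcription-factor binding sites)
#' whose presence disqualifies a primer candidate. Each entry has a unique
#' identifier and an IUPAC consensus string; entries may carry the
#' position-frequency matrix the consensus was derived from.
#'
#' @param id character vector of unique motif identifiers.
#' @param consensus character vector of IUPAC consensus strings.
#' @param scan_both_strands also match the reverse complement of each motif.
#' @param pfm optional list of position-frequency matrices (4 x width,
#'   rows A, C, G, T), parallel to `id`.
#' @return A `motif_catalog` object (a data.frame of id/consensus with
#'   attributes).
#' @export
motif_catalog <- function(id, consensus, scan_both_strands = TRUE, pfm = NULL) {
  id <- as.character(id)
  consensus <- toupper(as.character(consensus))
  if (length(id) != length(consensus))
    stop("id and consensus must have equal length", call. = FALSE)
  if (anyDuplicated(id))
    stop("motif identifiers must be unique", call. = FALSE)
  if (any(nchar(consensus) < 1L))
    stop("every consensus must have length >= 1", call. = FALSE)
  for (cs in consensus) iupac_to_regex(cs)  # validates IUPAC codes
  structure(data.frame(id = id, consensus = consensus,
                       stringsAsFactors = FALSE),
            scan_both_strands = isTRUE(scan_both_strands),
            pfm = pfm,
            class = c("motif_catalog", "data.frame"))
}

#' Read a JASPAR-style PFM text file into a motif catalog
#'
#' Parses the JASPAR CORE flat format: a header line `>ID NAME` followed by
#' four rows of counts for A, C, G and T (optionally prefixed by the base
#' letter and wrapped in brackets). A consensus is derived per column as the
#' IUPAC merge of all bases reaching `min_frac` of the column total.
#'
#' @param path path to the PFM text file.
#' @param min_frac minimum relative frequency for a base to enter the
#'   consensus code of a column.
#' @param scan_both_strands passed to [motif_catalog()].
#' @return A [motif_catalog].
#' @export
read_motifs_jaspar <- function(path, min_frac = 0.25, scan_both_strands = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts))
    stop("catalog-parse error: no '>' headers in ", path, call. = FALSE)
  ids <- character(0); cons <- character(0); pfms <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1L]][1L]
    body_end <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    rows <- lines[(starts[i] + 1L):body_end]
    if (length(rows) < 4L)
      stop("catalog-parse error: motif ", id, " has fewer than 4 matrix rows",
           call. = FALSE)
    mat <- t(vapply(rows[1:4], function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
      r <- gsub("[\\[\\]]", "", r, perl = TRUE)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }, numeric(length(strsplit(gsub("[\\[\\]]", "",
        gsub("^[ACGTacgt]\\s*", "", trimws(rows[1L])), perl = TRUE),
        "\\s+")[[1L]]))))
    rownames(mat) <- c("A", "C", "G", "T")
    tot <- colSums(mat)
    cs <- paste(vapply(seq_len(ncol(mat)), function(j) {
      if (tot[j] <= 0) return("N")
      keep <- rownames(mat)[mat[, j] / tot[j] >= min_frac]
      if (!length(keep)) keep <- rownames(mat)[which.max(mat[, j])]
      as.character(Biostrings::mergeIUPACLetters(paste(sort(keep),
                                                       collapse = "")))
    }, ""), collapse = "")
    ids <- c(ids, id); cons <- c(cons, cs); pfms[[id]] <- mat
  }
  motif_catalog(ids, cons, scan_both_strands = scan_both_strands, pfm = pfms)
}

#' Read a plain consensus list into a motif catalog
#'
#' One motif per line, either `id<TAB>consensus` or a bare consensus string
#' (ids are then generated). Lines starting with `#` are skipped.
#'
#' @inheritParams read_motifs_jaspar
#' @return A [motif_catalog].
#' @export
read_motifs_consensus <- function(path, scan_both_strands = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("catalog-parse error: empty motif list", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  has_id <- lengths(parts) >= 2L
  ids <- ifelse(has_id, vapply(parts, `[`, "", 1L),
                sprintf("MOTIF%d", seq_along(lines)))
  cons <- ifelse(has_id, vapply(parts, `[`, "", 2L),
                 vapply(parts, `[`, "", 1L))
  motif_catalog(ids, cons, scan_both_strands = scan_both_strands)
}
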