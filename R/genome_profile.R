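#' Count k-mer occurrences in a genome
#'
#' Counts every overlapping k-length window (step 1) on the forward strand of
#' every record, using `Biostrings::oligonucleotideFrequency`. Windows
#' containing any non-ACGT character are skipped and excluded from
#' `total_windows`; windows never cross record boundaries.
#'
#' @param genome a FASTA path (optionally gzipped), a
#'   `Biostrings::DNAStringSet`, or a named character vector of sequences.
#' @param k k-mer length (>= 1).
#' @param species_id label stored in the profile.
#' @param both_strands also count the reverse complement of each record
#'   (off by default, mirroring the deposited-strand convention).
#' @return A `species_kmer_profile`: list with `species_id`, `k`, `counts`
#'   (named integer vector of the observed, nonzero k-mers, sorted) and
#'   `total_windows`.
#' @examples
#' p <- count_kmers(c(chr = "ACGTACGT"), k = 4)
#' p$counts  # ACGT:2 CGTA:1 GTAC:1 TACG:1
#' @export
count_kmers <- function(genome, k, species_id = "species", both_strands = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stop("invalid-parameter: k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  dna <- as_dnastringset(genome)
  if (length(dna) == 0L || sum(Biostrings::width(dna)) == 0L)
    stop("I/O error: empty genome", call. = FALSE)
  if (both_strands) dna <- c(dna, Biostrings::reverseComplement(dna))
  counts <- colSums(Biostrings::oligonucleotideFrequency(dna, width = k,
                                                         step = 1L))
  counts <- counts[counts > 0L]
  counts <- counts[order(names(counts))]
  structure(list(species_id = as.character(species_id), k = k,
                 counts = counts, total_windows = sum(counts)),
            class = "species_kmer_profile")
}

# Coerce FASTA path / DNAStringSet / character vector to DNAStringSet.
as_dnastringset <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) return(Biostrings::DNAStringSet(genome))
  if (inherits(genome, "synthetic_genome"))
    return(Biostrings::DNAStringSet(setNames(genome$sequence, genome$seq_id)))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(tryCatch(Biostrings::readDNAStringSet(genome),
                    error = function(e)
                      stop("I/O error reading FASTA: ", conditionMessage(e),
                           call. = FALSE)))
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- sprintf("seq%d", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("unsupported genome input", call. = FALSE)
}

#' @export
print.species_kmer_profile <- function(x, ...) {
  cat(sprintf("species_kmer_profile: %s, k=%d, %d distinct k-mers, %d windows\n",
              x$species_id, x$k, length(x$counts), x$total_windows))
  invisible(x)
}

#' Stratify a k-mer profile into frequency grades
#'
#' Assigns every k-mer of a [count_kmers()] profile a LOW/MID/HIGH grade under
#' [grade_boundaries()]. K-mers absent from the profile are implicitly LOW
#' (count 0) wherever the grade profile is consulted.
#'
#' @param profile a `species_kmer_profile`.
#' @param boundaries a [grade_boundaries()].
#' @return A `grade_profile`: list with `species_id`, `k`, `grades` (named
#'   character vector over the observed k-mers) and `boundaries`.
#' @export
stratify <- function(profile, boundaries = grade_boundaries()) {
  stopifnot(inherits(profile, "species_kmer_profile"),
            inherits(boundaries, "grade_boundaries"))
  structure(list(species_id = profile$species_id, k = profile$k,
                 grades = setNames(grade_of(as.numeric(profile$counts),
                                            boundaries),
                                   names(profile$counts)),
                 boundaries = boundaries),
            class = "grade_profile")
}

#' K-mers grade-concordant across species
#'
#' Returns the k-mers whose modal grade across the supplied per-species grade
#' profiles strictly exceeds `threshold` of the species count. K-mers absent
#' from a profile count as LOW in that species, so the universe scanned is
#' the union of observed k-mers plus (implicitly) everything else, which is
#' LOW everywhere and therefore trivially concordant; only the observed union
#' is returned unless `universe` is supplied.
#'
#' @param profiles list of `grade_profile` objects sharing `k` and boundaries.
#' @param threshold concordance threshold (strict), default 0.8.
#' @param universe optional character vector of k-mers to evaluate; defaults
#'   to the union of k-mers observed in any profile.
#' @return Character vector of concordant k-mers (sorted).
#' @export
concordant_kmers <- function(profiles, threshold = 0.8, universe = NULL) {
  if (!length(profiles))
    stop("invalid-parameter: no profiles", call. = FALSE)
  ks <- unique(vapply(profiles, function(p) p$k, 1L))
  if (length(ks) != 1L)
    stop("invalid-parameter: profiles have mixed k", call. = FALSE)
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(profiles,
                                          function(p) names(p$grades)))))
  if (!length(universe)) return(character(0))
  gmat <- vapply(profiles, function(p) {
    g <- p$grades[universe]
    g[is.na(g)] <- "LOW"
    g
  }, character(length(universe)))
  if (length(universe) == 1L) gmat <- matrix(gmat, nrow = 1L)
  n <- length(profiles)
  keep <- apply(gmat, 1L, function(g) max(table(g)) > threshold * n)
  sort(universe[keep])
}

#' Write / read a k-mer profile as TSV
#'
#' Profiles are serialized as a sorted two-column TSV (`kmer`, `count`) with
#' `#` header lines carrying `species_id`, `k` and `total_windows`, so grade
#' profiles are reproducible byte-for-byte.
#'
#' @param profile a `species_kmer_profile`.
#' @param path TSV path.
#' @return `write_profile`: `path` invisibly; `read_profile`: the profile.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "species_kmer_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# species_id=%s", profile$species_id),
               sprintf("# k=%d", profile$k),
               sprintf("# total_windows=%d", profile$total_windows),
               "kmer\tcount",
               sprintf("%s\t%d", names(profile$counts), profile$counts)), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE)[1L])
  body <- lines[!grepl("^#", lines)][-1L]  # drop column header
  counts <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- setNames(as.integer(vapply(parts, `[`, "", 2L)),
                       vapply(parts, `[`, "", 1L))
  }
  structure(list(species_id = get("species_id"), k = as.integer(get("k")),
                 counts = counts,
                 total_windows = as.integer(get("total_windows"))),
            class = "species_kmer_profile")
}
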