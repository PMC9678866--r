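#' Simulate a genome with planted features
#'
#' Generates an i.i.d. random DNA sequence at a stated GC content and
#' overwrites it with planted features (priming sites, SSRs, motifs) at fixed
#' positions. Deterministic under `seed`. This is the stand-in for a
#' reference genome: it reproduces base composition and exact planted priming
#' sites, but none of the repeat structure, chromosome organisation or
#' polymorphism of a real genome.
#'
#' @param length genome length in bases.
#' @param gc GC fraction in [0,1] (default 0.5).
#' @param seed integer seed.
#' @param plants list of `list(seq = <DNA string>, pos = <0-based offset>)`
#'   features to embed; they must fit within the genome and not overlap.
#' @param seq_id sequence name (default "chr1").
#' @return A `synthetic_genome`: list with `seq_id`, `sequence` (character),
#'   `plants` (manifest data.frame with seq, start, end) and `length`.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL, plants = list(),
                            seq_id = "chr1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  manifest <- data.frame(seq = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  if (length(plants)) {
    manifest <- do.call(rbind, lapply(plants, function(p) {
      s <- assert_dna(p$seq, "plant")
      data.frame(seq = s, start = as.integer(p$pos),
                 end = as.integer(p$pos) + nchar(s), stringsAsFactors = FALSE)
    }))
    if (any(manifest$start < 0L) || any(manifest$end > length))
      stop("invalid-spec: plant outside genome bounds", call. = FALSE)
    o <- order(manifest$start)
    if (any(manifest$start[o][-1L] < manifest$end[o][-nrow(manifest)]))
      stop("invalid-spec: overlapping plants", call. = FALSE)
  }
  base <- with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  for (i in seq_len(nrow(manifest)))
    base[(manifest$start[i] + 1L):manifest$end[i]] <-
      strsplit(manifest$seq[i], "", fixed = TRUE)[[1L]]
  structure(list(seq_id = seq_id, sequence = paste(base, collapse = ""),
                 plants = manifest, length = as.integer(length)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %s, %d bp, %d planted features\n",
              x$seq_id, x$length, nrow(x$plants)))
  invisible(x)
}

#' Write a synthetic genome as FASTA
#'
#' @param genome a `synthetic_genome`.
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome), path)
  invisible(path)
}

#' Plant a forward/reverse priming-site pair defining one amplicon
#'
#' Writes `forward_target` at `start` and the reverse complement of
#' `reverse_target` so that the product interval
#' `[start, start + product_len)` ends with it, and records the resulting
#' truth-table row. The truth table is the ground truth against which
#' amplicon prediction and the bias model are checked.
#'
#' @param genome a `synthetic_genome`.
#' @param forward_target,reverse_target priming sequences (A/C/G/T).
#' @param start 0-based product start.
#' @param product_len product length in bases (>= sum of target lengths).
#' @param forward_name,reverse_name primer names recorded in the truth row.
#' @param weight relative amplification efficiency (> 0) recorded in the
#'   truth row.
#' @return The updated `synthetic_genome`, with the truth table in
#'   `attr(, "truth")` grown by one row (columns seq_id, start, end,
#'   forward_primer, reverse_primer, weight).
#' @export
plant_amplicon_pair <- function(genome, forward_target, reverse_target,
                                start, product_len,
                                forward_name = forward_target,
                                reverse_name = reverse_target,
                                weight = 1) {
  stopifnot(inherits(genome, "synthetic_genome"), weight > 0)
  forward_target <- assert_dna(forward_target, "forward target")
  reverse_target <- assert_dna(reverse_target, "reverse target")
  flen <- nchar(forward_target); rlen <- nchar(reverse_target)
  if (product_len < flen + rlen)
    stop("invalid-spec: product shorter than its priming sites", call. = FALSE)
  end <- start + product_len
  if (start < 0L || end > genome$length)
    stop("invalid-spec: product outside genome bounds", call. = FALSE)
  new <- data.frame(seq = c(forward_target, revcomp(reverse_target)),
                    start = as.integer(c(start, end - rlen)),
                    end = as.integer(c(start + flen, end)),
                    stringsAsFactors = FALSE)
  all_pl <- rbind(genome$plants, new)
  o <- order(all_pl$start)
  if (any(all_pl$start[o][-1L] < all_pl$end[o][-nrow(all_pl)]))
    stop("invalid-spec: collision with an existing plant", call. = FALSE)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  for (i in 1:2)
    chars[(new$start[i] + 1L):new$end[i]] <-
      strsplit(new$seq[i], "", fixed = TRUE)[[1L]]
  genome$sequence <- paste(chars, collapse = "")
  genome$plants <- all_pl[order(all_pl$start), , drop = FALSE]
  rownames(genome$plants) <- NULL
  row <- data.frame(seq_id = genome$seq_id, start = as.integer(start),
                    end = as.integer(end), forward_primer = forward_name,
                    reverse_primer = reverse_name, weight = weight,
                    stringsAsFactors = FALSE)
  attr(genome, "truth") <- rbind(attr(genome, "truth"), row)
  genome
}

#' Truth amplicon table of a synthetic genome
#'
#' @param genome a `synthetic_genome` built up with [plant_amplicon_pair()].
#' @return data.frame with columns seq_id, start, end, forward_primer,
#'   reverse_primer, weight (zero rows if nothing planted).
#' @export
truth_table <- function(genome) {
  tt <- attr(genome, "truth")
  if (is.null(tt))
    tt <- data.frame(seq_id = character(0), start = integer(0),
                     end = integer(0), forward_primer = character(0),
                     reverse_primer = character(0), weight = numeric(0),
                     stringsAsFactors = FALSE)
  tt
}

#' Simulate amplification-biased reads over a truth amplicon table
#'
#' Per-amplicon efficiencies are the truth weights multiplied by log-normal
#' draws with standard deviation `bias_sdlog` on the log scale (0 = unbiased);
#' reads are allocated to amplicons multinomially by efficiency and each read
#' is placed at one end of its amplicon (paired-end geometry: the forward
#' read covers the first `read_len` bases of the product, the reverse read
#' the last `read_len`). Read counts are conserved exactly. Large
#' `bias_sdlog` reproduces the regime where a few products soak up most of
#' the sequencing output.
#'
#' @param truth a truth table (see [truth_table()]).
#' @param n_reads total reads to place (>= 0).
#' @param read_len read length (default 150); must not exceed the shortest
#'   amplicon.
#' @param bias_sdlog sdlog of the log-normal per-amplicon efficiency.
#' @param seed integer seed.
#' @param individual_id label for the returned placements.
#' @return A [read_placements()] data.frame with an `amplicon` column, and
#'   the realized per-amplicon allocation in `attr(, "allocation")`.
#' @export
simulate_reads <- function(truth, n_reads, read_len = 150L, bias_sdlog = 0,
                           seed = NULL, individual_id = "ind") {
  stopifnot(n_reads >= 0, bias_sdlog >= 0)
  if (n_reads > 0 && !nrow(truth))
    stop("invalid-spec: no amplicons to place reads on", call. = FALSE)
  empty <- read_placements(data.frame(seq_id = character(0),
                                      start = integer(0), end = integer(0)),
                           individual_id)
  if (n_reads == 0) {
    attr(empty, "allocation") <- integer(nrow(truth))
    return(empty)
  }
  if (read_len > min(truth$end - truth$start))
    stop("invalid-spec: read_len exceeds the shortest amplicon", call. = FALSE)
  with_seed(seed, {
    eff <- truth$weight * rlnorm(nrow(truth), meanlog = 0, sdlog = bias_sdlog)
    alloc <- as.integer(rmultinom(1L, size = as.integer(n_reads),
                                  prob = eff / sum(eff)))
    fwd_n <- rbinom(nrow(truth), alloc, 0.5)
  })
  rev_n <- alloc - fwd_n
  idx_f <- rep(seq_len(nrow(truth)), fwd_n)
  idx_r <- rep(seq_len(nrow(truth)), rev_n)
  pl <- data.frame(
    seq_id = c(truth$seq_id[idx_f], truth$seq_id[idx_r]),
    start = c(truth$start[idx_f], truth$end[idx_r] - read_len),
    end = c(truth$start[idx_f] + read_len, truth$end[idx_r]),
    amplicon = c(idx_f, idx_r),
    stringsAsFactors = FALSE)
  out <- read_placements(pl[, c("seq_id", "start", "end")], individual_id)
  out$amplicon <- pl$amplicon
  attr(out, "allocation") <- alloc
  out
}

#' Simulate a multi-individual cohort with per-locus dropout
#'
#' Every individual shares the same locus set (the truth-table intervals plus
#' an optional always-retained core) and retains each non-core locus
#' independently with probability `retention`; retained locus bases receive a
#' constant depth `depth_at`. The expected commonly covered bases over x
#' individuals is therefore `locus_bases * retention^x + core_bases`, i.e.
#' the reduction model holds exactly with C1 = locus bases, a = retention,
#' C2 = core bases.
#'
#' @param loci data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), e.g. a [truth_table()].
#' @param n_individuals cohort size.
#' @param retention per-locus retention probability p in (0, 1].
#' @param core_bases bases of an always-retained core locus appended on a
#'   dedicated `core` sequence (default 0).
#' @param depth_at constant depth assigned to retained bases (default 20).
#' @param genome_length reference denominator for the profiles; defaults to
#'   total locus + core bases.
#' @param seed integer seed (one stream, individuals drawn sequentially).
#' @return List of [depth_profile()] objects, one per individual, with the
#'   per-individual retained locus indices in `attr(, "retained")`.
#' @export
simulate_cohort <- function(loci, n_individuals, retention, core_bases = 0L,
                            depth_at = 20L, genome_length = NULL,
                            seed = NULL) {
  stopifnot(n_individuals >= 1, retention > 0, retention <= 1,
            core_bases >= 0, depth_at >= 1)
  loci <- loci[, c("seq_id", "start", "end")]
  if (nrow(loci) && any(loci$start >= loci$end))
    stop("invalid-spec: loci must satisfy start < end", call. = FALSE)
  locus_bases <- sum(loci$end - loci$start)
  if (is.null(genome_length)) genome_length <- locus_bases + core_bases
  core <- if (core_bases > 0)
    data.frame(seq_id = "core", pos = seq_len(core_bases),
               depth = as.integer(depth_at), stringsAsFactors = FALSE)
  else NULL
  keep_mat <- with_seed(seed,
    matrix(runif(n_individuals * nrow(loci)) <= retention,
           nrow = n_individuals))
  profiles <- lapply(seq_len(n_individuals), function(i) {
    kept <- which(keep_mat[i, ])
    rows <- core
    if (length(kept)) {
      li <- loci[kept, , drop = FALSE]
      pos <- unlist(lapply(seq_len(nrow(li)),
                           function(j) (li$start[j] + 1L):li$end[j]))
      sid <- rep(li$seq_id, li$end - li$start)
      rows <- rbind(rows, data.frame(seq_id = sid, pos = pos,
                                     depth = as.integer(depth_at),
                                     stringsAsFactors = FALSE))
    }
    if (is.null(rows))
      rows <- data.frame(seq_id = character(0), pos = integer(0),
                         depth = integer(0))
    p <- depth_profile(rows, genome_length, sprintf("ind%02d", i))
    attr(p, "retained") <- kept
    p
  })
  attr(profiles, "locus_bases") <- locus_bases
  attr(profiles, "core_bases") <- as.integer(core_bases)
  profiles
}

#' Write a depth profile as a samtools-depth-style TSV
#'
#' @param profile a [depth_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  write.table(profile$depths, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write read placements as BED3
#'
#' @param placements a [read_placements()] data.frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_placements_bed <- function(placements, path) {
  write.table(placements[, c("seq_id", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ (fixed quality)
#'
#' Optional sugar: emits one fixed-quality FASTQ record per placement, with
#' the read sequence cut from the genome (reverse-complemented for reverse
#' placements, i.e. placements ending at an amplicon end).
#'
#' @param genome a `synthetic_genome` the placements refer to.
#' @param placements a [read_placements()] data.frame from [simulate_reads()].
#' @param path output FASTQ path.
#' @param quality_char Phred+33 quality character (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(genome, placements, path, quality_char = "I") {
  dna <- as_dnastringset(genome)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(placements))) {
    s <- as.character(Biostrings::subseq(dna[[placements$seq_id[i]]],
                                         start = placements$start[i] + 1L,
                                         end = placements$end[i]))
    writeLines(c(sprintf("@read%d %s:%d-%d", i, placements$seq_id[i],
                         placements$start[i], placements$end[i]),
                 s, "+", strrep(quality_char, nchar(s))), con)
  }
  invisible(path)
}
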