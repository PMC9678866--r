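# Independent brute-force oracles. These are deliberately written with a
# different structure from the package code (explicit position loops, no
# regex, no Biostrings) so that agreement is informative.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  ch <- strsplit(s, "")[[1]]
  paste(COMP[rev(ch)], collapse = "")
}

# SSR oracle: exhaustive scan over every (start, unit length, repeat count).
oracle_ssr_fails <- function(seq, max_mono_run = 5,
                             thresholds = c(`2` = 3, `3` = 3, `4` = 2),
                             extra = character()) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  run <- 1
  for (i in seq_len(n - 1)) {
    run <- if (ch[i + 1] == ch[i]) run + 1 else 1
    if (run > max_mono_run) return(TRUE)
  }
  for (u in as.integer(names(thresholds))) {
    r <- thresholds[[as.character(u)]]
    for (i in seq_len(max(n - u * r + 1, 0))) {
      unit <- substr(seq, i, i + u - 1)
      # primitive unit check by direct comparison against all divisors
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            unit == strrep(substr(unit, 1, d), u / d)) prim <- FALSE
      }
      if (!prim) next
      ok <- TRUE
      for (j in seq_len(r - 1)) {
        if (substr(seq, i + j * u, i + (j + 1) * u - 1) != unit) {
          ok <- FALSE; break
        }
      }
      if (ok) return(TRUE)
    }
  }
  for (m in extra) {
    for (probe in c(m, oracle_revcomp(m))) {
      lm <- nchar(probe)
      for (i in seq_len(max(n - lm + 1, 0)))
        if (substr(seq, i, i + lm - 1) == probe) return(TRUE)
    }
  }
  FALSE
}

# IUPAC motif oracle: expand the consensus into all concrete strings and
# test each by substring equality on both strands.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_expand_iupac <- function(consensus) {
  sets <- IUPAC_SETS[strsplit(consensus, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

oracle_motif_fails <- function(seq, consensi, both_strands = TRUE) {
  for (cs in consensi) {
    if (nchar(cs) > nchar(seq)) next
    for (concrete in oracle_expand_iupac(cs)) {
      strands <- if (both_strands) c(seq, oracle_revcomp(seq)) else seq
      for (s in strands) {
        lm <- nchar(concrete)
        for (i in seq_len(nchar(s) - lm + 1))
          if (substr(s, i, i + lm - 1) == concrete) return(TRUE)
      }
    }
  }
  FALSE
}

# Self-complementarity oracle (self_only scope): explicit double loop over
# disjoint window pairs, plus the 3'-end dinucleotide pairing rule.
oracle_selfcomp_fails <- function(target, w = 3) {
  n <- nchar(target)
  last2 <- substr(target, n - 1, n)
  if (oracle_revcomp(last2) == last2) return(TRUE)
  if (n >= w) {
    for (i in seq_len(n - w + 1)) {
      for (j in seq_len(n - w + 1)) {
        if (j + w - 1 < i || j > i + w - 1) {
          ok <- TRUE
          for (p in seq_len(w)) {
            if (substr(target, i + p - 1, i + p - 1) !=
                COMP[[substr(target, j + w - p, j + w - p)]]) {
              ok <- FALSE; break
            }
          }
          if (ok) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Quadratic in-silico PCR oracle: scan every position for every target on
# both strands, then pair every (+, -) site.
oracle_sites <- function(seqs, targets) {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    primer = character(0))
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    for (nm in names(targets)) {
      t <- targets[[nm]]; lt <- nchar(t); rt <- oracle_revcomp(t)
      for (i in seq_len(nchar(s) - lt + 1)) {
        seg <- substr(s, i, i + lt - 1)
        if (seg == t)
          out <- rbind(out, data.frame(seq_id = sid, start = i - 1L,
                                       end = i - 1L + lt, strand = "+",
                                       primer = nm))
        if (seg == rt)
          out <- rbind(out, data.frame(seq_id = sid, start = i - 1L,
                                       end = i - 1L + lt, strand = "-",
                                       primer = nm))
      }
    }
  }
  out[order(out$seq_id, out$start, out$strand, out$primer), , drop = FALSE]
}

oracle_amplicons <- function(sites, min_len, max_len) {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    forward_primer = character(0),
                    reverse_primer = character(0))
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$seq_id[i] != minus$seq_id[j]) next
      len <- minus$end[j] - plus$start[i]
      if (len >= min_len && len <= max_len)
        out <- rbind(out, data.frame(seq_id = plus$seq_id[i],
                                     start = plus$start[i],
                                     end = minus$end[j], length = len,
                                     forward_primer = plus$primer[i],
                                     reverse_primer = minus$primer[j]))
    }
  }
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random depth profile over a small genome, plus its dense vector
random_depth_profile <- function(genome_length, n_pos, max_depth = 50,
                                 id = "ind") {
  pos <- sort(sample.int(genome_length, n_pos))
  depth_profile(data.frame(seq_id = "chr1", pos = pos,
                           depth = sample.int(max_depth, n_pos,
                                              replace = TRUE)),
                genome_length, id)
}

dense_depth <- function(profile) {
  v <- integer(profile$genome_length)
  v[profile$depths$pos] <- profile$depths$depth
  v
}
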