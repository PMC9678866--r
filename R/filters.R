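#' Filter verdicts
#'
#' All per-sequence design filters return a `filter_verdict`: a list with
#' elements `verdict` (`"pass"` or `"fail"`) and `evidence` (a string naming
#' the offending feature on failure, `NA` on pass).
#'
#' @param pass logical scalar.
#' @param evidence evidence string; required when `pass` is `FALSE`.
#' @return A `filter_verdict` list.
#' @keywords internal
filter_verdict <- function(pass, evidence = NA_character_) {
  if (!pass && (is.na(evidence) || !nzchar(evidence)))
    stop("evidence required for a fail verdict", call. = FALSE)
  structure(list(verdict = if (pass) "pass" else "fail",
                 evidence = if (pass) NA_character_ else evidence),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(x$verdict, if (!is.na(x$evidence)) paste0("(", x$evidence, ")"), "\n")
  invisible(x)
}

# Longest mononucleotide run; returns c(len, offset0) or NULL.
longest_mono_run <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  i <- which.max(r$lengths)
  off <- if (i > 1L) sum(r$lengths[seq_len(i - 1L)]) else 0L
  list(base = r$values[i], len = r$lengths[i], offset = off)
}

# Is unit a repetition of a shorter unit? (non-primitive units are skipped:
# their repeats are reported at the shorter period)
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        unit == paste(rep(substr(unit, 1L, d), u / d), collapse = ""))
      return(FALSE)
  }
  TRUE
}

# First tandem repeat of a primitive unit of length `u` with >= `r` copies;
# returns list(unit, repeats, offset) or NULL.
find_tandem_repeat <- function(seq, u, r) {
  n <- nchar(seq)
  if (n < u * r) return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  i <- 1L
  while (i <= n - u * r + 1L) {
    unit <- substr(seq, i, i + u - 1L)
    if (is_primitive_unit(unit)) {
      reps <- 1L
      while (i + (reps + 1L) * u - 1L <= n &&
             substr(seq, i + reps * u, i + (reps + 1L) * u - 1L) == unit)
        reps <- reps + 1L
      if (reps >= r)
        return(list(unit = unit, repeats = reps, offset = i - 1L))
    }
    i <- i + 1L
  }
  NULL
}

#' Simple-sequence-repeat filter
#'
#' Fails a candidate priming sequence that contains a mononucleotide run
#' longer than allowed, a tandem repeat of a primitive 2-4 base unit reaching
#' its repeat threshold, or an explicitly excluded repeat motif on either
#' strand. See [ssr_policy()] for the thresholds.
#'
#' @param seq DNA string over {A,C,G,T}.
#' @param policy an [ssr_policy()].
#' @return A [filter_verdict]; evidence names the repeat and its 0-based
#'   offset.
#' @examples
#' ssr_filter("ACACACACAC", ssr_policy())  # dinucleotide SSR -> fail
#' ssr_filter("TTTTTGTAAA", ssr_policy())  # T run of 5 -> pass
#' @export
ssr_filter <- function(seq, policy = ssr_policy()) {
  seq <- assert_dna(seq)
  stopifnot(inherits(policy, "ssr_policy"))
  mono <- longest_mono_run(seq)
  if (mono$len > policy$max_mono_run)
    return(filter_verdict(FALSE, sprintf(
      "mononucleotide run %s x%d at %d", mono$base, mono$len, mono$offset)))
  for (u in as.integer(names(policy$min_repeats_by_unit))) {
    hit <- find_tandem_repeat(seq, u, policy$min_repeats_by_unit[[as.character(u)]])
    if (!is.null(hit))
      return(filter_verdict(FALSE, sprintf(
        "tandem repeat unit=%s repeats=%d at %d",
        hit$unit, hit$repeats, hit$offset)))
  }
  for (m in policy$extra_motifs) {
    fwd <- regexpr(m, seq, fixed = TRUE)
    if (fwd > 0L)
      return(filter_verdict(FALSE, sprintf(
        "excluded motif %s at %d (+)", m, fwd - 1L)))
    rev_ <- regexpr(revcomp(m), seq, fixed = TRUE)
    if (rev_ > 0L)
      return(filter_verdict(FALSE, sprintf(
        "excluded motif %s at %d (-)", m, rev_ - 1L)))
  }
  filter_verdict(TRUE)
}

#' Functional-motif filter
#'
#' Fails a candidate that contains any catalog motif, matched as an IUPAC
#' consensus substring on the forward strand or (when the catalog scans both
#' strands) on the reverse complement. Motifs longer than the candidate are
#' skipped.
#'
#' @param seq DNA string.
#' @param catalog a [motif_catalog()].
#' @return A [filter_verdict]; evidence names the motif id, 0-based offset
#'   and strand.
#' @export
motif_filter <- function(seq, catalog) {
  seq <- assert_dna(seq)
  stopifnot(inherits(catalog, "motif_catalog"))
  both <- isTRUE(attr(catalog, "scan_both_strands"))
  for (i in seq_len(nrow(catalog))) {
    cs <- catalog$consensus[i]
    if (nchar(cs) > nchar(seq)) next
    m <- regexpr(iupac_to_regex(cs), seq, perl = TRUE)
    if (m > 0L)
      return(filter_verdict(FALSE, sprintf(
        "motif %s at %d (+)", catalog$id[i], m - 1L)))
    if (both) {
      m <- regexpr(iupac_to_regex(iupac_revcomp(cs)), seq, perl = TRUE)
      if (m > 0L)
        return(filter_verdict(FALSE, sprintf(
          "motif %s at %d (-)", catalog$id[i], m - 1L)))
    }
  }
  filter_verdict(TRUE)
}

#' Frequency grade of an occurrence count
#'
#' Stratifies genome occurrence counts into LOW / MID / HIGH under
#' [grade_boundaries()]. Vectorized over `count`.
#'
#' @param count non-negative integer vector of k-mer occurrence counts.
#' @param boundaries a [grade_boundaries()].
#' @return Character vector of grades in {"LOW","MID","HIGH"}.
#' @examples
#' grade_of(c(99, 100, 1000, 1001), grade_boundaries())
#' @export
grade_of <- function(count, boundaries = grade_boundaries()) {
  stopifnot(inherits(boundaries, "grade_boundaries"))
  if (any(is.na(count)) || any(count < 0))
    stop("counts must be non-negative", call. = FALSE)
  ifelse(count < boundaries$low_upper, "LOW",
         ifelse(count > boundaries$high_lower, "HIGH", "MID"))
}

#' Cross-taxon grade concordance filter
#'
#' A candidate k-mer is kept only when one grade is shared by strictly more
#' than `threshold` of the species profiled (with 17 species and the default
#' 0.8 this admits 14 concordant species and rejects 13). Ties between modal
#' grades do not affect the verdict; the reported modal grade is the
#' alphabetically first of the tied maxima.
#'
#' @param grades_per_species character vector of grades, one per species.
#' @param threshold required modal fraction (strict inequality), in (0,1).
#' @return A list with `verdict` (`"keep"`/`"drop"`), `modal_grade`,
#'   `modal_count` and `n_species`.
#' @export
concordance_filter <- function(grades_per_species, threshold = 0.8) {
  if (!length(grades_per_species))
    stop("invalid-parameter: empty grade list", call. = FALSE)
  if (!(threshold > 0 && threshold < 1))
    stop("invalid-parameter: threshold must be in (0,1)", call. = FALSE)
  tab <- table(grades_per_species)
  modal <- max(tab)
  n <- length(grades_per_species)
  list(verdict = if (modal > threshold * n) "keep" else "drop",
       modal_grade = names(tab)[which.max(tab)],
       modal_count = as.integer(modal),
       n_species = n)
}

# All length-w windows of a string (character vector), with 0-based offsets.
seq_windows <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  substring(seq, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
}

#' Self-complementarity (primer-dimer) filter
#'
#' Screens a candidate target for dimer- and hairpin-forming complementarity
#' after assembly into its full constructs (adapter + N spacer + target), per
#' [self_comp_policy()]: rule (i) fails mutually reverse-complementary
#' 3'-terminal dinucleotides (under the default `self_only` scope this
#' rejects targets ending in the palindromic dinucleotides AT, TA, GC, CG);
#' rule (ii) fails a target containing a window of `window_check_len` bases
#' whose reverse complement occurs at a non-overlapping position of the same
#' target, or -- under `pairwise_cocktail` scope -- anywhere in another
#' construct of the cocktail.
#'
#' @param target candidate priming sequence (A/C/G/T).
#' @param policy a [self_comp_policy()].
#' @param cocktail_context optional character vector of other targets in the
#'   cocktail, used under `pairwise_cocktail` scope.
#' @return A [filter_verdict].
#' @examples
#' self_complementarity_filter("GAATTC")   # palindrome -> fail
#' self_complementarity_filter("GTCGCCC")  # published target -> pass
#' @export
self_complementarity_filter <- function(target,
                                        policy = self_comp_policy(),
                                        cocktail_context = NULL) {
  target <- assert_dna(target, "target")
  stopifnot(inherits(policy, "self_comp_policy"))
  pairwise <- policy$scope == "pairwise_cocktail" && length(cocktail_context)
  others <- if (pairwise)
    vapply(cocktail_context, assert_dna, "", what = "cocktail target",
           USE.NAMES = FALSE) else character(0)

  last2 <- function(t) substr(t, nchar(t) - 1L, nchar(t))
  # rule (i): annealed 3' ends
  if (policy$end_dinucleotide_check) {
    partners <- c(target, others)
    seed <- revcomp(last2(target))
    hit <- partners[last2(partners) == seed]
    if (length(hit))
      return(filter_verdict(FALSE, sprintf(
        "3'-end dinucleotide %s pairs with 3' end of %s",
        last2(target), if (hit[1L] == target) "itself" else hit[1L])))
  }

  # rule (ii): complementary windows
  w <- policy$window_check_len
  wins <- seq_windows(target, w)
  n <- nchar(target)
  for (i in seq_along(wins)) {
    rcw <- revcomp(wins[i])
    # hairpin within the target: occurrence disjoint from the window itself
    starts <- gregexpr(rcw, target, fixed = TRUE)[[1L]]
    if (starts[1L] > 0L) {
      disjoint <- starts[starts + w - 1L < i | starts > i + w - 1L]
      if (length(disjoint))
        return(filter_verdict(FALSE, sprintf(
          "window %s at %d reverse-complements %s at %d in target",
          wins[i], i - 1L, rcw, disjoint[1L] - 1L)))
    }
    if (pairwise) {
      for (ot in others) {
        cons <- c(assemble_construct(policy$adapter_forward,
                                     policy$spacer_len, ot),
                  assemble_construct(policy$adapter_reverse,
                                     policy$spacer_len, ot))
        off <- regexpr(rcw, cons[1L], fixed = TRUE)
        if (off < 0L) off <- regexpr(rcw, cons[2L], fixed = TRUE)
        if (off > 0L)
          return(filter_verdict(FALSE, sprintf(
            "window %s at %d reverse-complements construct of %s",
            wins[i], i - 1L, ot)))
      }
    }
  }
  filter_verdict(TRUE)
}

#' Run the full primer-design cascade
#'
#' Applies the design filters in their canonical order -- exhaustive k-mer
#' enumeration, SSR exclusion, functional-motif exclusion, cross-taxon grade
#' concordance, self-complementarity screen -- records a per-filter verdict
#' for every candidate, and derives short primers from the survivors. The
#' surviving set is invariant to reordering of the pure per-sequence filters.
#'
#' @param k candidate k-mer length (the cascade enumerates all 4^k).
#' @param short_k length of the derived short primers; `NULL` to skip
#'   derivation.
#' @param ssr an [ssr_policy()], or `NULL` to skip the SSR filter.
#' @param motifs a [motif_catalog()], or `NULL` to skip the motif filter.
#' @param profiles list of grade profiles (see [stratify()]) for the
#'   concordance filter, or `NULL` to skip it.
#' @param threshold concordance threshold (strict), default 0.8.
#' @param selfcomp a [self_comp_policy()], or `NULL` to skip the screen.
#' @return A `maas_design` list: `candidates` (data.frame with target,
#'   per-filter verdicts, evidence and `surviving`), `survivors`
#'   ([kmer_catalog]) and `short_primers` ([kmer_catalog] or `NULL`).
#' @export
run_design_pipeline <- function(k,
                                short_k = NULL,
                                ssr = ssr_policy(),
                                motifs = NULL,
                                profiles = NULL,
                                threshold = 0.8,
                                selfcomp = self_comp_policy()) {
  cat_k <- enumerate_kmers(k)
  targets <- as.character(unclass(cat_k))
  nc <- length(targets)

  res <- data.frame(target = targets, stringsAsFactors = FALSE)
  run_filter <- function(fun) {
    v <- lapply(targets, fun)
    list(verdict = vapply(v, `[[`, "", "verdict"),
         evidence = vapply(v, `[[`, NA_character_, "evidence"))
  }

  if (!is.null(ssr)) {
    f <- run_filter(function(t) ssr_filter(t, ssr))
    res$ssr <- f$verdict; res$ssr_evidence <- f$evidence
  } else res$ssr <- rep("pass", nc)

  if (!is.null(motifs) && nrow(motifs) > 0L) {
    f <- run_filter(function(t) motif_filter(t, motifs))
    res$motif <- f$verdict; res$motif_evidence <- f$evidence
  } else res$motif <- rep("pass", nc)

  if (!is.null(profiles) && length(profiles)) {
    if (length(unique(vapply(profiles, function(p) p$k, 1L))) != 1L ||
        profiles[[1L]]$k != attr(cat_k, "k"))
      stop("configuration error: profiles must share the catalog's k",
           call. = FALSE)
    grades <- vapply(profiles, function(p) {
      g <- p$grades[targets]
      g[is.na(g)] <- "LOW"
      g
    }, character(nc))
    if (nc == 1L) grades <- matrix(grades, nrow = 1L)
    conc <- apply(grades, 1L, function(g) {
      cf <- concordance_filter(g, threshold)
      c(cf$verdict, cf$modal_grade)
    })
    res$concordance <- ifelse(conc[1L, ] == "keep", "pass", "fail")
    res$concordance_evidence <- ifelse(conc[1L, ] == "keep", NA_character_,
      sprintf("modal grade %s below concordance threshold", conc[2L, ]))
    res$modal_grade <- conc[2L, ]
  } else res$concordance <- rep("pass", nc)

  if (!is.null(selfcomp)) {
    f <- run_filter(function(t) self_complementarity_filter(t, selfcomp))
    res$selfcomp <- f$verdict; res$selfcomp_evidence <- f$evidence
  } else res$selfcomp <- rep("pass", nc)

  res$surviving <- res$ssr == "pass" & res$motif == "pass" &
    res$concordance == "pass" & res$selfcomp == "pass"
  survivors <- kmer_catalog(res$target[res$surviving], k = attr(cat_k, "k"))
  short <- if (!is.null(short_k) && length(survivors))
    derive_short_primers(survivors, short_k) else NULL
  structure(list(candidates = res, survivors = survivors,
                 short_primers = short),
            class = "maas_design")
}

#' @export
print.maas_design <- function(x, ...) {
  cat(sprintf("maas_design: %d candidates, %d survivors%s\n",
              nrow(x$candidates), length(x$survivors),
              if (!is.null(x$short_primers))
                sprintf(", %d short primers", length(x$short_primers)) else ""))
  invisible(x)
}

#' Write design candidates to TSV
#'
#' @param design a `maas_design` from [run_design_pipeline()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(design, path) {
  stopifnot(inherits(design, "maas_design"))
  write.table(design$candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
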