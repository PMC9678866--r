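#' @importFrom methods is
#' @importFrom stats nls rmultinom rbinom runif rlnorm setNames coef resid
#'   aggregate
#' @importFrom utils head write.table read.table
NULL

# Validate a DNA string over {A,C,G,T}; returns the uppercased sequence.
assert_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("invalid %s: must be a single character string", what), call. = FALSE)
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L)
    stop(sprintf("invalid %s: empty", what), call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(sprintf("invalid %s: non-ACGT character in '%s'", what, x), call. = FALSE)
  x
}

# Reverse complement of a plain character DNA string (N allowed, maps to N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

# Run expr with a temporary RNG state seeded by `seed`; restores global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# IUPAC nucleotide code -> regex character class (uppercase input).
IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(consensus, what = "motif consensus") {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_REGEX))
  if (length(bad))
    stop(sprintf("catalog-parse error: malformed IUPAC code '%s' in %s '%s'",
                 bad[[1L]], what, consensus), call. = FALSE)
  paste(IUPAC_REGEX[chars], collapse = "")
}

# Reverse complement of an IUPAC consensus string.
iupac_revcomp <- function(consensus) {
  chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]),
               collapse = ""))
}
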