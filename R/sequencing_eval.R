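#' Depth profiles
#'
#' A `depth_profile` stores the per-base sequencing depth of one individual as
#' a sparse table (positions absent from the table have depth 0) plus the
#' genome-length denominator used by all coverage fractions. The denominator
#' is supplied explicitly (e.g. from a FASTA index) rather than inferred from
#' observed positions, mirroring how coverage percentages are reported
#' against the full reference length.
#'
#' @param depths data.frame with columns `seq_id`, `pos` (1-based), `depth`.
#' @param genome_length total reference bases (> 0).
#' @param individual_id label.
#' @return A `depth_profile` object.
#' @export
depth_profile <- function(depths, genome_length, individual_id = "ind") {
  stopifnot(is.data.frame(depths),
            all(c("seq_id", "pos", "depth") %in% names(depths)))
  if (!(is.numeric(genome_length) && length(genome_length) == 1L &&
        genome_length > 0))
    stop("genome_length must be a positive number", call. = FALSE)
  if (nrow(depths)) {
    if (any(depths$depth < 0)) stop("negative depth", call. = FALSE)
    if (any(depths$pos < 1)) stop("positions must be 1-based", call. = FALSE)
    if (anyDuplicated(paste(depths$seq_id, depths$pos)))
      stop("duplicate position in depth table", call. = FALSE)
  }
  structure(list(individual_id = as.character(individual_id),
                 depths = depths[, c("seq_id", "pos", "depth")],
                 genome_length = as.numeric(genome_length)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %s, %d nonzero positions / %s reference bases\n",
              x$individual_id, sum(x$depths$depth > 0),
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Load a per-base depth table
#'
#' Reads a three-column TSV compatible with `samtools depth` output
#' (sequence name, 1-based position, depth) into a [depth_profile()].
#'
#' @param path TSV path (no header).
#' @param genome_length reference denominator in bases.
#' @param individual_id label for the profile.
#' @return A [depth_profile()].
#' @export
load_depth <- function(path, genome_length, individual_id = basename(path)) {
  if (file.size(path) == 0L) {
    df <- data.frame(seq_id = character(0), pos = integer(0),
                     depth = integer(0))
  } else {
    dt <- tryCatch(
      data.table::fread(path, header = FALSE, sep = "\t",
                        col.names = c("seq_id", "pos", "depth"),
                        colClasses = list(character = 1L)),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    df <- as.data.frame(dt)
  }
  if (nrow(df) && (anyNA(df$pos) || anyNA(df$depth)))
    stop("parse error in ", path, ": malformed row at line ",
         which(is.na(df$pos) | is.na(df$depth))[1L], call. = FALSE)
  depth_profile(df, genome_length, individual_id)
}

#' Depth-stratified coverage fractions
#'
#' For each depth threshold t, the percentage of all reference bases with
#' depth >= t. Default thresholds follow the standard stratification
#' (>=1, >=3, >=10, >=30, >=100, >=500, >=1000); the resulting fractions are
#' nonincreasing in the threshold.
#'
#' @param profile a [depth_profile()].
#' @param thresholds strictly increasing positive depth thresholds.
#' @return A `coverage_fraction_table` data.frame with columns `threshold`
#'   and `fraction` (percent of `genome_length`).
#' @export
coverage_fractions <- function(profile,
                               thresholds = c(1, 3, 10, 30, 100, 500, 1000)) {
  stopifnot(inherits(profile, "depth_profile"))
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  d <- profile$depths$depth
  frac <- vapply(thresholds, function(t) sum(d >= t), 0) /
    profile$genome_length * 100
  structure(data.frame(threshold = thresholds, fraction = frac),
            class = c("coverage_fraction_table", "data.frame"))
}

#' Read placement sets
#'
#' Retained (e.g. uniquely mapped) reads are represented by their genomic
#' placements: 0-based half-open intervals, one per read.
#'
#' @param placements data.frame with columns `seq_id`, `start`, `end`.
#' @param individual_id label.
#' @return A `read_placements` data.frame.
#' @export
read_placements <- function(placements, individual_id = "ind") {
  stopifnot(is.data.frame(placements),
            all(c("seq_id", "start", "end") %in% names(placements)))
  if (nrow(placements) && any(placements$start >= placements$end))
    stop("placements must satisfy start < end", call. = FALSE)
  structure(placements[, c("seq_id", "start", "end")],
            individual_id = as.character(individual_id),
            class = c("read_placements", "data.frame"))
}

#' Standardize a read set to a fixed size
#'
#' Uniform subsample without replacement, so samples of different total yield
#' are compared at the same read number (e.g. 6 million uniquely mapped
#' reads). Deterministic under `seed`.
#'
#' @param placements a [read_placements()] data.frame.
#' @param n subsample size (0 <= n <= number of reads).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [read_placements()] of `n` rows.
#' @export
standardize_reads <- function(placements, n, seed = NULL) {
  total <- nrow(placements)
  if (!is.numeric(n) || length(n) != 1L || n < 0L || n > total)
    stop(sprintf("invalid-parameter: n must be in [0, %d]", total),
         call. = FALSE)
  n <- as.integer(n)
  if (n == total) return(placements)
  idx <- with_seed(seed, sample.int(total, n))
  out <- placements[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "individual_id") <- attr(placements, "individual_id")
  class(out) <- class(placements)
  out
}

# Per-base depth implied by placements, as an RleList keyed by seq_id.
placements_coverage <- function(placements) {
  if (!nrow(placements)) return(NULL)
  sp <- split(placements, placements$seq_id)
  lapply(sp, function(p)
    IRanges::coverage(IRanges::IRanges(start = p$start + 1L, end = p$end)))
}

# Count positions with depth >= min_depth from placements.
covered_bases_from_placements <- function(placements, min_depth) {
  cov <- placements_coverage(placements)
  if (is.null(cov)) return(0L)
  sum(vapply(cov, function(r)
    sum(S4Vectors::runLength(r)[S4Vectors::runValue(r) >= min_depth]), 0))
}

#' Convert placements to a depth profile
#'
#' @param placements a [read_placements()] data.frame.
#' @param genome_length reference denominator.
#' @param individual_id label; defaults to the placements' own.
#' @return A [depth_profile()] with one row per covered base.
#' @export
placements_to_depth <- function(placements, genome_length,
                                individual_id = NULL) {
  if (is.null(individual_id))
    individual_id <- attr(placements, "individual_id") %||% "ind"
  cov <- placements_coverage(placements)
  rows <- list()
  for (sid in names(cov)) {
    r <- cov[[sid]]
    pos <- which(as.integer(r) > 0L)
    if (length(pos))
      rows[[sid]] <- data.frame(seq_id = sid, pos = pos,
                                depth = as.integer(r)[pos],
                                stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), pos = integer(0), depth = integer(0))
  rownames(df) <- NULL
  depth_profile(df, genome_length, individual_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Saturation curve of sufficiently sequenced bases
#'
#' For each subsample size, draws that many reads without replacement and
#' counts the bases whose implied depth reaches `min_depth` ("sufficiently
#' sequenced"). The curve is nondecreasing in the read number in expectation.
#'
#' @param placements a [read_placements()] data.frame.
#' @param subsample_sizes positive read counts, each <= total reads
#'   (e.g. 0.5, 1, 2 and 6 million in a full-scale run).
#' @param min_depth depth threshold (default 10).
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns `n_reads` and `covered_bases`.
#' @export
saturation_curve <- function(placements, subsample_sizes, min_depth = 10L,
                             seed = NULL) {
  total <- nrow(placements)
  if (any(subsample_sizes <= 0) || any(subsample_sizes > total))
    stop("invalid-parameter: subsample sizes must be in (0, total reads]",
         call. = FALSE)
  with_seed(seed, {
    covered <- vapply(subsample_sizes, function(n) {
      sub <- standardize_reads(placements, n)
      as.numeric(covered_bases_from_placements(sub, min_depth))
    }, 0)
  })
  data.frame(n_reads = as.integer(subsample_sizes), covered_bases = covered)
}

#' Bases commonly sequenced across individuals
#'
#' Size of the intersection, over all supplied individuals, of the base sets
#' with depth >= `min_depth`. This is the "no missing genotype call" base
#' count at a depth threshold.
#'
#' @param profiles list of [depth_profile()] objects sharing a reference
#'   (equal `genome_length`).
#' @param min_depth depth threshold (default 10).
#' @return Integer count of commonly covered bases.
#' @export
common_bases <- function(profiles, min_depth = 10L) {
  if (!length(profiles)) stop("invalid-parameter: no profiles", call. = FALSE)
  gl <- unique(vapply(profiles, function(p) p$genome_length, 0))
  if (length(gl) != 1L)
    stop("invalid-parameter: profiles use different references", call. = FALSE)
  intersect_keysets(depth_keysets(profiles, min_depth))
}

#' Reduction curve of commonly sequenced bases
#'
#' For each x in `n_grid`, draws `n_replicates` random subsets of x
#' individuals (without replacement) and averages [common_bases()] over the
#' subsets. Under independent per-locus dropout with retention p the
#' expectation is L * p^x (+ core), the exponential-decay form fitted by
#' [fit_reduction_model()].
#'
#' @param profiles list of [depth_profile()] objects.
#' @param n_grid individual counts to evaluate (default 1..#individuals).
#' @param n_replicates random subsets per x (default 20).
#' @param min_depth depth threshold (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `x` and `Y` (mean common bases).
#' @export
reduction_curve <- function(profiles, n_grid = seq_along(profiles),
                            n_replicates = 20L, min_depth = 10L,
                            seed = NULL) {
  m <- length(profiles)
  if (any(n_grid < 1L) || any(n_grid > m))
    stop("invalid-parameter: n_grid must lie in [1, #individuals]",
         call. = FALSE)
  if (n_replicates < 1L)
    stop("invalid-parameter: n_replicates must be >= 1", call. = FALSE)
  keysets <- depth_keysets(profiles, min_depth)
  with_seed(seed, {
    Y <- vapply(n_grid, function(x) {
      reps <- if (x == m) 1L else n_replicates
      mean(vapply(seq_len(reps), function(r) {
        idx <- if (x == m) seq_len(m) else sample.int(m, x)
        as.numeric(intersect_keysets(keysets[idx]))
      }, 0))
    }, 0)
  })
  data.frame(x = as.integer(n_grid), Y = Y)
}

# Per-profile sets of (seq, pos) keys with depth >= min_depth, encoded as
# numerics (exact below 2^53).
depth_keysets <- function(profiles, min_depth) {
  seq_ids <- unique(unlist(lapply(profiles,
                                  function(p) unique(p$depths$seq_id))))
  lapply(profiles, function(p) {
    d <- p$depths[p$depths$depth >= min_depth, , drop = FALSE]
    unique(match(d$seq_id, seq_ids) * 2^33 + d$pos)
  })
}

intersect_keysets <- function(keysets) {
  keysets <- keysets[order(lengths(keysets))]
  common <- keysets[[1L]]
  for (ks in keysets[-1L]) {
    if (!length(common)) break
    common <- common[match(common, ks, nomatch = 0L) > 0L]
  }
  length(common)
}

# Model function with analytic gradient for nls.
reduction_rhs <- function(C1, a, C2, x) {
  v <- C1 * a^x + C2
  grad <- cbind(C1 = a^x, a = C1 * x * a^(x - 1), C2 = rep(1, length(x)))
  attr(v, "gradient") <- grad
  v
}

#' Fit the common-base reduction model Y = C1 * a^x + C2
#'
#' Bounded nonlinear least squares (`nls`, algorithm "port") with analytic
#' gradient. Initialization: C2_0 = min(Y), a_0 = 0.7,
#' C1_0 = (max(Y) - C2_0) / a_0^min(x); `a` is constrained to
#' [1e-6, 1 - 1e-6] and C1, C2 to be non-negative. Non-convergence and
#' degenerate (near-constant) inputs yield a result flagged accordingly, not
#' an exception.
#'
#' @param points data.frame with columns `x` (distinct individual counts) and
#'   `Y` (common bases); at least 4 points.
#' @return A `reduction_curve_fit`: list with `C1`, `C2`, `a`, `rss`,
#'   `converged`, `degenerate`, `message` and `points`.
#' @export
fit_reduction_model <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "Y") %in% names(points)))
  points <- points[order(points$x), , drop = FALSE]
  if (nrow(points) < 4L)
    stop("invalid-parameter: need at least 4 points", call. = FALSE)
  if (anyDuplicated(points$x))
    stop("invalid-parameter: x values must be distinct", call. = FALSE)
  x <- as.numeric(points$x); Y <- as.numeric(points$Y)

  span <- max(Y) - min(Y)
  if (span <= max(1e-12, 1e-9 * max(abs(Y), 1))) {
    return(structure(list(C1 = 0, C2 = mean(Y), a = NA_real_,
                          rss = sum((Y - mean(Y))^2), converged = FALSE,
                          degenerate = TRUE,
                          message = "constant data: C1 -> 0, C2 = mean(Y)",
                          points = points),
                     class = "reduction_curve_fit"))
  }

  a0 <- 0.7
  C2_0 <- min(Y)
  C1_0 <- (max(Y) - C2_0) / a0^min(x)
  do_fit <- function(ctrl) tryCatch(
    nls(Y ~ reduction_rhs(C1, a, C2, x),
        start = list(C1 = C1_0, a = a0, C2 = C2_0),
        algorithm = "port",
        lower = c(C1 = 0, a = 1e-6, C2 = 0),
        upper = c(C1 = Inf, a = 1 - 1e-6, C2 = Inf),
        control = ctrl),
    error = function(e) e)
  # strict tolerance first (exact recovery on noiseless data); when a
  # parameter sits on a bound port can report singular convergence there,
  # so fall back to the default tolerance and accept its own verdict
  fit <- do_fit(list(maxiter = 1000L, tol = 1e-10))
  if (inherits(fit, "error"))
    fit <- do_fit(list(maxiter = 1000L, warnOnly = TRUE))
  if (inherits(fit, "error")) {
    return(structure(list(C1 = NA_real_, C2 = NA_real_, a = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          degenerate = FALSE,
                          message = conditionMessage(fit), points = points),
                     class = "reduction_curve_fit"))
  }
  cf <- coef(fit)
  at_bound <- cf[["a"]] <= 1e-6 || cf[["a"]] >= 1 - 1e-6
  structure(list(C1 = cf[["C1"]], C2 = cf[["C2"]], a = cf[["a"]],
                 rss = sum(resid(fit)^2),
                 converged = fit$convInfo$isConv && !at_bound,
                 degenerate = at_bound,
                 message = if (at_bound)
                   "decay factor at its bound (degenerate)" else
                     fit$convInfo$stopMessage,
                 points = points),
            class = "reduction_curve_fit")
}

#' @export
print.reduction_curve_fit <- function(x, ...) {
  cat("Reduction-curve fit: Y = C1 * a^x + C2\n")
  cat(sprintf("  C1 = %.6g  a = %.6g  C2 = %.6g\n", x$C1, x$a, x$C2))
  cat(sprintf("  rss = %.6g  converged = %s%s\n", x$rss, x$converged,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Predict from a reduction-curve fit
#'
#' @param object a `reduction_curve_fit`.
#' @param x individual counts to predict at; defaults to the fitted points.
#' @param ... unused.
#' @return Numeric vector of predicted common-base counts.
#' @export
predict.reduction_curve_fit <- function(object, x = object$points$x, ...) {
  object$C1 * object$a^x + object$C2
}

#' Read a genome index (FASTA .fai or two-column name/length TSV)
#'
#' @param path index path; the first two columns must be sequence name and
#'   length.
#' @return Named numeric vector of sequence lengths. `sum()` of it is the
#'   genome-length denominator.
#' @export
read_genome_index <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), df[[1L]])
}
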