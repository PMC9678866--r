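test_that("enumerate_kmers enumerates lexicographically and completely", {
  k3 <- enumerate_kmers(3)
  expect_length(k3, 64L)
  expect_identical(unclass(k3)[1L], "AAA")
  expect_identical(unclass(k3)[64L], "TTT")
  expect_false(is.unsorted(unclass(k3), strictly = TRUE))
  expect_identical(as.character(unclass(enumerate_kmers(1))),
                   c("A", "C", "G", "T"))
  for (k in 1:8) expect_length(enumerate_kmers(k), 4L^k)
  expect_error(enumerate_kmers(0), "invalid-parameter")
  expect_error(enumerate_kmers(17), "invalid-parameter")
  expect_error(enumerate_kmers(2.5), "invalid-parameter")
})

test_that("derive_short_primers prefixes and deduplicates", {
  expect_identical(as.character(derive_short_primers(
    kmer_catalog("GTCGCCCAAA"), 7)), "GTCGCCC")
  expect_identical(as.character(derive_short_primers(
    kmer_catalog(c("AAAAAAAAAA", "AAAAAAATTT")), 7)), "AAAAAAA")
  # prefix surjection: all 4^k 10-mer prefixes of length m cover all 4^m
  k4 <- enumerate_kmers(4)
  s2 <- derive_short_primers(k4, 2)
  expect_length(s2, 16L)
  expect_setequal(as.character(s2), as.character(enumerate_kmers(2)))
  expect_error(derive_short_primers(k4, 4), "invalid-parameter")
  expect_error(derive_short_primers(k4, 5), "invalid-parameter")
})

test_that("ssr_filter matches its spec examples and validates input", {
  v <- ssr_filter("ACACACACAC")
  expect_identical(v$verdict, "fail")
  expect_match(v$evidence, "unit=AC repeats=5")
  expect_identical(ssr_filter("TTTTTGTAAA")$verdict, "pass")
  v <- ssr_filter("TTTTTTGTAA")
  expect_identical(v$verdict, "fail")
  expect_match(v$evidence, "run T x6")
  expect_error(ssr_filter("ACGTN"), "invalid")
  # extra motifs are matched on either strand
  pol <- ssr_policy(extra_motifs = "GACGAC")
  expect_identical(ssr_filter("TTGACGACTT", pol)$verdict, "fail")
  expect_identical(ssr_filter("TTGTCGTCTT", pol)$verdict, "fail")  # revcomp
  expect_identical(ssr_filter("TTGACGTCTT", pol)$verdict, "pass")
})

test_that("ssr_filter agrees with the brute-force oracle on all 5-mers and random 10-mers", {
  pol <- ssr_policy()
  for (s in as.character(enumerate_kmers(5))) {
    expect_identical(ssr_filter(s, pol)$verdict == "fail",
                     oracle_ssr_fails(s), info = s)
  }
  set.seed(11)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
    expect_identical(ssr_filter(s, pol)$verdict == "fail",
                     oracle_ssr_fails(s), info = s)
  }
})

test_that("motif_filter honors IUPAC degeneracy and strands", {
  cat1 <- motif_catalog("TBP", "TATAA")
  expect_match(motif_filter("GGTATAAGGG", cat1)$evidence, "TBP at 2")
  expect_identical(motif_filter("GGGGGGGGGG", cat1)$verdict, "pass")
  expect_identical(motif_filter("GGTTATAGGG", cat1)$verdict, "fail")
  # single-strand catalog does not see the reverse complement
  cat_f <- motif_catalog("TBP", "TATAA", scan_both_strands = FALSE)
  expect_identical(motif_filter("GGTTATAGGG", cat_f)$verdict, "pass")
  # degenerate code
  cat2 <- motif_catalog("deg", "TRTAA")
  expect_identical(motif_filter("GGTGTAAGGG", cat2)$verdict, "fail")
  expect_identical(motif_filter("GGTCTAAGGG", cat2)$verdict, "pass")
  # motifs longer than the sequence are skipped
  cat3 <- motif_catalog("long", strrep("A", 20))
  expect_identical(motif_filter("AAAAA", cat3)$verdict, "pass")
  expect_error(motif_catalog("bad", "TAZAA"), "IUPAC")
})

test_that("motif_filter agrees with the expansion oracle on all 5-mers", {
  cat_ <- motif_catalog(c("m1", "m2"), c("TAR", "CGCG"))
  for (s in as.character(enumerate_kmers(5))) {
    expect_identical(motif_filter(s, cat_)$verdict == "fail",
                     oracle_motif_fails(s, c("TAR", "CGCG")), info = s)
  }
})

test_that("grade_of applies the stated boundary convention", {
  b <- grade_boundaries()
  expect_identical(grade_of(99, b), "LOW")
  expect_identical(grade_of(100, b), "MID")
  expect_identical(grade_of(1000, b), "MID")
  expect_identical(grade_of(1001, b), "HIGH")
  expect_identical(grade_of(0, b), "LOW")
  # the three grades partition the non-negative integers
  counts <- 0:2000
  g <- grade_of(counts, b)
  expect_true(all(g %in% c("LOW", "MID", "HIGH")))
  expect_identical(sum(g == "LOW") + sum(g == "MID") + sum(g == "HIGH"),
                   length(counts))
  expect_error(grade_of(-1, b), "non-negative")
  expect_error(grade_boundaries(1000, 100))
})

test_that("concordance_filter uses a strict more-than threshold", {
  g14 <- c(rep("MID", 14), "LOW", "HIGH", "LOW")
  expect_identical(concordance_filter(g14)$verdict, "keep")
  g13 <- c(rep("MID", 13), rep("LOW", 2), rep("HIGH", 2))
  expect_identical(concordance_filter(g13)$verdict, "drop")
  expect_identical(concordance_filter(rep("LOW", 5))$verdict, "keep")
  cf <- concordance_filter(g14)
  expect_identical(cf$modal_grade, "MID")
  expect_identical(cf$modal_count, 14L)
  expect_error(concordance_filter(character(0)), "invalid-parameter")
  expect_error(concordance_filter(g14, threshold = 1), "invalid-parameter")
})

test_that("self_complementarity_filter spec examples and published targets", {
  expect_identical(self_complementarity_filter("GAATTC")$verdict, "fail")
  pol0 <- self_comp_policy(adapter_forward = "A", adapter_reverse = "A",
                           spacer_len = 0)
  expect_identical(self_complementarity_filter("AAAAAAA", pol0)$verdict,
                   "pass")
  v <- self_complementarity_filter("AAACGTCG")
  expect_identical(v$verdict, "fail")
  expect_match(v$evidence, "3'-end")
  for (t in c("GTCGCCC", "TTTGATC", "TTTATGT", "TTTTTGT"))
    expect_identical(self_complementarity_filter(t)$verdict, "pass",
                     info = t)
})

test_that("self_complementarity_filter agrees with the pairwise-window oracle on all 5-mers", {
  pol <- self_comp_policy()
  for (s in as.character(enumerate_kmers(5))) {
    expect_identical(self_complementarity_filter(s, pol)$verdict == "fail",
                     oracle_selfcomp_fails(s), info = s)
  }
})

test_that("pairwise cocktail scope catches cross-primer complementarity", {
  pol <- self_comp_policy(scope = "pairwise_cocktail")
  # GGGGGGG is clean alone but a CCC window elsewhere in the cocktail pairs
  expect_identical(self_complementarity_filter("GGGGGGG", pol)$verdict,
                   "pass")
  expect_identical(
    self_complementarity_filter("GGGGGGG", pol,
                                cocktail_context = "TTCCCTT")$verdict,
    "fail")
})

test_that("per-sequence filters are idempotent and order-invariant", {
  pol <- ssr_policy()
  cat_ <- motif_catalog("m", "TATAA")
  scp <- self_comp_policy()
  kmers <- as.character(enumerate_kmers(4))
  pass1 <- list(
    ssr = vapply(kmers, function(s) ssr_filter(s, pol)$verdict, ""),
    motif = vapply(kmers, function(s) motif_filter(s, cat_)$verdict, ""),
    sc = vapply(kmers, function(s)
      self_complementarity_filter(s, scp)$verdict, ""))
  surv_any_order <- function(ord) {
    keep <- rep(TRUE, length(kmers))
    for (f in ord) keep <- keep & pass1[[f]] == "pass"
    kmers[keep]
  }
  ref <- surv_any_order(c("ssr", "motif", "sc"))
  expect_identical(surv_any_order(c("sc", "ssr", "motif")), ref)
  expect_identical(surv_any_order(c("motif", "sc", "ssr")), ref)
  # idempotence: filtering the survivors changes nothing
  again <- vapply(ref, function(s) ssr_filter(s, pol)$verdict == "pass" &&
                    motif_filter(s, cat_)$verdict == "pass" &&
                    self_complementarity_filter(s, scp)$verdict == "pass",
                  TRUE)
  expect_true(all(again))
})

test_that("run_design_pipeline equals the brute-force filter intersection", {
  des <- run_design_pipeline(4, ssr = ssr_policy(), motifs = NULL,
                             profiles = NULL, selfcomp = NULL)
  manual <- Filter(function(s) !oracle_ssr_fails(s),
                   as.character(enumerate_kmers(4)))
  expect_identical(as.character(des$survivors), manual)
  # empty motif catalog passes everything; single profile keeps all
  prof <- stratify(count_kmers(c(chr = strrep("ACGT", 50)), 4))
  des2 <- run_design_pipeline(4, ssr = NULL, motifs = NULL,
                              profiles = list(prof), selfcomp = NULL)
  expect_true(all(des2$candidates$surviving))
  # full cascade records one verdict column per filter plus evidence
  des3 <- run_design_pipeline(4, motifs = motif_catalog("m", "TATA"),
                              profiles = list(prof), short_k = 2)
  expect_true(all(c("ssr", "motif", "concordance", "selfcomp",
                    "surviving") %in% names(des3$candidates)))
  fails <- des3$candidates$ssr == "fail"
  expect_true(all(!is.na(des3$candidates$ssr_evidence[fails])))
  expect_true(all(nchar(as.character(des3$short_primers)) == 2L))
})

test_that("candidate TSV round-trips through write_candidates", {
  des <- run_design_pipeline(3, short_k = 2)
  tsv <- tempfile(fileext = ".tsv")
  write_candidates(des, tsv)
  back <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(des$candidates))
  expect_identical(back$target, des$candidates$target)
  expect_identical(back$surviving, des$candidates$surviving)
})
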