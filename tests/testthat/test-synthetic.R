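test_that("simulate_genome honors GC, seed determinism and plant placement", {
  g <- simulate_genome(10000, gc = 0.5, seed = 1)
  gc_frac <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.5), 3 * sqrt(0.25 / 10000))
  g2 <- simulate_genome(10000, gc = 0.5, seed = 1)
  expect_identical(g$sequence, g2$sequence)
  g3 <- simulate_genome(10000, gc = 0.5, seed = 2)
  expect_false(identical(g$sequence, g3$sequence))
  # planted site is recovered by the site finder
  gp <- simulate_genome(5000, seed = 4,
                        plants = list(list(seq = "GTCGCCC", pos = 1000)))
  expect_identical(substr(gp$sequence, 1001, 1007), "GTCGCCC")
  ck <- cocktail_spec(primer_construct("p", target = "GTCGCCC"))
  sites <- find_priming_sites(gp, ck)
  expect_true(any(sites$start == 1000 & sites$strand == "+"))
  # skewed GC
  g4 <- simulate_genome(10000, gc = 0.8, seed = 5)
  gc4 <- mean(strsplit(g4$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc4 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_error(simulate_genome(100, plants = list(
    list(seq = "AAAA", pos = 98))), "bounds")
  expect_error(simulate_genome(100, plants = list(
    list(seq = "AAAA", pos = 10), list(seq = "CCCC", pos = 12))),
    "overlapping")
})

test_that("plant_amplicon_pair closes the loop with amplicon prediction", {
  ck <- default_cocktail()
  g <- simulate_genome(20000, gc = 0.3, seed = 8)
  g <- plant_amplicon_pair(g, "GTCGCCC", "TTTGATC", start = 2000,
                           product_len = 800,
                           forward_name = "7mer-S3-f",
                           reverse_name = "7mer-M3-f")
  tt <- truth_table(g)
  expect_identical(nrow(tt), 1L)
  expect_identical(tt$end - tt$start, 800L)
  # the planted product is predicted (chance sites may add others)
  amp <- predict_amplicons(find_priming_sites(g, ck), ck)
  expect_true(any(amp$start == 2000 & amp$end == 2800 & amp$length == 800))
  # oversized product is planted but not predicted
  g2 <- simulate_genome(20000, gc = 0.3, seed = 9)
  g2 <- plant_amplicon_pair(g2, "GTCGCCC", "TTTGATC", 1000, 2500)
  ck1 <- cocktail_spec(list(primer_construct("f", target = "GTCGCCC"),
                            primer_construct("r", target = "TTTGATC")))
  amp2 <- predict_amplicons(find_priming_sites(g2, ck1), ck1)
  expect_false(any(amp2$length == 2500))
  # two non-overlapping pairs -> two truth rows
  g3 <- simulate_genome(20000, gc = 0.3, seed = 10)
  g3 <- plant_amplicon_pair(g3, "GTCGCCC", "TTTGATC", 1000, 600)
  g3 <- plant_amplicon_pair(g3, "TTTATGT", "TTTTTGT", 5000, 700)
  expect_identical(nrow(truth_table(g3)), 2L)
  # collision detection
  expect_error(plant_amplicon_pair(g3, "GTCGCCC", "TTTGATC", 1003, 600),
               "collision")
})

test_that("simulate_maas_dataset yields a genome whose prediction equals truth", {
  for (seed in c(2, 31)) {
    sim <- simulate_maas_dataset(genome_length = 80000, n_amplicons = 15,
                                 seed = seed)
    tt <- truth_table(sim$genome)
    amp <- predict_amplicons(find_priming_sites(sim$genome, sim$cocktail),
                             sim$cocktail)
    expect_identical(nrow(amp), nrow(tt))
    o <- order(tt$start)
    expect_identical(amp$start, tt$start[o])
    expect_identical(amp$end, tt$end[o])
    expect_identical(amp$forward_primer, tt$forward_primer[o])
    expect_identical(amp$reverse_primer, tt$reverse_primer[o])
    sm <- amplicon_summary(amp)
    expect_identical(sm$total, nrow(tt))
  }
})

test_that("simulate_reads conserves counts and reflects the bias model", {
  sim <- simulate_maas_dataset(genome_length = 30000, n_amplicons = 2,
                               seed = 12)
  tt <- truth_table(sim$genome)
  # unbiased: per-amplicon counts within 4 multinomial SD of n/2
  reads <- simulate_reads(tt, 10000, bias_sdlog = 0, seed = 1)
  alloc <- attr(reads, "allocation")
  expect_identical(sum(alloc), 10000L)
  expect_identical(nrow(reads), 10000L)
  expect_true(all(abs(alloc - 5000) < 4 * sqrt(10000 * 0.25)))
  # zero reads
  r0 <- simulate_reads(tt, 0)
  expect_identical(nrow(r0), 0L)
  # determinism
  expect_identical(simulate_reads(tt, 500, bias_sdlog = 1, seed = 7),
                   simulate_reads(tt, 500, bias_sdlog = 1, seed = 7))
  # read_len guard
  expect_error(simulate_reads(tt, 10, read_len = 10000), "read_len")
  # placements sit at amplicon ends
  r <- simulate_reads(tt, 200, seed = 3)
  ok <- mapply(function(s, e, a)
    (s == tt$start[a] && e == tt$start[a] + 150) ||
    (e == tt$end[a] && s == tt$end[a] - 150),
    r$start, r$end, r$amplicon)
  expect_true(all(ok))
})

test_that("heavy-tailed bias concentrates reads on the top amplicon", {
  sim <- simulate_maas_dataset(genome_length = 80000, n_amplicons = 10,
                               seed = 14)
  tt <- truth_table(sim$genome)
  unbiased_share <- 1 / nrow(tt)
  hits <- vapply(1:50, function(s) {
    r <- simulate_reads(tt, 5000, bias_sdlog = 2, seed = s)
    max(attr(r, "allocation")) / 5000 > unbiased_share
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # and bias increases the top share relative to the unbiased regime
  top_share <- function(sdlog) mean(vapply(1:20, function(s)
    max(attr(simulate_reads(tt, 5000, bias_sdlog = sdlog, seed = s),
             "allocation")) / 5000, 0))
  expect_gt(top_share(2), top_share(0))
})

test_that("simulate_cohort realizes independent dropout with a retained core", {
  sim <- simulate_maas_dataset(genome_length = 50000, n_amplicons = 10,
                               seed = 16)
  tt <- truth_table(sim$genome)
  L <- sum(tt$end - tt$start)
  # p = 1: common bases constant in x, fit flags degenerate
  coh1 <- simulate_cohort(tt, 6, retention = 1, seed = 2)
  sizes <- vapply(1:6, function(x) common_bases(coh1[seq_len(x)], 10), 0L)
  expect_identical(unique(sizes), L)
  fit1 <- fit_reduction_model(data.frame(x = 1:6, Y = as.numeric(sizes)))
  expect_true(fit1$degenerate)
  # core bases always retained
  coh2 <- simulate_cohort(tt, 8, retention = 0.5, core_bases = 1000,
                          seed = 3)
  expect_gte(common_bases(coh2, 10), 1000L)
  core_pos <- coh2[[1]]$depths$seq_id == "core"
  expect_identical(sum(core_pos), 1000L)
  # determinism
  coh3 <- simulate_cohort(tt, 4, retention = 0.7, seed = 5)
  coh4 <- simulate_cohort(tt, 4, retention = 0.7, seed = 5)
  expect_identical(lapply(coh3, `[[`, "depths"),
                   lapply(coh4, `[[`, "depths"))
})

test_that("cohort parameter recovery: fitted a tracks the simulated retention", {
  sim <- simulate_maas_dataset(genome_length = 100000, n_amplicons = 20,
                               seed = 7)
  tt <- truth_table(sim$genome)
  # a single cohort here (the full 20-cohort sweep runs in the acceptance
  # suite); the fitted decay must sit near the simulated retention
  coh <- simulate_cohort(tt, 30, retention = 0.71, seed = 101)
  rc <- reduction_curve(coh, n_replicates = 10, seed = 201)
  fit <- fit_reduction_model(rc)
  expect_lt(abs(fit$a - 0.71), 0.05)
  # core recovery: fitted C2 within 10% of the planted core
  coh_core <- simulate_cohort(tt, 30, retention = 0.71, core_bases = 5000,
                              seed = 42)
  fit_core <- fit_reduction_model(reduction_curve(coh_core,
                                                  n_replicates = 20,
                                                  seed = 43))
  expect_lt(abs(fit_core$C2 - 5000) / 5000, 0.10)
})

test_that("synthetic outputs serialize to plain-text formats", {
  sim <- simulate_maas_dataset(genome_length = 20000, n_amplicons = 3,
                               seed = 19)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(sim$genome, fa)
  back <- count_kmers(fa, 7)
  direct <- count_kmers(sim$genome, 7)
  expect_identical(back$counts, direct$counts)
  reads <- simulate_reads(truth_table(sim$genome), 100, seed = 1)
  bed <- tempfile(fileext = ".bed")
  write_placements_bed(reads, bed)
  expect_identical(nrow(read.table(bed)), 100L)
  dp <- placements_to_depth(reads, 20000)
  tsv <- tempfile(fileext = ".tsv")
  write_depth(dp, tsv)
  round_trip <- load_depth(tsv, 20000)
  expect_identical(round_trip$depths$depth, dp$depths$depth)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(sim$genome, reads[1:5, ], fq)
  lines <- readLines(fq)
  expect_identical(length(lines), 20L)
  expect_true(all(startsWith(lines[seq(1, 20, 4)], "@")))
  expect_identical(unique(nchar(lines[seq(2, 20, 4)])), 150L)
})
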