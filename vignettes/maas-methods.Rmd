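---
title: "Arbitrary amplicon primer design and efficiency evaluation: models and choices"
author: "maasr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrary amplicon primer design and efficiency evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maasr)
```

## The problem

Multiple arbitrary amplicon sequencing (MAAS) genotypes individuals from the
pooled PCR products of a small cocktail of short arbitrary primers. Each
primer's 3' priming portion (the *target*, 3–10 bases) matches the genome at
many positions; every pair of a forward-oriented and a downstream
reverse-oriented site within the amplifiable size range yields a product. Two
failure modes dominate genotyping efficiency:

* **amplification bias** — unequal per-product efficiency lets a few
  amplicons soak up most reads, so most loci stay under the calling depth;
* **locus dropout** — a locus missing in even one individual is lost for
  cohort-wide analyses, so the number of commonly genotyped bases decays
  with cohort size.

`maasr` implements the primer-design cascade that minimises the first and the
evaluation statistics that quantify both.

## The design cascade

Candidates are all `4^k` k-mers (`enumerate_kmers`). Filters are pure
predicates on the candidate (plus per-species genome profiles for the
concordance step), so applying any of them twice equals applying it once and
the surviving set does not depend on their order; the canonical order is the
cheapest-first one used by `run_design_pipeline`.

### SSR filter

"Simple sequence repeat" is operationalised as: a mononucleotide run longer
than `max_mono_run = 5`; a tandem repeat of a *primitive* unit (one that is
not itself a repetition of a shorter unit) of length 2, 3 or 4 with at least
3, 3 or 2 copies respectively; or any explicitly supplied repeat motif (e.g.
the ISSR units exploited by MIG-seq primers) as a substring of either strand.
The mono-run bound of 5 is the loosest value under which a T₅-containing
published 7-mer target (`TTTTTGT`) survives while canonical
di-/tri-nucleotide microsatellite units are still rejected; the unit
thresholds are the shortest repeats a primer of design length 10 can
physically contain more than once. All thresholds are configurable
(`ssr_policy`).

### Motif filter

Functional motifs (transcription-factor binding sites and similar) are
matched as IUPAC consensus substrings on both strands; motifs longer than the
candidate are skipped. When a catalog arrives as position-frequency matrices
(JASPAR flat format, `read_motifs_jaspar`), a consensus is derived per column
as the IUPAC merge of all bases reaching 25% of the column total — the
conventional cutoff for consensus derivation. Whether the original screen
used consensus matching or PWM-threshold scanning is not knowable from the
outside; consensus matching was chosen as the default because it is
deterministic, parameter-free and conservative (every PWM hit above a
sensible threshold contains the consensus core). PWMs are retained in the
catalog object so a score-based scan can be added without changing the
interface.

### Frequency grades and cross-taxon concordance

Per-species occurrence counts of every k-mer (forward strand, overlapping
windows, ambiguity-containing windows skipped — `count_kmers`, backed by
`Biostrings::oligonucleotideFrequency`, the same counting primitive the
original workflow used) are stratified into LOW (< 10²), MID (10²–10³) and
HIGH (> 10³). Boundary counts of exactly 100 or 1000 are assigned to MID so
the three grades partition the non-negative integers. A candidate is kept
when one grade is shared by *strictly more than* 80% of species: with 17
species this admits 14 concordant species and rejects 13, the only reading
consistent with "more than 80% (14/17)" since 13/17 ≈ 0.765 < 0.8 < 14/17.
K-mers absent from a species count as LOW (count 0) there. Only the forward
strand is counted by default (the deposited-strand convention of the counting
function); a `both_strands` option exists.

### Self-complementarity screen

The published rule — "self-complementation of two bases at the 3' end or
every three continuous bases", taking the Illumina adapters into account —
is ambiguous about *where* the complementary partner may sit. A literal
"window's reverse complement anywhere in the full adapter+target construct"
reading is self-refuting: it rejects all four published 7-mer targets (e.g.
`TTTGATC` contains the 4-base palindrome `GATC`, whose halves `GAT`/`ATC`
are mutually reverse-complementary windows; the constant adapter contains
`CGA`, the reverse complement of the frequent target window `TCG`). Since
those primers demonstrably survived the original screen, the package adopts
the physically motivated reading under which they do:

* **3'-end seed rule** — a primer dimer extends when two 3' ends anneal;
  a construct fails when its 3'-terminal dinucleotide is the reverse
  complement of the 3'-terminal dinucleotide of an evaluated partner. Under
  the default `self_only` scope the partner is the construct itself, so the
  rule rejects exactly the palindromic terminal dinucleotides AT, TA, GC,
  CG.
* **window rule** — a hairpin or self-dimer needs two *distinct*
  complementary segments; a target fails when a `window_check_len = 3`
  window's reverse complement occurs at a non-overlapping position of the
  same target. Under `pairwise_cocktail` scope the window is also searched
  against every other construct of the cocktail (adapter included; spacer
  N bases never pair), which is where the adapters and cross-primer dimers
  enter.

All worked examples of the rule's intended behaviour (palindromes fail; an
all-A target passes; a target ending in the self-complementary dinucleotide
CG fails) hold under this reading, and the four published targets pass.

### Short-primer derivation

m-mers are the deduplicated first `m` bases of the surviving k-mers
(`derive_short_primers`), mirroring how 7-mer primers were produced from
selected 10-mers by removing three 3' bases.

## In-silico PCR

`find_priming_sites` reports every exact (or ≤ `max_mismatch` substitutions;
no indels — the annealing of a 7-base 3' end tolerates substitutions, not
gaps) occurrence of each target on the + strand and each reverse complement
on the − strand, overlaps included. `predict_amplicons` enumerates every
(+ site, − site) pair on the same sequence whose product — measured 5' end
to 5' end, both priming sites included, which is the fragment a sequencer
reads after two-step PCR — lies within `[min_len, max_len]`. All qualifying
pairs are emitted; PCR competition between overlapping products is
deliberately *not* modelled here but delegated to the read simulator's
efficiency weights, so prediction stays a deterministic geometry question.
Coordinates are 0-based half-open throughout (BED convention). The default
size window 500–2000 bp is the smear window used to select cocktails on
gels; the tighter 600–1000 bp library (bead-selection) window is available
as a preset.

## Efficiency indicators

* `coverage_fractions` — per-threshold percentages of the full reference
  length (denominator supplied explicitly, e.g. from a FASTA index, never
  inferred from observed positions). Thresholds default to
  1, 3, 10, 30, 100, 500, 1000.
* `standardize_reads` / `saturation_curve` — uniform subsampling without
  replacement; covered bases are counted at depth ≥ `min_depth`. The
  published text says both "depths of more than 10" and "depth ≥ 10"; the
  package standardises on **≥** `min_depth` (default 10) everywhere.
* `common_bases` — the intersection across individuals of base sets at
  depth ≥ `min_depth`.
* `reduction_curve` — for each cohort size x, the mean of `common_bases`
  over `n_replicates = 20` independent random x-subsets drawn without
  replacement (the original averaging scheme — orderings vs independent
  subsets — is unstated; independent subsets give the unbiased mean at each
  x and are the default).

## The reduction model and its fit

`fit_reduction_model` fits `Y = C1·a^x + C2` by bounded Gauss–Newton
(`nls`, algorithm "port") with the analytic Jacobian
`(a^x, C1·x·a^(x−1), 1)`; bounds `C1 ≥ 0`, `C2 ≥ 0`,
`a ∈ [1e−6, 1−1e−6]`; initial values `C2₀ = min Y`, `a₀ = 0.7`,
`C1₀ = (max Y − C2₀)/a₀^min(x)`. A strict parameter tolerance (1e−10) is
tried first — on noiseless model data this recovers all three constants to
better than 1e−6 relative error, the correctness gate for the wrapper — and,
because the port algorithm reports "singular convergence" rather than
success when a parameter sits exactly on an active bound (typically C2 = 0),
a second attempt at the default tolerance accepts the solver's own verdict.
Constant input is detected up front and returned as a degenerate result
(C1 = 0, C2 = mean Y, no exception), as is a fit whose decay lands on a
bound.

## What the synthetic data does and does not establish

`simulate_genome` draws i.i.d. bases at a stated GC fraction (default 0.5;
the worked examples use 0.3–0.42, the range typical of AT-rich vertebrate
genomes) and overwrites planted features. `simulate_maas_dataset`
additionally spaces planted products so no cross-pair product can fall in
the size window and point-mutates every chance occurrence of a cocktail
target, making the truth table *exactly* the predictable amplicon set — a
deliberately clean world for closed-loop testing.

`simulate_reads` draws per-amplicon efficiencies log-normally
(`bias_sdlog`; 0 = unbiased, ≥ 2 = the heavy-tailed regime where one product
dominates, qualitatively the ISSR-primer situation) and allocates reads
multinomially, conserving counts exactly. The log-normal was chosen because
PCR efficiency differences compound multiplicatively over cycles; the
original work describes bias only qualitatively, so `bias_sdlog` is exposed
rather than fixed.

`simulate_cohort` drops each locus independently per individual with
retention probability p (default in examples 0.71, matching the published
decay factor), giving the closed form `E[Y(x)] = L·p^x + core` — so
parameter recovery (fitted a within 0.05 of p over 20 seeded cohorts of 30
individuals; fitted C2 within 10% of a planted core) is a sharp test of the
whole curve-then-fit pipeline. Real cohorts violate the independence
assumption (shared library-prep batches, mappability), so a green recovery
test validates the estimator under the stated model, not the model itself.
Correlated dropout is outside the closed-form machinery on purpose.

Neither generator models sequencing error, quality scores, mapping ambiguity
or polymorphism; variant calling is out of scope, and published full-scale
figures that require the original reads (genome-wide coverage percentages,
absolute common-base counts) are not reproduced at desk scale.

## Numerical and interface conventions

* Sequences are validated uppercase A/C/G/T; anything else raises an error
  rather than being skipped silently.
* All stochastic operations take a `seed` and are bit-reproducible; the
  caller's RNG state is saved and restored.
* `count_kmers` keeps only nonzero counts (absent ⇒ LOW); profile TSVs are
  sorted and carry their metadata in `#` headers, so serialisation is
  byte-stable.
* Common-base intersection encodes (sequence, position) as numerics below
  2^53, exact for any realistic genome, and intersects smallest-set-first
  with early exit.
* In `concordance_filter`, modal-grade ties take the maximum count (the
  verdict is unaffected; the reported modal grade is the alphabetically
  first of the tied maxima).

## Known limitations

* No thermodynamic (nearest-neighbour ΔG, melting temperature) dimer or
  annealing model: the screen is purely string-based, as the original rule
  is.
* Exact-match site finding ignores mismatch-tolerant arbitrary priming at
  low annealing temperature beyond the optional substitution budget.
* `enumerate_kmers` materialises the catalog; k ≤ 12 is practical in
  memory, though the contract admits k ≤ 16.
* The evaluation layer ingests depth tables and read placements; it does
  not map reads or call variants, by design.
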