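Package: maasr
Title: Arbitrary Amplicon Primer Design and Genotyping Efficiency Evaluation
Version: 0.1.0
Authors@R: person("maasr", "developers", role = c("aut", "cre"),
    email = "maasr@example.org")
Description: Tools for multiple arbitrary amplicon sequencing (MAAS), a
    reduced-representation genotyping-by-sequencing strategy that amplifies
    many loci with short (3-10 base) arbitrary primers. Provides the full
    primer-design cascade (exhaustive k-mer enumeration; simple-sequence-repeat,
    functional-motif, cross-taxon frequency-concordance and
    self-complementarity filters; short-primer derivation), genome k-mer
    frequency grade profiles, exact-match in-silico PCR amplicon prediction,
    sequencing-efficiency indicators (depth-stratified coverage fractions,
    read standardization, saturation curves, common-base intersection across
    individuals, and the exponential reduction-curve model Y = C1 * a^x + C2
    fitted by bounded nonlinear least squares), and seeded synthetic-data
    generators (genomes with planted priming sites, amplification-biased read
    sets, multi-individual cohorts with per-locus dropout) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
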