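Package: comphet
Title: Compound Heterozygosity, Enrichment and Segregation Analysis for
    Rare-Variant Cohorts
Version: 0.1.0
Authors@R:
    person("comphet", "maintainers", email = "maintainers@comphet.dev",
           role = c("aut", "cre"))
Description: Tools for isoform-aware protein consequence annotation of
    single-nucleotide variants, detection of compound heterozygotes in
    trans from phased population genotypes or parent-proband trios,
    individual-level case/control enrichment statistics (two-sided Fisher
    exact test, chi-square with Yates continuity correction, rounded
    frequency ratios), Mendelian segregation expectation and depletion
    tests for intercross litters, and per-column conservation scoring of
    protein multiple sequence alignments with projection of per-residue
    scores into PDB B-factor fields. Includes a synthetic-cohort
    generator (phased populations, trios, enriched case/control cohorts,
    intercross litters with per-genotype viability) so that every stage
    of the pipeline is testable with known ground truth and no external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
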