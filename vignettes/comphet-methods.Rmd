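---
title: "Methods: compound-het detection, enrichment and segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound-het detection, enrichment and segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comphet)
```

## Scope and model

This package operationalizes a recurring rare-variant study design: a
gene carries several common-ish missense polymorphisms that are
individually benign, and the hypothesis is that *combinations in trans*
(compound heterozygotes, both gene copies hit) are enriched in a disease
cohort. The motivating gene is the necroptosis pseudokinase MLKL, whose
brace region harbors three such variants — one of them coding only on a
short splice isoform — but nothing in the machinery is MLKL-specific.

The analysis decomposes into: isoform-aware consequence annotation of
SNVs; phase resolution of variant pairs; individual-level case/control
statistics; Mendelian segregation tests for the companion mouse
intercross data; and MSA conservation scoring. A synthetic-cohort
generator supplies every input with known ground truth.

## Phase resolution

Two variants in one individual are classified `trans`, `cis`,
`ambiguous`, `mendelian_error` or `unknown`, with the evidence recorded:

1. **hom_trans**: homozygous-alt at one site plus any carrier genotype at
   a second site is called trans — diploidy places one alt on each
   haplotype. The underlying data conventions here are genuinely
   unstated in the wild (population panels differ in whether such
   individuals are tallied as compound hets), so every count is emitted
   both with and without hom_trans-only individuals.
2. **population_phase**: both calls phased (`|` separator, taken at face
   value from the input; no re-phasing occurs anywhere): compare the
   haplotype columns.
3. **trio**: exhaustive enumeration of the ≤ 4 assignments of the
   proband's alleles to parental gametes, keeping those where each
   transmitted allele is carried by (or unconstrained for) the
   corresponding parent. All consistent assignments trans → `trans`; all
   cis → `cis`; both → `ambiguous`; none → `mendelian_error` (covers de
   novo alleles, which are never phased). A missing parental genotype is
   a wildcard, which is why e.g. an unavailable father plus a mother who
   is ref-hom at only one of the two sites still yields `ambiguous`.

Counting is strictly per individual. The denominator `n` counts
individuals with a complete (non-missing) genotype across the variant
set; `ambiguous` individuals remain in the denominator and never enter
the numerator. This is the conservative reading of individual-level
counting; it can only understate enrichment.

## Enrichment statistics

* **Fisher, two-sided**, "sum of tables at most as probable": the
  hypergeometric support with fixed margins is enumerated and point
  probabilities `≤ p_obs · (1 + 1e−7)` are summed, in log space via
  `lchoose`. The relative tolerance is the dominant software convention
  and reproduces the printed 0.001 / 0.074 values. Degenerate margins
  give p = 1. Tests hold the implementation to an independent
  enumeration oracle (`dhyper` route) to 1e−10 over every table with
  N ≤ 40.
* **Yates chi-square**: `N(max(|ad−bc|−N/2, 0))²/(R₁R₂C₁C₂)` with a 1-df
  upper tail. The clamp prevents under-correction; a zero margin is an
  error, deliberately distinct from p = 1. On the headline global table
  this test gives p = 2.6×10⁻⁶ where the source tabulation prints
  "0.0001" — treated as a reporting floor and asserted only as an upper
  bound.
* **Frequency ratio**: `(a/(a+b))/(c/(c+d))`, displayed rounded half
  away from zero as `k:1`. No printed ratio sits at .5, so the tie rule
  is unconstrained by any reference value; it is simply declared.
  Stored values keep full precision; labels are formatting only.
* No multiple-testing correction anywhere: the comparisons are reported
  individually, as in the source design.

## Segregation

Expected intercross counts are `total·r_i/Σr`; the *display* rounding is
half-to-even (R's `round`). That rule is pinned by internal consistency
of the reference litter table: the printed cells include 22.5→22,
4.5→4, 18.5→18, 3.5→4 and 15.5→16, which are simultaneously consistent
only with half-to-even. All 27 cells are regression-tested.

Depletion of a genotype class (recessive lethality) is tested two ways:
the exact binomial lower tail `P(X ≤ k)`, `X ~ Bin(n, p₀)`, and a
two-class chi-square. The category structure behind the source's
linkage-scan p-value is unrecoverable (its df are unstated), so that
number is explicitly not a target; both tests are provided and the
choice is left to the analyst.

## Conservation

Column information `R = log2 20 − H` with `H` the Shannon entropy of the
amino-acid frequencies. Gaps **and** the ambiguity letter X are excluded
from normalization; coverage (fraction of sequences with a standard
residue) is reported alongside rather than folded into the score.
Rationale: distributing X uniformly adds noise with no information, and
the standard logo convention scores the observed residues. Two optional
flags: the small-sample correction `e_n = 19/(2·ln2·n)` (negligible at
the ~257-sequence scale the defaults anticipate, hence off by default)
and a gap penalty that multiplies R by coverage. All-gap columns score 0
with coverage 0 — flagged, not an error. Logo heights are `p·R` and
partition R exactly; scores are clamped to `[0, log2 20]`.

Projection into a structure file edits bytes 61–66 of ATOM/HETATM
records in place and proves byte-identity everywhere else; this is why
the PDB handling does not round-trip through a structure object.

## Synthetic cohorts: the stated world

The generator is the package's ground-truth instrument, not a tuning
knob:

* A **haplotype pool** with explicit frequencies (LD only through those
  frequencies; no r² parameterization, no recombination). Individuals
  are two independent draws; trio children inherit one complete
  haplotype per parent. Sites default to the biallelic, two-to-three
  site scale of the motivating study.
* **Enrichment by rejection sampling**: compound-het draws accepted at
  ρ-fold the rate of others, so the target relative frequency is exact,
  not asymptotic. ρ = 1 reduces to i.i.d. draws — which is why the
  type-I-error property is simulated at the count level: cohort
  compound-het counts under ρ = 1 are *exactly* Binomial(n, q) with q
  the pool's enumerable compound-het probability, so sampling counts is
  distributionally identical to simulating full cohorts and keeps 10⁴
  replicates inside the test-suite budget.
* **Genotype error** (trios) replaces a call with a uniform random
  genotype at the configured rate — a crude model whose only job is to
  produce detectable Mendelian inconsistencies.
* Every emitted file carries its seed in the header; identical seeds
  give byte-identical files.

What a green test establishes: the classifier, counters and statistics
are correct *on the generative model above*. What it does not establish:
robustness to real-data features the model omits — genotyping batch
effects, population stratification within a cohort, linkage to untyped
variants, statistical-phasing switch errors in the "population-phased"
panel (phase flags are trusted as given).

## Numerical and boundary choices

* Fisher pmf comparisons use a `1 + 1e−7` relative tolerance; the
  oracle-equivalence tolerance is 1e−10 absolute.
* The Yates statistic is computed in doubles end to end (the
  cross-product `R₁R₂C₁C₂` overflows 32-bit integers at panel scale).
* VCF positions are 1-based at the boundary; internal interval
  arithmetic is 0-based half-open. Multi-allelic records are kept
  unsplit and addressed by (record, alt index). A `.` in either GT slot
  makes the whole call missing; the phase flag comes from the separator
  and nothing else.
* Consequence calling supports SNVs only; anything else raises an
  explicit unsupported-variant error (all variants in scope are SNVs,
  and silent skipping is the failure mode this guards against). The
  declared REF is checked against the genome slice; a mismatch is an
  error, not a warning.
* Minus-strand transcripts count CDS offsets from the 3′-most base and
  complement alleles; a strand-symmetry property test mirrors a whole
  locus and requires identical consequences.
* Domain maps are config-driven. Mouse defaults (4HB 1–125, brace
  126–180) follow the published construct boundaries; human boundaries
  (brace 126–182 of 471) are labelled configurable approximations
  because no exact human definition exists in the source material.

## An end-to-end synthetic run

```{r, eval = FALSE}
pool <- pool_from_mafs(
  data.frame(chrom = "chr16", pos = c(1000L, 2000L),
             ref = c("A", "C"), alt = c("G", "T")),
  mafs = c(0.02, 0.02))
sim <- build_case_control(pool, n_cases = 128, n_controls = 2504,
                          rho = 30, seed = 1)
cases <- count_compound_hets(sim$cases$vcf,
                             c("chr16:1000:G", "chr16:2000:T"))
ctrls <- count_compound_hets(sim$controls$vcf,
                             c("chr16:1000:G", "chr16:2000:T"))
enrichment_report(cases$count, cases$n, ctrls$count, ctrls$n)
```

At these frequencies the pool's true compound-het probability is
`comphet_probability(pool)` ≈ 8×10⁻⁴; with ρ = 30 and only 128 cases the
*estimated* ratio is expectedly noisy (the acceptance suite checks
parameter recovery at n = 10⁴, where it is not).

## Known limitations

* No statistical phasing and no read-backed phasing: phase comes from
  the input separator or from parents, full stop.
* No indel/frameshift consequences; no splice-site prediction; no UTR
  annotation.
* The PED dialect is the 6-column one; the family column doubles as the
  population label (ancestry labels are inputs here, never inferred).
* Missingness-scoring trade-off: an individual with one missing
  genotype but a resolvable trans pair elsewhere is still excluded from
  the denominator; at the cohort sizes in scope this is a < 1-individual
  effect, and determinism was preferred over cleverness.
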