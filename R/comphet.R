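# Compound-heterozygote detection.
#
# Two variants are "in trans" when they sit on opposite homologous
# chromosomes. Three evidence routes are used, in order of preference:
#   1. hom_trans  - homozygous alt at one site forces one alt per
#      haplotype, so any carrier genotype at a second site is in trans
#      with it (diploidy argument; convention flagged in output so
#      tallies with and without it are both recoverable);
#   2. population_phase - both calls phased ("|"): compare haplotype
#      columns directly;
#   3. trio - exhaustive enumeration of parental transmissions
#      consistent with the observed genotypes.
# Anything unresolvable is ambiguous and never counted as a compound
# het; counting is strictly at the individual level.

PAIR_STATUSES <- c("trans", "cis", "ambiguous", "mendelian_error", "unknown")
PAIR_EVIDENCE <- c("population_phase", "trio", "hom_trans", "none")

pair_phase <- function(status, evidence) {
  stopifnot(status %in% PAIR_STATUSES, evidence %in% PAIR_EVIDENCE)
  # invariant: evidence "none" exactly for the undecidable statuses
  if ((evidence == "none") != (status %in% c("ambiguous", "unknown")))
    stop("internal error: pair_phase evidence/status mismatch (", status,
         "/", evidence, ")")
  structure(list(status = status, evidence = evidence), class = "pair_phase")
}

n_alt_alleles <- function(g, alt) {
  if (gt_is_missing(g)) return(NA_integer_)
  sum(g$a == alt)
}

#' Phase a variant pair from population-phased genotypes
#'
#' @param gA,gB [genotype_call()]s for two sites in the same sample
#' @param altA,altB target alt allele index at each site (default 1)
#' @return a `pair_phase`: list with `status` in
#'   `trans/cis/ambiguous/mendelian_error/unknown` and `evidence` in
#'   `population_phase/trio/hom_trans/none`
#' @export
phase_pair_population <- function(gA, gB, altA = 1L, altB = 1L) {
  if (!identical(gA$sample_id, gB$sample_id))
    stop("genotype calls come from different samples: ",
         gA$sample_id, " vs ", gB$sample_id)
  nA <- n_alt_alleles(gA, altA)
  nB <- n_alt_alleles(gB, altB)
  if (is.na(nA) || is.na(nB) || nA == 0L || nB == 0L)
    return(pair_phase("unknown", "none"))
  if (nA == 2L || nB == 2L)
    return(pair_phase("trans", "hom_trans"))
  if (gA$phased && gB$phased) {
    hapA <- which(gA$a == altA)
    hapB <- which(gB$a == altB)
    return(pair_phase(if (hapA == hapB) "cis" else "trans", "population_phase"))
  }
  pair_phase("ambiguous", "none")
}

#' Phase a variant pair from a parent-proband trio
#'
#' Enumerates every assignment of the proband's alleles to parental
#' gametes consistent with the six genotypes (a missing parental
#' genotype is treated as unconstrained). If every consistent
#' assignment puts the two alt alleles on different gametes the pair is
#' `trans`; all on the same gamete, `cis`; both achievable, `ambiguous`;
#' none consistent (e.g. a de novo allele), `mendelian_error`.
#'
#' @param proband,father,mother length-2 lists of [genotype_call()]s,
#'   one per site (father/mother may be `NULL` = unavailable)
#' @param altA,altB target alt allele index at each site
#' @return a `pair_phase`
#' @export
phase_pair_trio <- function(proband, father = NULL, mother = NULL,
                            altA = 1L, altB = 1L) {
  gA <- proband[[1]]; gB <- proband[[2]]
  if (gt_is_missing(gA) || gt_is_missing(gB))
    return(pair_phase("unknown", "none"))
  nA <- n_alt_alleles(gA, altA)
  nB <- n_alt_alleles(gB, altB)
  if (nA == 0L || nB == 0L) return(pair_phase("unknown", "none"))
  if (nA == 2L || nB == 2L) return(pair_phase("trans", "hom_trans"))

  parent_ok <- function(parent, site, allele) {
    # can this parent have transmitted `allele` at `site`?
    if (is.null(parent)) return(TRUE)
    g <- parent[[site]]
    if (is.null(g) || gt_is_missing(g)) return(TRUE)
    allele %in% g$a
  }
  statuses <- character()
  # child is het at both sites: alleles at A are {gA$a}, one paternal, one
  # maternal; idem at B. 2 x 2 assignments.
  for (pa_A in 1:2) for (pa_B in 1:2) {
    pat_A <- gA$a[pa_A]; mat_A <- gA$a[3 - pa_A]
    pat_B <- gB$a[pa_B]; mat_B <- gB$a[3 - pa_B]
    if (parent_ok(father, 1, pat_A) && parent_ok(father, 2, pat_B) &&
        parent_ok(mother, 1, mat_A) && parent_ok(mother, 2, mat_B)) {
      alt_A_paternal <- pat_A == altA
      alt_B_paternal <- pat_B == altB
      statuses <- c(statuses,
                    if (alt_A_paternal == alt_B_paternal) "cis" else "trans")
    }
  }
  if (length(statuses) == 0) return(pair_phase("mendelian_error", "trio"))
  statuses <- unique(statuses)
  if (length(statuses) == 2) return(pair_phase("ambiguous", "none"))
  pair_phase(statuses, "trio")
}

#' Classify one individual's compound-heterozygote status
#'
#' Considers every pair of distinct sites in the variant set at which
#' the individual carries the target alt allele. An individual is a
#' compound heterozygote iff some pair is in trans; individuals whose
#' only carrier pairs are ambiguous are reported as `ambiguous` and are
#' never counted as compound hets.
#'
#' @param sample_id individual identifier
#' @param calls list of [genotype_call()]s, one per site in the variant set
#' @param alts integer vector of target alt indices (recycled)
#' @param father_calls,mother_calls optional parallel call lists for the
#'   parents (trio evidence)
#' @return list of class `comphet_call`: `sample_id`, `status`
#'   (`comphet`/`ambiguous`/`not_comphet`), `complete` (no missing calls),
#'   `pairs` data.frame (siteA, siteB, status, evidence)
#' @export
classify_individual <- function(sample_id, calls, alts = 1L,
                                father_calls = NULL, mother_calls = NULL) {
  k <- length(calls)
  if (k < 2) comphet_validation_error("variant set must list >= 2 sites")
  alts <- rep_len(as.integer(alts), k)
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    gA <- calls[[i]]; gB <- calls[[j]]
    nA <- n_alt_alleles(gA, alts[i]); nB <- n_alt_alleles(gB, alts[j])
    if (is.na(nA) || is.na(nB) || nA == 0L || nB == 0L) next
    pp <- if (nA == 2L || nB == 2L) {
      pair_phase("trans", "hom_trans")
    } else if (gA$phased && gB$phased) {
      phase_pair_population(gA, gB, alts[i], alts[j])
    } else if (!is.null(father_calls) || !is.null(mother_calls)) {
      phase_pair_trio(
        list(gA, gB),
        if (is.null(father_calls)) NULL else list(father_calls[[i]], father_calls[[j]]),
        if (is.null(mother_calls)) NULL else list(mother_calls[[i]], mother_calls[[j]]),
        alts[i], alts[j]
      )
    } else {
      pair_phase("ambiguous", "none")
    }
    pairs[[length(pairs) + 1]] <- data.frame(
      siteA = i, siteB = j, status = pp$status, evidence = pp$evidence,
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(siteA = integer(), siteB = integer(),
               status = character(), evidence = character(),
               stringsAsFactors = FALSE)
  status <- if (any(pairs$status == "trans")) "comphet"
  else if (any(pairs$status == "ambiguous")) "ambiguous"
  else "not_comphet"
  structure(
    list(sample_id = sample_id, status = status,
         complete = !any(vapply(calls, gt_is_missing, TRUE)),
         hom_trans_only = any(pairs$status == "trans") &&
           all(pairs$evidence[pairs$status == "trans"] == "hom_trans"),
         pairs = pairs),
    class = "comphet_call"
  )
}

resolve_sites <- function(vcf, sites) {
  # sites: "chrom:pos:alt" strings or data.frame(chrom, pos, alt)
  if (is.character(sites)) {
    parts <- strsplit(sites, ":", fixed = TRUE)
    sites <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      pos = as.integer(vapply(parts, `[`, "", 2)),
      alt = vapply(parts, `[`, "", 3),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(sites) == 0) comphet_validation_error("empty variant set")
  sites <- unique(sites)
  idx <- integer(nrow(sites)); alt_idx <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- which(vcf$variants$chrom == sites$chrom[i] &
                   vcf$variants$pos == sites$pos[i])
    if (length(hit) == 0)
      comphet_validation_error(paste0("site ", sites$chrom[i], ":",
                                      sites$pos[i], " not found in VCF"))
    hit <- hit[1]
    ai <- match(sites$alt[i], vcf$variants$alts[[hit]])
    if (is.na(ai))
      comphet_validation_error(paste0("alt allele ", sites$alt[i],
                                      " not present at ", sites$chrom[i],
                                      ":", sites$pos[i]))
    idx[i] <- hit; alt_idx[i] <- ai
  }
  keep <- !duplicated(paste(idx, alt_idx))
  list(row = idx[keep], alt = alt_idx[keep])
}

#' Count compound heterozygotes in a cohort
#'
#' Classifies every sample of a cohort against a variant set. The
#' denominator `n` counts individuals with a non-missing genotype at
#' every site of the set; the numerator counts those classified in
#' trans. A separate tally excluding individuals whose only trans
#' evidence is the hom_trans convention is always reported alongside.
#'
#' @param vcf a [cohort_vcf()]
#' @param sites variant set: `"chrom:pos:alt"` strings or a data.frame
#'   with those columns (duplicates are ignored)
#' @param ped optional [read_pedigree()] result used for trio evidence
#'   and population filtering
#' @param population optional population label; only samples whose
#'   pedigree population matches are counted
#' @return list with `count`, `n`, `count_excl_hom_trans`,
#'   `n_ambiguous`, `individuals` (per-sample data.frame), `comphet_ids`
#' @export
count_compound_hets <- function(vcf, sites, ped = NULL, population = NULL) {
  if (length(vcf$samples) == 0) comphet_validation_error("empty cohort")
  rs <- resolve_sites(vcf, sites)
  samples <- vcf$samples
  if (!is.null(population)) {
    if (is.null(ped))
      comphet_validation_error("population filter requires a pedigree")
    keep <- ped$id[ped$population == population]
    samples <- intersect(samples, keep)
    if (length(samples) == 0)
      comphet_validation_error(paste0("no samples in population '",
                                      population, "'"))
  }
  calls_for <- function(sample) {
    lapply(seq_along(rs$row), function(i) genotype_call(vcf, rs$row[i], sample))
  }
  rows <- lapply(samples, function(s) {
    fa_calls <- mo_calls <- NULL
    if (!is.null(ped)) {
      pr <- parents_of(ped, s)
      if (!is.na(pr$father) && pr$father %in% vcf$samples)
        fa_calls <- calls_for(pr$father)
      if (!is.na(pr$mother) && pr$mother %in% vcf$samples)
        mo_calls <- calls_for(pr$mother)
    }
    cc <- classify_individual(s, calls_for(s), rs$alt, fa_calls, mo_calls)
    data.frame(sample = s, status = cc$status, complete = cc$complete,
               hom_trans_only = cc$hom_trans_only, stringsAsFactors = FALSE)
  })
  ind <- do.call(rbind, rows)
  counted <- ind$complete & ind$status == "comphet"
  list(
    count = sum(counted),
    n = sum(ind$complete),
    count_excl_hom_trans = sum(counted & !ind$hom_trans_only),
    n_ambiguous = sum(ind$complete & ind$status == "ambiguous"),
    individuals = ind,
    comphet_ids = ind$sample[counted]
  )
}
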