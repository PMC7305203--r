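# Synthetic cohorts with known ground truth.
#
# The generative model is a pool of haplotypes with explicit
# frequencies (linkage disequilibrium is expressed only through those
# frequencies). Individuals are two independent draws from the pool;
# trio children inherit one whole parental haplotype from each parent
# (no recombination at the within-gene scale simulated here);
# case/control enrichment is produced by rejection sampling so the
# target relative frequency is exactly known; intercross litters are
# 1:2:1 multinomial draws thinned by per-genotype viability.
# Every emitted file records the seed in its header.

#' Define a haplotype pool
#'
#' @param sites data.frame with `chrom`, `pos`, `id`, `ref`, `alt`
#'   (one biallelic row per site)
#' @param haplotypes integer matrix, one row per haplotype, one column
#'   per site, entries 0 (ref) or 1 (alt)
#' @param freqs haplotype frequencies, must sum to 1 within 1e-9
#' @return object of class `haplotype_pool`
#' @export
haplotype_pool <- function(sites, haplotypes, freqs) {
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop("sites must have columns chrom, pos, ref, alt")
  if (is.null(sites$id)) sites$id <- NA_character_
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype vector length must equal site count")
  if (length(freqs) != nrow(haplotypes))
    stop("one frequency per haplotype required")
  if (any(freqs < 0)) stop("haplotype frequencies must be >= 0")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (tolerance 1e-9); got ",
         format(sum(freqs), digits = 12))
  structure(list(sites = sites, haplotypes = haplotypes,
                 freqs = as.numeric(freqs)),
            class = "haplotype_pool")
}

#' Haplotype pool from independent per-site MAFs
#'
#' Enumerates all 2^k haplotypes of k independent biallelic sites with
#' product frequencies.
#'
#' @param sites as in [haplotype_pool()]
#' @param mafs per-site alt-allele frequencies
#' @return a `haplotype_pool`
#' @export
pool_from_mafs <- function(sites, mafs) {
  k <- nrow(sites)
  stopifnot(length(mafs) == k, all(mafs >= 0 & mafs <= 1))
  haps <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(haps) <- NULL
  freqs <- apply(haps, 1, function(h) prod(ifelse(h == 1, mafs, 1 - mafs)))
  haplotype_pool(sites, haps, freqs)
}

#' Probability that one pool draw is a compound heterozygote
#'
#' Exact enumeration over ordered haplotype pairs: an individual is a
#' compound het when two distinct sites carry alt alleles on opposite
#' haplotypes (the hom_trans convention is implied: homozygous alt at a
#' site places an alt on both haplotypes).
#'
#' @param pool a `haplotype_pool`
#' @return probability in `[0, 1]`
#' @export
comphet_probability <- function(pool) {
  H <- nrow(pool$haplotypes)
  p <- 0
  for (i in seq_len(H)) for (j in seq_len(H)) {
    if (is_trans_pair(pool$haplotypes[i, ], pool$haplotypes[j, ]))
      p <- p + pool$freqs[i] * pool$freqs[j]
  }
  p
}

# two variant sites with alts on opposite haplotypes?
is_trans_pair <- function(h1, h2) {
  k <- length(h1)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && h1[a] == 1 && h2[b] == 1) return(TRUE)
  }
  FALSE
}

draw_haps <- function(pool, n) {
  sample.int(nrow(pool$haplotypes), n, replace = TRUE, prob = pool$freqs)
}

pool_vcf <- function(pool, hap1, hap2, sample_ids, phased, seed) {
  n <- length(sample_ids)
  k <- nrow(pool$sites)
  a1 <- t(pool$haplotypes[hap1, , drop = FALSE])  # sites x samples
  a2 <- t(pool$haplotypes[hap2, , drop = FALSE])
  variants <- data.frame(chrom = pool$sites$chrom, pos = pool$sites$pos,
                         id = pool$sites$id, ref = pool$sites$ref,
                         stringsAsFactors = FALSE)
  variants$alts <- as.list(pool$sites$alt)
  cohort_vcf(variants, sample_ids,
             matrix(as.integer(a1), k, n), matrix(as.integer(a2), k, n),
             matrix(phased, k, n),
             meta = c("##fileformat=VCFv4.2",
                      paste0("##comphet_simulation_seed=", seed)))
}

truth_table <- function(pool, hap1, hap2, sample_ids) {
  data.frame(
    sample = sample_ids, hap1 = hap1, hap2 = hap2,
    comphet = vapply(seq_along(hap1), function(i)
      is_trans_pair(pool$haplotypes[hap1[i], ], pool$haplotypes[hap2[i], ]),
      TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a phased population cohort
#'
#' Each individual is two independent haplotype draws; genotypes are
#' emitted phased (`|`), haplotype 1 first, mirroring a statistically
#' phased reference panel. Deterministic given `seed`, which is also
#' written into the VCF header.
#'
#' @param pool a [haplotype_pool()]
#' @param n number of individuals
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   output contract)
#' @param prefix sample-name prefix
#' @return list with `vcf` (a [cohort_vcf()]) and `truth` (data.frame:
#'   `sample`, `hap1`, `hap2`, `comphet`)
#' @export
sample_population <- function(pool, n, seed, prefix = "S") {
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  hap1 <- draw_haps(pool, n)
  hap2 <- draw_haps(pool, n)
  list(vcf = pool_vcf(pool, hap1, hap2, ids, TRUE, seed),
       truth = truth_table(pool, hap1, hap2, ids))
}

#' Simulate parent-proband trios
#'
#' Parents are pool draws; each child inherits one complete haplotype
#' from each parent. Genotypes are emitted unphased (`/`) so that trio
#' logic is the only phase evidence. With `error_rate > 0` each call
#' is independently replaced, with that probability, by a uniform
#' random genotype (the crude error model is deliberate: its purpose is
#' to produce detectable Mendelian inconsistencies, not realism).
#'
#' @param pool a [haplotype_pool()]
#' @param n_trios number of father/mother/child triples
#' @param seed integer seed
#' @param error_rate per-call genotype error probability
#' @return list with `vcf`, `ped` (pedigree data.frame), `truth`
#'   (per-child haplotype origins and true pair phase)
#' @export
sample_trios <- function(pool, n_trios, seed, error_rate = 0) {
  set.seed(seed)
  fa1 <- draw_haps(pool, n_trios); fa2 <- draw_haps(pool, n_trios)
  mo1 <- draw_haps(pool, n_trios); mo2 <- draw_haps(pool, n_trios)
  pat <- ifelse(runif(n_trios) < 0.5, fa1, fa2)
  mat <- ifelse(runif(n_trios) < 0.5, mo1, mo2)
  fid <- sprintf("F%04d", seq_len(n_trios))
  mid <- sprintf("M%04d", seq_len(n_trios))
  cid <- sprintf("C%04d", seq_len(n_trios))
  ids <- c(fid, mid, cid)
  hap1 <- c(fa1, mo1, pat)
  hap2 <- c(fa2, mo2, mat)
  vcf <- pool_vcf(pool, hap1, hap2, ids, FALSE, seed)
  if (error_rate > 0) {
    k <- nrow(vcf$variants)
    flip <- matrix(runif(k * length(ids)) < error_rate, k, length(ids))
    vcf$a1[flip] <- sample(0:1, sum(flip), replace = TRUE)
    vcf$a2[flip] <- sample(0:1, sum(flip), replace = TRUE)
  }
  ped <- data.frame(
    family = rep(sprintf("T%04d", seq_len(n_trios)), 3),
    id = ids,
    father = c(rep(NA_character_, 2 * n_trios), fid),
    mother = c(rep(NA_character_, 2 * n_trios), mid),
    sex = c(rep("1", n_trios), rep("2", n_trios), rep("0", n_trios)),
    phenotype = "0", stringsAsFactors = FALSE
  )
  ped$affected <- FALSE
  ped$population <- ped$family
  class(ped) <- c("pedigree", "data.frame")
  truth <- data.frame(
    child = cid, paternal_hap = pat, maternal_hap = mat,
    father_hap1 = fa1, father_hap2 = fa2,
    mother_hap1 = mo1, mother_hap2 = mo2,
    comphet = vapply(seq_len(n_trios), function(i)
      is_trans_pair(pool$haplotypes[pat[i], ], pool$haplotypes[mat[i], ]),
      TRUE),
    stringsAsFactors = FALSE
  )
  list(vcf = vcf, ped = ped, truth = truth)
}

#' Simulate enriched case/control cohorts
#'
#' Controls are plain pool draws. Cases are drawn by rejection
#' sampling: compound-het individuals are always accepted,
#' non-compound-het individuals with probability `1/rho`, making the
#' relative acceptance of compound hets exactly `rho`-fold.
#'
#' @param pool a [haplotype_pool()]
#' @param n_cases,n_controls cohort sizes
#' @param rho compound-het enrichment factor (>= 1)
#' @param seed integer seed
#' @return list with `cases`, `controls` (each `list(vcf, truth)`),
#'   `true_control_freq` (the pool's exact compound-het probability)
#'   and `true_case_freq` (the exact post-enrichment probability)
#' @export
build_case_control <- function(pool, n_cases, n_controls, rho = 1, seed = 1L) {
  if (rho < 1) stop("enrichment factor rho must be >= 1")
  q <- comphet_probability(pool)
  p_accept <- q + (1 - q) / rho
  if (p_accept < 1e-6)
    stop("acceptance probability ", format(p_accept),
         " too small: expected acceptances < 1 per 1e6 draws")
  set.seed(seed)
  ctrl1 <- draw_haps(pool, n_controls); ctrl2 <- draw_haps(pool, n_controls)
  case1 <- integer(0); case2 <- integer(0)
  while (length(case1) < n_cases) {
    batch <- max(100L, ceiling((n_cases - length(case1)) / p_accept * 1.5))
    h1 <- draw_haps(pool, batch); h2 <- draw_haps(pool, batch)
    ch <- vapply(seq_len(batch), function(i)
      is_trans_pair(pool$haplotypes[h1[i], ], pool$haplotypes[h2[i], ]), TRUE)
    accept <- ch | (runif(batch) < 1 / rho)
    case1 <- c(case1, h1[accept]); case2 <- c(case2, h2[accept])
  }
  case1 <- case1[seq_len(n_cases)]; case2 <- case2[seq_len(n_cases)]
  case_ids <- sprintf("CASE%04d", seq_len(n_cases))
  ctrl_ids <- sprintf("CTRL%04d", seq_len(n_controls))
  list(
    cases = list(vcf = pool_vcf(pool, case1, case2, case_ids, TRUE, seed),
                 truth = truth_table(pool, case1, case2, case_ids)),
    controls = list(vcf = pool_vcf(pool, ctrl1, ctrl2, ctrl_ids, TRUE, seed),
                    truth = truth_table(pool, ctrl1, ctrl2, ctrl_ids)),
    true_control_freq = q,
    true_case_freq = q / p_accept
  )
}

#' Simulate an intercross litter with per-genotype viability
#'
#' Offspring genotypes are drawn 1:2:1 (wt/wt, wt/mut, mut/mut), then
#' each class is thinned by its viability. `v = c(1, 1, 0)` models
#' fully penetrant recessive lethality.
#'
#' @param n number of conceived offspring
#' @param viability length-3 survival probabilities per genotype class
#' @param seed integer seed
#' @return list with `conceived` and `observed` per-class counts
#' @export
simulate_intercross <- function(n, viability = c(1, 1, 1), seed = 1L) {
  stopifnot(length(viability) == 3, all(viability >= 0 & viability <= 1))
  set.seed(seed)
  conceived <- as.vector(rmultinom(1, n, c(1, 2, 1) / 4))
  observed <- rbinom(3, conceived, viability)
  names(conceived) <- names(observed) <- c("wt/wt", "wt/mut", "mut/mut")
  list(conceived = conceived, observed = observed)
}

#' Null distribution of Fisher p-values for cohort comparisons
#'
#' Under `rho = 1` every individual, case or control, is an independent
#' pool draw, so the compound-het counts of the two cohorts are exact
#' Binomial(n, q) variables with q = [comphet_probability()]. This
#' samples those counts directly (distributionally identical to
#' simulating full cohorts, and fast enough for 10^4 replicates) and
#' returns the two-sided Fisher p-value of each replicate.
#'
#' @param pool a [haplotype_pool()]
#' @param n_cases,n_controls cohort sizes
#' @param reps number of replicates
#' @param seed integer seed
#' @return numeric vector of p-values, length `reps`
#' @export
simulate_null_pvalues <- function(pool, n_cases, n_controls, reps, seed = 1L) {
  q <- comphet_probability(pool)
  set.seed(seed)
  a <- rbinom(reps, n_cases, q)
  c_ <- rbinom(reps, n_controls, q)
  key <- paste(a, c_)
  uniq <- !duplicated(key)
  pv <- vapply(which(uniq), function(i)
    fisher_exact_2x2(c(a[i], n_cases - a[i], c_[i], n_controls - c_[i])), 0)
  unname(pv[match(key, key[uniq])])
}
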