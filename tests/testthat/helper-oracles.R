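# Independent oracles. Each deliberately takes a different computational
# route from the implementation it checks.

# Two-sided Fisher p by exhaustive enumeration using stats::dhyper point
# probabilities (the implementation uses log-factorials instead).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- dhyper(support, r1, r2, c1)
  obs <- pmf[support == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# Exhaustive haplotype-consistency oracle for trio phasing of two
# biallelic sites: enumerate both parental phasings and both transmitted
# haplotypes per parent, keep configurations reproducing the child
# genotype, and collect whether the two alt alleles land on the same
# child haplotype.
trio_oracle <- function(child, father, mother, altA = 1L, altB = 1L) {
  if (anyNA(child[[1]]$a) || anyNA(child[[2]]$a)) return("unknown")
  nA <- sum(child[[1]]$a == altA); nB <- sum(child[[2]]$a == altB)
  if (nA == 0 || nB == 0) return("unknown")
  if (nA == 2 || nB == 2) return("trans")
  parent_haps <- function(parent) {
    # all ordered 2-site haplotype pairs a parent could carry; an
    # unavailable/missing call contributes a wildcard (NA)
    gA <- if (is.null(parent)) c(NA, NA) else parent[[1]]$a
    gB <- if (is.null(parent)) c(NA, NA) else parent[[2]]$a
    if (anyNA(gA)) gA <- c(NA, NA)
    if (anyNA(gB)) gB <- c(NA, NA)
    out <- list()
    for (ph_A in 1:2) for (ph_B in 1:2) {
      h1 <- c(gA[ph_A], gB[ph_B])
      h2 <- c(gA[3 - ph_A], gB[3 - ph_B])
      out[[length(out) + 1]] <- list(h1, h2)
    }
    out
  }
  same_multiset <- function(x, y) {
    # NA in x is a wildcard
    for (perm in list(1:2, 2:1)) {
      ok <- all(is.na(x) | x == y[perm])
      if (ok) return(TRUE)
    }
    FALSE
  }
  outcomes <- character()
  for (fh in parent_haps(father)) for (fi in 1:2) {
    for (mh in parent_haps(mother)) for (mi in 1:2) {
      pat <- fh[[fi]]; mat <- mh[[mi]]
      gotA <- c(pat[1], mat[1]); gotB <- c(pat[2], mat[2])
      if (same_multiset(gotA, child[[1]]$a) &&
          same_multiset(gotB, child[[2]]$a)) {
        # resolve wildcards: transmitted allele must equal the child
        # allele it explains; with child het-het each config fixes which
        # child allele is paternal at each site
        for (cA in 1:2) for (cB in 1:2) {
          pA <- child[[1]]$a[cA]; mA <- child[[1]]$a[3 - cA]
          pB <- child[[2]]$a[cB]; mB <- child[[2]]$a[3 - cB]
          if ((is.na(pat[1]) || pat[1] == pA) &&
              (is.na(mat[1]) || mat[1] == mA) &&
              (is.na(pat[2]) || pat[2] == pB) &&
              (is.na(mat[2]) || mat[2] == mB)) {
            alt_A_pat <- pA == altA
            alt_B_pat <- pB == altB
            outcomes <- c(outcomes,
                          if (alt_A_pat == alt_B_pat) "cis" else "trans")
          }
        }
      }
    }
  }
  outcomes <- unique(outcomes)
  if (length(outcomes) == 0) return("mendelian_error")
  if (length(outcomes) == 2) return("ambiguous")
  outcomes
}

# Consequence oracle: translate the full reference and mutated spliced
# CDS and diff the proteins (implementation mutates a single codon).
consequence_oracle <- function(t, pos, ref, alt) {
  g <- strsplit(t$seq, "")[[1]]
  stopifnot(g[pos - t$seq_start + 1] == ref)
  g2 <- g
  g2[pos - t$seq_start + 1] <- alt
  t2 <- t
  t2$seq <- paste(g2, collapse = "")
  pep1 <- comphet:::translate_cds(spliced_cds(t))
  pep2 <- comphet:::translate_cds(spliced_cds(t2))
  if (pep1 == pep2) return(list(kind = "synonymous"))
  diff <- which(strsplit(pep1, "")[[1]] != strsplit(pep2, "")[[1]])[1]
  ra <- substr(pep1, diff, diff); aa <- substr(pep2, diff, diff)
  kind <- if (aa == "*") "stop_gain" else if (ra == "*") "stop_loss" else "missense"
  list(kind = kind, protein_pos = diff,
       ref_aa = if (ra == "*") "X" else ra,
       alt_aa = if (aa == "*") "X" else aa)
}

# enumerate spliced-CDS genomic coordinates in transcription order
cds_positions_oracle <- function(t) {
  pos <- integer()
  for (i in seq_len(nrow(t$exons))) {
    s <- max(t$exons$start[i], t$cds_start)
    e <- min(t$exons$end[i], t$cds_end)
    if (s <= e) pos <- c(pos, s:e)
  }
  if (t$strand == "-") rev(pos) else pos
}
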