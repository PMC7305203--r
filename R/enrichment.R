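# Individual-level case/control enrichment statistics for 2x2 tables:
# two-sided Fisher exact test (sum of tables at most as probable,
# computed in log space), chi-square with Yates continuity correction,
# allele frequencies, and frequency ratios rounded for display.

#' Construct a 2x2 contingency table
#'
#' @param a cases positive, @param b cases negative,
#' @param c controls positive, @param d controls negative
#' @return object of class `contingency_2x2` with derived margins
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(x < 0) || any(x != round(x)))
    stop("contingency counts must be non-negative integers")
  structure(as.list(x), N = sum(x), class = "contingency_2x2")
}

as_counts <- function(t) {
  if (inherits(t, "contingency_2x2")) unlist(t[c("a", "b", "c", "d")])
  else if (is.numeric(t) && length(t) == 4) t
  else stop("expected a contingency_2x2 or a length-4 numeric vector")
}

#' Two-sided Fisher exact test
#'
#' P-value is the sum, over the hypergeometric support with the table's
#' margins fixed, of all point probabilities at most as large as the
#' observed one (with a `1 + 1e-7` relative tolerance on the
#' comparison, the dominant software convention). Probabilities are
#' computed in log space via log-factorials. A degenerate margin gives
#' p = 1.
#'
#' @param t a [contingency_2x2()] or numeric `c(a, b, c, d)`
#' @return the two-sided p-value
#' @export
fisher_exact_2x2 <- function(t) {
  x <- as_counts(t)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logpmf <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  obs <- logpmf[support == a]
  p <- sum(exp(logpmf[logpmf <= obs + log1p(1e-7)]))
  min(1, p)
}

#' Chi-square test with Yates continuity correction
#'
#' Statistic `N * (max(|ad - bc| - N/2, 0))^2 / (R1 R2 C1 C2)` with the
#' clamp at zero preventing under-correction; p from the upper tail of
#' the 1-df chi-square distribution. A zero margin makes the test
#' undefined and is an error (distinct from p = 1).
#'
#' @param t a [contingency_2x2()] or numeric `c(a, b, c, d)`
#' @return list with `statistic` and `p`
#' @export
chisq_yates <- function(t) {
  x <- as.numeric(as_counts(t))  # doubles: the cross-product overflows int32
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n <- sum(x)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("chi-square with Yates correction undefined: zero margin")
  num <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = unname(stat),
       p = unname(pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Case:control frequency ratio with display rounding
#'
#' Ratio of positive-fraction in cases to positive-fraction in
#' controls; the label rounds half away from zero (the printed-table
#' convention is unconstrained at .5, so the choice is documented, not
#' inferred). `c = 0` yields an infinite-ratio sentinel.
#'
#' @param t a [contingency_2x2()] or numeric `c(a, b, c, d)`
#' @return list with `ratio` and `label` (e.g. `"29:1"`)
#' @export
frequency_ratio <- function(t) {
  x <- as_counts(t)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if (c == 0) return(list(ratio = Inf, label = "inf"))
  ratio <- (a / (a + b)) / (c / (c + d))
  k <- sign(ratio) * floor(abs(ratio) + 0.5)  # half away from zero
  list(ratio = unname(ratio), label = paste0(format(k, scientific = FALSE), ":1"))
}

#' Alt-allele frequency at one site
#'
#' @param calls list of [genotype_call()]s (diploid autosomal); missing
#'   calls are excluded from the denominator
#' @param alt target alt allele index
#' @return alt-allele count / (2 x called individuals)
#' @export
allele_frequency <- function(calls, alt = 1L) {
  counts <- vapply(calls, n_alt_alleles, 1L, alt = alt)
  called <- sum(!is.na(counts))
  if (called == 0) stop("allele frequency undefined: zero called individuals")
  sum(counts, na.rm = TRUE) / (2 * called)
}

#' One row of an enrichment report
#'
#' Assembles the per-population comparison of individual-level
#' compound-het frequencies between a case and a control cohort: both
#' frequencies, the rounded frequency ratio, the two-sided Fisher exact
#' p, and the Yates chi-square statistic and p (NA when a zero margin
#' makes the test undefined). Full-precision values are stored;
#' rounding happens only in formatting.
#'
#' @param case_count,case_n positives and denominator in cases
#' @param control_count,control_n idem for controls
#' @param population row label
#' @param control_label label for the control cohort
#' @return one-row data.frame of class `enrichment_row`
#' @export
enrichment_report <- function(case_count, case_n, control_count, control_n,
                              population = "all", control_label = "controls") {
  if (case_n <= 0 || control_n <= 0)
    comphet_validation_error("empty cohort in enrichment report")
  t <- contingency_2x2(case_count, case_n - case_count,
                       control_count, control_n - control_count)
  fr <- if (case_count == 0 && control_count == 0)
    list(ratio = NaN, label = "n/a") else frequency_ratio(t)
  cy <- tryCatch(chisq_yates(t),
                 error = function(e) list(statistic = NA_real_, p = NA_real_))
  out <- data.frame(
    population = population, control_label = control_label,
    case_freq = case_count / case_n,
    case_counts = paste0(case_count, "/", case_n),
    control_freq = control_count / control_n,
    control_counts = paste0(control_count, "/", control_n),
    ratio = fr$ratio, ratio_label = fr$label,
    fisher_p = fisher_exact_2x2(t),
    chisq_stat = cy$statistic, chisq_p = cy$p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_row", "data.frame")
  out
}
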