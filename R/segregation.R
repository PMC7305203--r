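# Mendelian segregation: expected genotype counts under a cross ratio,
# goodness-of-fit chi-square, and exact binomial depletion probabilities
# (the recessive-lethality signal: too few of one homozygote class).

#' Parse a ratio specification like "1:2:1"
#' @param x character `"1:2:1"` or a numeric vector of positive weights
#' @return numeric weight vector
#' @export
parse_ratio <- function(x) {
  r <- if (is.character(x)) as.numeric(strsplit(x, ":", fixed = TRUE)[[1]]) else as.numeric(x)
  if (anyNA(r) || any(r <= 0)) stop("ratio terms must be positive numbers")
  r
}

#' Expected genotype counts under a segregation ratio
#'
#' Real expectations are `total * ratio_i / sum(ratio)`; the rounded
#' presentation uses round-half-to-even (bankers' rounding), the unique
#' simple nearest-integer rule consistent with standard litter-table
#' bookkeeping at exact halves.
#'
#' @param total number of offspring genotyped
#' @param ratio segregation ratio, e.g. `c(1, 2, 1)` or `"1:2:1"`
#' @return list with `expected` (real, sums exactly to `total`) and
#'   `rounded`
#' @export
expected_counts <- function(total, ratio = c(1, 2, 1)) {
  if (total < 0) stop("total must be >= 0")
  r <- parse_ratio(ratio)
  e <- total * r / sum(r)
  list(expected = e, rounded = round(e))
}

#' Goodness-of-fit chi-square against a segregation ratio
#'
#' @param observed integer vector of per-class counts
#' @param ratio expected ratio (same order as `observed`)
#' @return list with `statistic`, `df`, `p`
#' @export
gof_chisq <- function(observed, ratio = c(1, 2, 1)) {
  r <- parse_ratio(ratio)
  if (length(r) != length(observed))
    stop("observed and ratio must have the same number of classes")
  total <- sum(observed)
  if (total <= 0) stop("no observations")
  e <- total * r / sum(r)
  if (any(e == 0)) stop("expected count of zero; test undefined")
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Exact binomial lower-tail (depletion/absence) probability
#'
#' Probability of observing `k` or fewer members of a genotype class of
#' per-offspring probability `p0` among `n` offspring, under faithful
#' Mendelian segregation. Small values indicate depletion of the class
#' (e.g. recessive lethality of a homozygote genotype).
#'
#' @param k observed count of the class
#' @param n total offspring
#' @param p0 Mendelian class probability (e.g. 0.25 for an intercross
#'   homozygote)
#' @return `P(X <= k)` for `X ~ Binomial(n, p0)`
#' @export
absence_probability <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) stop("k must be in [0, n]")
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must be in (0, 1)")
  pbinom(k, n, p0)
}

#' Two-class depletion chi-square
#'
#' Companion to [absence_probability()]: chi-square on (class,
#' not-class) counts against `(p0, 1 - p0)`. The exact binomial is
#' preferred at small counts; both are offered because the appropriate
#' category structure for a depletion test is a modelling choice.
#'
#' @inheritParams absence_probability
#' @return list with `statistic`, `df`, `p`
#' @export
depletion_chisq <- function(k, n, p0) {
  gof_chisq(c(k, n - k), c(p0, 1 - p0))
}
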