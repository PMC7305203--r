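# Per-column conservation of a protein MSA, sequence-logo style.
#
# Information content R = log2(20) - H, with H the Shannon entropy of
# the column's amino-acid frequencies. Gaps and the ambiguity letter X
# are excluded from frequency normalization (coverage is reported
# separately); an optional small-sample correction e_n =
# 19 / (2 ln2 n) and an optional coverage (gap) penalty are available
# but off by default.

MAX_BITS <- log2(20)

column_freqs <- function(aln, col) {
  letters <- aln$mat[, col]
  letters <- letters[!(letters %in% c("-", "X"))]
  if (length(letters) == 0) return(NULL)
  tab <- table(letters)
  setNames(as.numeric(tab) / length(letters), names(tab))
}

#' Non-gap coverage of an alignment column
#' @param aln a `protein_alignment`
#' @param col 1-based column index
#' @return fraction of sequences with a standard residue (not `-`/`X`)
#' @export
column_coverage <- function(aln, col) {
  mean(!(aln$mat[, col] %in% c("-", "X")))
}

#' Information content of one alignment column (bits)
#'
#' @param aln a `protein_alignment`
#' @param col 1-based column index
#' @param small_sample apply the small-sample correction
#'   `e_n = 19 / (2 ln2 n)` with `n` the number of non-gap residues
#' @param gap_penalty multiply the score by the column's non-gap
#'   coverage (gap-penalized logo convention)
#' @return bits in `[0, log2(20)]`; an all-gap column scores 0
#' @export
column_information <- function(aln, col, small_sample = FALSE,
                               gap_penalty = FALSE) {
  if (col < 1 || col > aln$L) stop("column ", col, " out of range")
  p <- column_freqs(aln, col)
  if (is.null(p)) return(0)
  H <- -sum(p * log2(p))
  R <- MAX_BITS - H
  if (small_sample) {
    n <- sum(!(aln$mat[, col] %in% c("-", "X")))
    R <- R - 19 / (2 * log(2) * n)
  }
  R <- max(0, min(MAX_BITS, R))
  if (gap_penalty) R <- R * column_coverage(aln, col)
  R
}

#' Sequence-logo letter heights
#'
#' `height(letter, col) = p(letter, col) * R(col)`; per-column heights
#' sum to the column information.
#'
#' @inheritParams column_information
#' @return 20 x L numeric matrix (rows: amino acids)
#' @export
logo_matrix <- function(aln, small_sample = FALSE, gap_penalty = FALSE) {
  out <- matrix(0, nrow = length(AA20), ncol = aln$L,
                dimnames = list(AA20, NULL))
  for (col in seq_len(aln$L)) {
    p <- column_freqs(aln, col)
    if (is.null(p)) next
    R <- column_information(aln, col, small_sample, gap_penalty)
    out[names(p), col] <- p * R
  }
  out
}

#' Map alignment columns to reference-residue numbers
#'
#' @param aln a `protein_alignment`
#' @param ref_id id of the reference sequence in the alignment
#' @return integer vector of length L: residue number (1-based,
#'   consecutive over the reference's non-gap positions) or `NA` where
#'   the reference has a gap
#' @export
map_columns_to_reference <- function(aln, ref_id) {
  i <- match(ref_id, aln$ids)
  if (is.na(i)) stop("unknown reference id: ", ref_id)
  ref <- aln$mat[i, ]
  nongap <- ref != "-"
  out <- rep(NA_integer_, aln$L)
  out[nongap] <- seq_len(sum(nongap))
  out
}

#' Per-residue conservation track for a reference sequence
#'
#' @inheritParams column_information
#' @param ref_id reference sequence id
#' @return data.frame of class `conservation_track`: `residue`, `score`
#'   (bits), `coverage`
#' @export
conservation_track <- function(aln, ref_id, small_sample = FALSE,
                               gap_penalty = FALSE) {
  m <- map_columns_to_reference(aln, ref_id)
  cols <- which(!is.na(m))
  out <- data.frame(
    residue = m[cols],
    score = vapply(cols, function(cc)
      column_information(aln, cc, small_sample, gap_penalty), 0),
    coverage = vapply(cols, function(cc) column_coverage(aln, cc), 0)
  )
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Write a conservation track as TSV
#' @param track a [conservation_track()]
#' @param path output path
#' @export
write_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
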