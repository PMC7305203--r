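# Projection of per-residue scores into the B-factor field of a PDB
# file. The contract is byte-preservation: only columns 61-66 of
# ATOM/HETATM records change, everything else round-trips identically,
# so the writer edits raw lines in place rather than going through a
# structure object.

#' Write per-residue scores into a PDB B-factor column
#'
#' Replaces the B-factor field (fixed-width columns 61-66, `%6.2f`) of
#' every ATOM/HETATM record of the requested chain whose residue number
#' appears in `track`. All other bytes of the file are preserved.
#' Track residues absent from the chain produce a warning; chain
#' residues absent from the track are left untouched.
#'
#' @param pdb_in input PDB path
#' @param chain chain identifier (column 22)
#' @param track a [conservation_track()] or any data.frame with
#'   `residue` and `score` columns
#' @param pdb_out output path
#' @return `pdb_out`, invisibly
#' @export
write_scores_to_structure <- function(pdb_in, chain, track, pdb_out) {
  lines <- readLines(pdb_in, warn = FALSE)
  scores <- setNames(track$score, track$residue)
  if (any(abs(track$score) >= 1000))
    stop("score magnitude >= 1000 cannot be formatted in a 6-char B-factor field")
  seen <- integer()
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (!(rec %in% c("ATOM  ", "HETATM"))) next
    if (nchar(lines[i]) < 66)
      stop("PDB parse error at line ", i, ": ATOM/HETATM record shorter than 66 columns")
    if (substr(lines[i], 22, 22) != chain) next
    resseq <- suppressWarnings(as.integer(trimws(substr(lines[i], 23, 26))))
    if (is.na(resseq))
      stop("PDB parse error at line ", i, ": unparseable residue number")
    key <- as.character(resseq)
    if (!key %in% names(scores)) next
    substr(lines[i], 61, 66) <- sprintf("%6.2f", scores[[key]])
    seen <- c(seen, resseq)
  }
  missing <- setdiff(track$residue, unique(seen))
  if (length(missing))
    warning("track residues not found in chain ", chain, ": ",
            paste(missing, collapse = ", "))
  writeLines(lines, pdb_out)
  invisible(pdb_out)
}

#' Read the residue numbers present in a PDB chain
#' @param pdb_in PDB path
#' @param chain chain id
#' @return sorted unique residue numbers of ATOM records in the chain
#' @export
pdb_chain_residues <- function(pdb_in, chain) {
  lines <- readLines(pdb_in, warn = FALSE)
  atom <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM") &
    substr(lines, 22, 22) == chain
  sort(unique(as.integer(trimws(substr(lines[atom], 23, 26)))))
}
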