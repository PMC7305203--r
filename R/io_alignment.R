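# Aligned-FASTA loader for protein MSAs. FASTA parsing is delegated to
# Biostrings; this layer enforces the alignment contract (equal lengths,
# restricted alphabet, uppercase normalization).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a protein multiple sequence alignment
#'
#' Loads an aligned FASTA file. Sequences are uppercased on load; the
#' alphabet is restricted to the 20 amino acids plus the gap character
#' `-` and the ambiguity letter `X`. Ragged (unequal-length) inputs are
#' rejected with the offending sequence ids.
#'
#' @param path aligned FASTA file
#' @return object of class `protein_alignment`: list with `ids`,
#'   `seqs` (character), `mat` (n x L character matrix), `n`, `L`
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (length(seqs) == 0) stop("alignment error: no sequences in ", path)
  L <- nchar(seqs[[1]])
  bad <- ids[nchar(seqs) != L]
  if (length(bad))
    stop("alignment error: unequal sequence lengths for: ",
         paste(bad, collapse = ", "))
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  letters_seen <- unique(as.vector(mat))
  illegal <- setdiff(letters_seen, c(AA20, "-", "X"))
  if (length(illegal))
    stop("alignment error: illegal characters: ",
         paste(illegal, collapse = ", "))
  structure(list(ids = ids, seqs = unname(seqs), mat = mat,
                 n = length(seqs), L = L),
            class = "protein_alignment")
}

#' Construct an alignment from in-memory sequences
#' @param seqs named character vector of equal-length aligned sequences
#' @return a `protein_alignment`
#' @export
alignment_from_seqs <- function(seqs) {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(paste0(">", names(seqs), "\n", seqs), tmp)
  read_alignment(tmp)
}

#' Write an alignment as FASTA
#' @param aln a `protein_alignment`
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> ", x$n, " sequences x ", x$L, " columns\n", sep = "")
  invisible(x)
}
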