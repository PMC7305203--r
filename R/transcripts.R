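# Isoform-aware consequence annotation for SNVs.
#
# A TranscriptModel is an exon/CDS structure over an explicit genomic
# slice; variants are projected through the spliced CDS onto protein
# coordinates per isoform. Coordinates are 1-based at the boundary (VCF
# convention) and 0-based internally for offsets. Only SNVs are
# supported: every variant class this pipeline targets is a SNV, and
# indel consequence calling has failure modes (frame recovery, HGVS
# normalization) that are out of scope, so non-SNVs raise an explicit
# error rather than being skipped silently.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("untranslatable codon(s): ",
                      paste(codons[is.na(aa)], collapse = ", "))
  paste(aa, collapse = "")
}

#' Build a transcript model
#'
#' @param transcript_id,gene identifiers
#' @param strand `"+"` or `"-"`
#' @param exons data.frame with `start`, `end` (1-based inclusive genomic
#'   coordinates), non-overlapping, ordered by position
#' @param cds_start,cds_end genomic bounds of the coding sequence
#'   (inclusive; `cds_start` is the lower coordinate regardless of strand)
#' @param seq reference genome slice covering the locus (plus strand)
#' @param seq_start genomic coordinate of the first base of `seq`
#' @param strict when `TRUE` (default) the spliced CDS must begin with a
#'   start codon, end with a stop and contain no internal stop; toy
#'   fixtures may relax this
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene, strand, exons,
                             cds_start, cds_end, seq, seq_start = 1L,
                             strict = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or are unordered")
  if (any(exons$end < exons$start)) stop("exon end < start")
  seq <- toupper(seq)
  slice_end <- seq_start + nchar(seq) - 1L
  if (min(exons$start) < seq_start || max(exons$end) > slice_end)
    stop("exons extend beyond the provided genome slice")
  if (cds_start > cds_end) stop("cds_start > cds_end")
  t <- structure(
    list(transcript_id = transcript_id, gene = gene, strand = strand,
         exons = exons, cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end), seq = seq,
         seq_start = as.integer(seq_start), strict = strict),
    class = "transcript_model"
  )
  cds <- spliced_cds(t)
  if (nchar(cds) %% 3 != 0)
    stop("spliced CDS length (", nchar(cds), ") not divisible by 3")
  if (strict) {
    pep <- translate_cds(cds)
    if (substr(pep, 1, 1) != "M")
      stop("CDS does not begin with a start codon (use strict = FALSE for toys)")
    if (substr(pep, nchar(pep), nchar(pep)) != "*")
      stop("CDS does not end with a stop codon (use strict = FALSE for toys)")
    if (grepl("\\*", substr(pep, 1, nchar(pep) - 1)))
      stop("internal stop codon in CDS")
  }
  t
}

# CDS sub-intervals (1-based inclusive genomic, ascending)
cds_intervals <- function(t) {
  s <- pmax(t$exons$start, t$cds_start)
  e <- pmin(t$exons$end, t$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced coding sequence of a transcript (transcription orientation)
#' @param t a `transcript_model`
#' @return character CDS string (reverse-complemented for minus strand)
#' @export
spliced_cds <- function(t) {
  iv <- cds_intervals(t)
  pieces <- substring(t$seq, iv$start - t$seq_start + 1L,
                      iv$end - t$seq_start + 1L)
  cds <- paste(pieces, collapse = "")
  if (t$strand == "-") revcomp(cds) else cds
}

cds_length <- function(t) {
  iv <- cds_intervals(t)
  sum(iv$end - iv$start + 1L)
}

#' Protein length encoded by a transcript (stop codon excluded)
#' @param t a `transcript_model`
#' @export
protein_length <- function(t) {
  pep <- translate_cds(spliced_cds(t))
  if (substr(pep, nchar(pep), nchar(pep)) == "*") nchar(pep) - 1L else nchar(pep)
}

#' Map a genomic position to a spliced-CDS offset
#'
#' @param t a `transcript_model`
#' @param pos genomic position (1-based)
#' @return 0-based offset into the spliced CDS (counted from the 3'-most
#'   CDS base for minus-strand transcripts), or `NULL` when `pos` is
#'   intronic or outside the CDS. Positions outside the genome slice are
#'   an error.
#' @export
map_genomic_to_cds <- function(t, pos) {
  slice_end <- t$seq_start + nchar(t$seq) - 1L
  if (pos < t$seq_start || pos > slice_end)
    stop("position ", pos, " outside the genome slice [",
         t$seq_start, ", ", slice_end, "]")
  iv <- cds_intervals(t)
  cum <- 0L
  asc <- NULL
  for (i in seq_len(nrow(iv))) {
    if (pos >= iv$start[i] && pos <= iv$end[i]) {
      asc <- cum + (pos - iv$start[i])
      break
    }
    if (pos > iv$end[i]) cum <- cum + (iv$end[i] - iv$start[i] + 1L)
  }
  if (is.null(asc)) return(NULL)
  as.integer(if (t$strand == "+") asc else cds_length(t) - 1L - asc)
}

aa_label <- function(aa) if (aa == "*") "X" else aa

#' Call the protein consequence of a SNV on one transcript
#'
#' Mutates the codon containing the variant's CDS offset and classifies
#' the substitution under the standard genetic code. Positions inside
#' the transcript span but outside every exon are `intronic`; exonic
#' positions outside the CDS, and positions outside the transcript
#' entirely, are `non_coding`.
#'
#' @param t a `transcript_model`
#' @param v a variant: list/row with `pos`, `ref`, `alts`
#' @param alt_index which alt allele to assess (default 1)
#' @return list of class `consequence`: `transcript_id`, `kind`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `label`
#' @export
call_codon_consequence <- function(t, v, alt_index = 1L) {
  alt <- v$alts[[1]][alt_index] %||% v$alts[alt_index]
  if (nchar(v$ref) != 1 || nchar(alt) != 1)
    stop("unsupported variant: only SNVs can be consequence-called (ref='",
         v$ref, "', alt='", alt, "')")
  cons <- function(kind, pp = NULL, ra = NULL, aa = NULL, lab = NULL) {
    structure(list(transcript_id = t$transcript_id, kind = kind,
                   protein_pos = pp, ref_aa = ra, alt_aa = aa, label = lab),
              class = "consequence")
  }
  off <- map_genomic_to_cds(t, v$pos)
  if (is.null(off)) {
    in_span <- v$pos >= min(t$exons$start) && v$pos <= max(t$exons$end)
    in_exon <- any(v$pos >= t$exons$start & v$pos <= t$exons$end)
    return(cons(if (in_span && !in_exon) "intronic" else "non_coding"))
  }
  # sanity: the slice must agree with the declared REF allele (plus strand)
  slice_base <- substr(t$seq, v$pos - t$seq_start + 1L, v$pos - t$seq_start + 1L)
  if (slice_base != toupper(v$ref))
    stop("reference mismatch at position ", v$pos, ": slice has '",
         slice_base, "', variant REF is '", v$ref, "'")
  ref_tx <- if (t$strand == "-") unname(DNA_COMPLEMENT[toupper(v$ref)]) else toupper(v$ref)
  alt_tx <- if (t$strand == "-") unname(DNA_COMPLEMENT[toupper(alt)]) else toupper(alt)
  cds <- spliced_cds(t)
  codon_i <- off %/% 3L
  phase <- off %% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (substr(codon, phase + 1L, phase + 1L) != ref_tx)
    stop("internal error: CDS base does not match REF")  # guarded by slice check
  mut <- codon
  substr(mut, phase + 1L, phase + 1L) <- alt_tx
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[mut])
  kind <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gain"
  else if (ref_aa == "*") "stop_loss"
  else "missense"
  pp <- codon_i + 1L
  cons(kind, pp, aa_label(ref_aa), aa_label(alt_aa),
       paste0(aa_label(ref_aa), pp, aa_label(alt_aa)))
}

#' Annotate a variant against several isoforms
#'
#' Each transcript is assessed independently; a position that is coding
#' in one isoform and intronic in another yields differing kinds, which
#' is the whole point of isoform-aware annotation.
#'
#' @param v variant (list/row with `pos`, `ref`, `alts`)
#' @param transcripts list of `transcript_model`s sharing the locus slice
#' @param alt_index alt allele to assess
#' @return data.frame, one row per isoform: `transcript_id`, `kind`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `label`
#' @export
annotate_variant <- function(v, transcripts, alt_index = 1L) {
  rows <- lapply(transcripts, function(t) {
    cq <- call_codon_consequence(t, v, alt_index)
    data.frame(transcript_id = cq$transcript_id, kind = cq$kind,
               protein_pos = cq$protein_pos %||% NA_integer_,
               ref_aa = cq$ref_aa %||% NA_character_,
               alt_aa = cq$alt_aa %||% NA_character_,
               label = cq$label %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- transcript table I/O -------------------------------------------------
# Custom TSV: transcript_id gene strand seq_id seq_start exons cds_start
# cds_end strict; exons serialized "start-end;start-end". Full GFF3 import
# is out of scope (two-isoform toy loci are the working scale).

#' Read transcript models from the package's tabular format
#'
#' @param path TSV with columns `transcript_id`, `gene`, `strand`,
#'   `seq_id`, `seq_start`, `exons` (`"s-e;s-e"`), `cds_start`,
#'   `cds_end`, `strict` (0/1)
#' @param sequences named character vector of genome slices, or a path
#'   to a FASTA file providing them (names matched to `seq_id`)
#' @return list of `transcript_model`s
#' @export
read_transcript_table <- function(path, sequences) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    set <- Biostrings::readBStringSet(sequences)
    sequences <- setNames(toupper(as.character(set)),
                          sub("\\s.*$", "", names(set)))
  }
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    if (!d$seq_id[i] %in% names(sequences))
      stop("no sequence provided for seq_id '", d$seq_id[i], "'")
    iv <- do.call(rbind, lapply(strsplit(d$exons[i], ";", fixed = TRUE)[[1]],
                                function(x) as.integer(strsplit(x, "-")[[1]])))
    transcript_model(d$transcript_id[i], d$gene[i], d$strand[i],
                     data.frame(start = iv[, 1], end = iv[, 2]),
                     d$cds_start[i], d$cds_end[i],
                     sequences[[d$seq_id[i]]], d$seq_start[i],
                     strict = as.logical(d$strict[i]))
  })
}

#' Write transcript models to the tabular format
#' @param transcripts list of `transcript_model`s
#' @param path output TSV path
#' @param seq_ids names used for each transcript's slice (default the
#'   transcript ids)
#' @export
write_transcript_table <- function(transcripts, path, seq_ids = NULL) {
  seq_ids <- seq_ids %||% vapply(transcripts, function(t) t$transcript_id, "")
  d <- data.frame(
    transcript_id = vapply(transcripts, function(t) t$transcript_id, ""),
    gene = vapply(transcripts, function(t) t$gene, ""),
    strand = vapply(transcripts, function(t) t$strand, ""),
    seq_id = seq_ids,
    seq_start = vapply(transcripts, function(t) t$seq_start, 1L),
    exons = vapply(transcripts, function(t)
      paste(paste0(t$exons$start, "-", t$exons$end), collapse = ";"), ""),
    cds_start = vapply(transcripts, function(t) t$cds_start, 1L),
    cds_end = vapply(transcripts, function(t) t$cds_end, 1L),
    strict = vapply(transcripts, function(t) as.integer(t$strict), 1L),
    stringsAsFactors = FALSE
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
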