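# Fixture builders. Everything is generated in code; no binary data.

SAFE_CODONS <- c("GCT", "GGA", "CTG", "AAA", "GAA", "TTC", "CCT", "ACG")

# Two-isoform toy locus on a 1600 bp slice (plus strand):
#   T1 "canonical": exons 101-400, 501-950, 1401-1433; CDS 101..1433
#       (261 codons incl stop; protein 260 aa). Codon 48 = CAA (Q),
#       codon 139 = GAT (D), codon 150 = GCT (A, synonymous test site).
#   T2 "short isoform": exons 101-400, 951-1313; CDS 101..1313
#       (221 codons incl stop; protein 220 aa). Its exon 2 extends into
#       T1's intron; T2 codon 202 = GGT (G) at genomic 1254-1256.
toy_locus <- function() {
  genome <- rep(strsplit("ACGT", "")[[1]], length.out = 1600)
  place_codons <- function(genome, positions, codons) {
    stopifnot(length(positions) == 3 * length(codons))
    genome[positions] <- strsplit(paste(codons, collapse = ""), "")[[1]]
    genome
  }
  body1 <- rep(SAFE_CODONS, length.out = 259)   # codons 2..260
  cds1 <- c("ATG", body1, "TAA")
  cds1[48] <- "CAA"
  cds1[139] <- "GAT"
  cds1[150] <- "GCT"
  t1_cds_pos <- c(101:400, 501:950, 1401:1433)
  genome <- place_codons(genome, t1_cds_pos, cds1)
  # T2 exon-2 codons 101..221 live at 951..1313
  body2 <- rep(rev(SAFE_CODONS), length.out = 120)  # codons 101..220
  cds2_tail <- c(body2, "TAA")
  cds2_tail[202 - 100] <- "GGT"
  genome <- place_codons(genome, 951:1313, cds2_tail)
  seq <- paste(genome, collapse = "")
  t1 <- transcript_model(
    "T1", "toygene", "+",
    data.frame(start = c(101, 501, 1401), end = c(400, 950, 1433)),
    101, 1433, seq, 1
  )
  t2 <- transcript_model(
    "T2", "toygene", "+",
    data.frame(start = c(101, 951), end = c(400, 1313)),
    101, 1313, seq, 1
  )
  list(t1 = t1, t2 = t2, seq = seq)
}

# mirror a transcript onto the minus strand of the reverse-complemented
# slice; genomic positions map p -> L - p + 1
flip_locus <- function(t) {
  L <- nchar(t$seq)
  flip <- function(p) L - p + 1L
  exons <- data.frame(start = flip(t$exons$end), end = flip(t$exons$start))
  transcript_model(t$transcript_id, t$gene,
                   if (t$strand == "+") "-" else "+",
                   exons[order(exons$start), ],
                   flip(t$cds_end), flip(t$cds_start),
                   comphet:::revcomp(t$seq), t$seq_start,
                   strict = t$strict)
}

make_gt <- function(a1, a2, phased = FALSE, sample_id = "S1") {
  structure(list(sample_id = sample_id,
                 a = c(a1, a2), phased = phased && !is.na(a1) && !is.na(a2)),
            class = "genotype_call")
}

toy_sites <- function(k = 2) {
  data.frame(chrom = "chr16", pos = 1000L * seq_len(k),
             id = sprintf("rsTOY%d", seq_len(k)),
             ref = rep_len(c("A", "C", "G"), k),
             alt = rep_len(c("G", "T", "A"), k),
             stringsAsFactors = FALSE)
}

site_strings <- function(sites) sprintf("%s:%d:%s", sites$chrom, sites$pos, sites$alt)

# fixed-width toy PDB: one CA atom per residue
toy_pdb_lines <- function(residues, chain = "A", bfactor = 0) {
  vapply(seq_along(residues), function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, " CA ", "ALA", chain, residues[i],
            i * 1.5, 2.0, 3.0, 1.00, bfactor, " C")
  }, "")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
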