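test_that("genomic-to-CDS mapping agrees with coordinate enumeration", {
  loc <- toy_locus()
  for (t in list(loc$t1, loc$t2, flip_locus(loc$t1), flip_locus(loc$t2))) {
    oracle <- cds_positions_oracle(t)
    # every CDS base maps to its transcription-order offset
    offs <- vapply(oracle, function(p) map_genomic_to_cds(t, p), 1L)
    expect_equal(offs, seq_along(oracle) - 1L)
    # boundary cases
    first <- if (t$strand == "+") min(oracle) else max(oracle)
    expect_equal(map_genomic_to_cds(t, first), 0L)
    last_low <- min(oracle)  # lowest-coordinate CDS base
    if (t$strand == "-")
      expect_equal(map_genomic_to_cds(t, last_low), length(oracle) - 1L)
  }
  # intronic and out-of-slice
  expect_null(map_genomic_to_cds(loc$t1, 450L))
  expect_null(map_genomic_to_cds(loc$t1, 50L))
  expect_error(map_genomic_to_cds(loc$t1, 2000L), "outside the genome slice")
})

test_that("codon consequences reproduce the designed substitutions", {
  loc <- toy_locus()
  # codon 139 = GAT in exon 2; A->T transversion at codon position 2
  cq <- call_codon_consequence(loc$t1, list(pos = 616L, ref = "A", alts = "T"))
  expect_equal(cq$kind, "missense")
  expect_equal(cq$label, "D139V")
  # codon 48 = CAA; C->T gives the stop gain Q48X
  cq <- call_codon_consequence(loc$t1, list(pos = 242L, ref = "C", alts = "T"))
  expect_equal(cq$kind, "stop_gain")
  expect_equal(cq$label, "Q48X")
  # codon 150 = GCT; third-position T->C stays alanine
  cq <- call_codon_consequence(loc$t1, list(pos = 650L, ref = "T", alts = "C"))
  expect_equal(cq$kind, "synonymous")
  # non-SNVs are an explicit error, never a silent skip
  expect_error(call_codon_consequence(loc$t1, list(pos = 616L, ref = "AA",
                                                   alts = "T")),
               "unsupported variant")
  # declared REF must match the slice
  expect_error(call_codon_consequence(loc$t1, list(pos = 616L, ref = "C",
                                                   alts = "T")),
               "reference mismatch")
})

test_that("isoform-aware annotation separates the two isoforms", {
  loc <- toy_locus()
  # T2 codon 202 = GGT at 1254-1256, inside T1's intron
  ann <- annotate_variant(list(pos = 1255L, ref = "G", alts = "T"),
                          list(loc$t1, loc$t2))
  expect_equal(ann$kind, c("intronic", "missense"))
  expect_equal(ann$label[2], "G202V")
  # shared exon 1: same consequence coordinates in both isoforms
  ann <- annotate_variant(list(pos = 616L, ref = "A", alts = "T"),
                          list(loc$t1, loc$t2))
  expect_equal(ann$kind, c("missense", "intronic"))
  # upstream of both CDSs
  ann <- annotate_variant(list(pos = 50L, ref = "C", alts = "A"),
                          list(loc$t1, loc$t2))
  expect_equal(ann$kind, c("non_coding", "non_coding"))
})

test_that("shared exon read in different frames gives different protein_pos", {
  seq <- paste0("ATG", "GCTGGACTG", "AAAGAAGCT", "TAA")  # 24 nt
  ta <- transcript_model("TA", "g", "+", data.frame(start = 1, end = 24),
                         1, 24, seq, 1)
  tb <- transcript_model("TB", "g", "+", data.frame(start = 1, end = 24),
                         5, 22, seq, 1, strict = FALSE)
  ann <- annotate_variant(list(pos = 8L, ref = "G", alts = "C"),
                          list(ta, tb))
  expect_true(all(ann$kind %in% c("missense", "synonymous")))
  expect_true(ann$protein_pos[1] != ann$protein_pos[2])
})

test_that("consequence calls agree with the translate-and-diff oracle", {
  loc <- toy_locus()
  set.seed(42)
  for (t in list(loc$t1, loc$t2)) {
    oracle_pos <- cds_positions_oracle(t)
    probe <- sample(oracle_pos, 40)
    g <- strsplit(t$seq, "")[[1]]
    for (p in probe) {
      ref <- g[p]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- call_codon_consequence(t, list(pos = p, ref = ref, alts = alt))
      want <- consequence_oracle(t, p, ref, alt)
      expect_equal(got$kind, want$kind)
      if (want$kind != "synonymous") {
        expect_equal(got$protein_pos, want$protein_pos)
        expect_equal(got$ref_aa, want$ref_aa)
        expect_equal(got$alt_aa, want$alt_aa)
      }
    }
  }
})

test_that("strand symmetry: mirrored locus yields identical consequences", {
  loc <- toy_locus()
  L <- nchar(loc$seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- flip_locus(loc$t1)
  set.seed(7)
  probe <- sample(cds_positions_oracle(loc$t1), 25)
  g <- strsplit(loc$seq, "")[[1]]
  for (p in probe) {
    ref <- g[p]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- call_codon_consequence(loc$t1, list(pos = p, ref = ref, alts = alt))
    rev <- call_codon_consequence(flipped,
                                  list(pos = L - p + 1L,
                                       ref = unname(comp[ref]),
                                       alts = unname(comp[alt])))
    expect_equal(fwd[c("kind", "protein_pos", "ref_aa", "alt_aa", "label")],
                 rev[c("kind", "protein_pos", "ref_aa", "alt_aa", "label")])
  }
})

test_that("transcript table round-trips through the TSV format", {
  loc <- toy_locus()
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">locus", loc$seq), fa)
  write_transcript_table(list(loc$t1, loc$t2), tsv,
                         seq_ids = c("locus", "locus"))
  back <- read_transcript_table(tsv, fa)
  expect_equal(length(back), 2)
  expect_equal(spliced_cds(back[[1]]), spliced_cds(loc$t1))
  expect_equal(back[[2]]$exons, loc$t2$exons)
  expect_equal(protein_length(back[[1]]), 260L)
  expect_equal(protein_length(back[[2]]), 220L)
})

test_that("transcript validation enforces structure", {
  seq <- strrep("A", 100)
  expect_error(transcript_model("t", "g", "+",
                                data.frame(start = c(1, 5), end = c(10, 20)),
                                1, 20, seq, 1),
               "overlap")
  expect_error(transcript_model("t", "g", "+",
                                data.frame(start = 1, end = 10),
                                1, 8, seq, 1, strict = FALSE),
               "not divisible by 3")
  expect_error(transcript_model("t", "g", "+",
                                data.frame(start = 1, end = 12),
                                1, 12, paste0("AAAGCTGCTGCT", strrep("A", 20)), 1),
               "start codon")
})

test_that("domain classification follows the configured map", {
  dm <- mlkl_domain_map("mouse")
  expect_equal(classify_domain(139, dm), "brace")
  expect_equal(classify_domain(30, dm), "4HB")
  expect_equal(classify_domain(300, dm), "pseudokinase")
  expect_error(classify_domain(9999, dm), "outside protein")
  expect_error(classify_domain(0, dm), "outside protein")
  # config-driven map with a hole
  cfg <- write_lines_tmp(c("# toy map", "length=100", "nterm=1-40",
                           "cterm=61-100"))
  dm2 <- read_domain_map(cfg)
  expect_equal(classify_domain(50, dm2), "unassigned")
  expect_equal(classify_domain(61, dm2), "cterm")
  expect_error(domain_map(data.frame(name = c("a", "b"), start = c(1, 10),
                                     end = c(12, 20)), 30),
               "overlap")
})
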