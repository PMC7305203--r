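# GT-only VCF reader/writer.
#
# The pipeline needs exactly five fixed columns (CHROM/POS/ID/REF/ALT) plus
# the GT subfield of every sample, with the phase separator ("|" vs "/")
# preserved bit-for-bit; all other FORMAT subfields and INFO are opaque.
# VariantAnnotation's readVcf() is deliberately not used here: it requires
# contig/header metadata our synthetic files do not carry, and it does not
# give the line-numbered parse errors this layer contracts to provide.
# The reader is lenient about the v4.1/v4.2/v4.3 dialect differences (none
# of which touch the columns used).

VALID_ALLELE_RE <- "^[ACGTN]+$"

#' Cohort genotype container
#'
#' Holds a set of variant records plus per-sample genotype calls with
#' explicit phase state. Genotypes are stored as two allele-index matrices
#' (`a1`, `a2`, sites x samples, `NA` = missing) and a logical `phased`
#' matrix derived solely from the GT separator (`"|"` vs `"/"`).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `id` (`NA` allowed), `ref`, and `alts` (list column of character
#'   vectors). Alleles must be non-empty strings over `{A,C,G,T,N}` and
#'   every alt must differ from its ref.
#' @param samples character vector of sample identifiers.
#' @param a1,a2 integer matrices, one row per variant, one column per
#'   sample; entries in `[0, n_alts]` or `NA`.
#' @param phased logical matrix of the same shape; may be `TRUE` only
#'   where both allele indices are present.
#' @param meta character vector of `##` header lines carried through
#'   opaquely.
#' @return An object of class `cohort_vcf`.
#' @export
cohort_vcf <- function(variants, samples = character(), a1 = NULL, a2 = NULL,
                       phased = NULL, meta = character()) {
  n <- nrow(variants)
  m <- length(samples)
  if (is.null(a1)) a1 <- matrix(NA_integer_, n, m)
  if (is.null(a2)) a2 <- matrix(NA_integer_, n, m)
  if (is.null(phased)) phased <- matrix(FALSE, n, m)
  obj <- structure(
    list(variants = variants, samples = as.character(samples),
         a1 = a1, a2 = a2, phased = phased, meta = meta),
    class = "cohort_vcf"
  )
  validate_cohort_vcf(obj)
  obj
}

validate_cohort_vcf <- function(x) {
  v <- x$variants
  req <- c("chrom", "pos", "id", "ref", "alts")
  if (!all(req %in% names(v)))
    stop("variants must have columns ", paste(req, collapse = ", "))
  if (any(v$pos < 1)) stop("POS must be >= 1")
  if (!all(grepl(VALID_ALLELE_RE, v$ref)))
    stop("REF alleles must be non-empty strings over {A,C,G,T,N}")
  for (i in seq_len(nrow(v))) {
    alts <- v$alts[[i]]
    if (length(alts) == 0) stop("record ", i, ": ALT list empty")
    if (!all(grepl(VALID_ALLELE_RE, alts)))
      stop("record ", i, ": ALT alleles must be over {A,C,G,T,N}")
    if (anyDuplicated(alts) || any(alts == v$ref[i]))
      stop("record ", i, ": ALT alleles must be distinct from REF and each other")
  }
  dims_ok <- all(dim(x$a1) == c(nrow(v), length(x$samples))) &&
    all(dim(x$a2) == dim(x$a1)) && all(dim(x$phased) == dim(x$a1))
  if (!dims_ok) stop("genotype matrix dimensions inconsistent with variants/samples")
  n_alt <- vapply(v$alts, length, 1L)
  for (i in seq_len(nrow(v))) {
    ai <- c(x$a1[i, ], x$a2[i, ])
    if (any(ai[!is.na(ai)] < 0 | ai[!is.na(ai)] > n_alt[i]))
      stop("record ", i, ": allele index out of range")
  }
  bad_phase <- x$phased & (is.na(x$a1) | is.na(x$a2))
  if (any(bad_phase)) stop("phased flag set on a missing call")
  invisible(x)
}

#' @export
print.cohort_vcf <- function(x, ...) {
  cat("<cohort_vcf> ", nrow(x$variants), " site(s) x ", length(x$samples),
      " sample(s)\n", sep = "")
  invisible(x)
}

#' Extract one genotype call
#'
#' @param x a [cohort_vcf()] object
#' @param site variant row index
#' @param sample sample name or column index
#' @return list with `sample_id`, `a` (length-2 integer vector of allele
#'   indices, `NA` = missing) and `phased`; class `genotype_call`.
#' @export
genotype_call <- function(x, site, sample) {
  j <- if (is.character(sample)) match(sample, x$samples) else sample
  if (is.na(j)) stop("unknown sample: ", sample)
  structure(
    list(sample_id = x$samples[j],
         a = c(x$a1[site, j], x$a2[site, j]),
         phased = x$phased[site, j]),
    class = "genotype_call"
  )
}

#' @rdname genotype_call
#' @param g a `genotype_call`
#' @export
gt_is_missing <- function(g) anyNA(g$a)

parse_gt_token <- function(tok, n_alt, lineno) {
  # returns c(a1, a2, phased); "." in either slot makes the whole call missing
  if (tok == "." || tok == "./." || tok == ".|.")
    return(c(NA_integer_, NA_integer_, 0L))
  m <- regmatches(tok, regexec("^(\\.|[0-9]+)([/|])(\\.|[0-9]+)$", tok))[[1]]
  if (length(m) == 0)
    stop("VCF parse error at line ", lineno, ": bad GT '", tok, "'")
  if (m[2] == "." || m[4] == ".")
    return(c(NA_integer_, NA_integer_, 0L))
  a <- c(as.integer(m[2]), as.integer(m[4]))
  if (any(a > n_alt))
    stop("VCF parse error at line ", lineno, ": allele index ", max(a),
         " exceeds ALT count ", n_alt)
  c(a, if (m[3] == "|") 1L else 0L)
}

#' Read a VCF file (GT-only guarantees)
#'
#' Parses a VCF v4.x text file into a [cohort_vcf()]. Only
#' CHROM/POS/ID/REF/ALT and the GT subfield are interpreted; the phase
#' flag of each call reflects the GT separator and nothing else.
#' Multi-allelic sites are retained unsplit.
#'
#' @param path path to an uncompressed VCF text file
#' @return a `cohort_vcf`
#' @export
read_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("VCF parse error: empty file")
  is_meta <- startsWith(lines, "##")
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1)
    stop("VCF parse error: expected exactly one #CHROM header line")
  if (any(!is_meta[seq_len(hdr_i - 1)]))
    stop("VCF parse error at line ", which(!is_meta[seq_len(hdr_i - 1)])[1],
         ": non-meta line before #CHROM header")
  if (!any(grepl("^##fileformat=VCFv4", lines[is_meta])))
    warning("no ##fileformat=VCFv4.x meta line; parsing leniently")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 8)
    stop("VCF parse error at line ", hdr_i, ": header has fewer than 8 columns")
  samples <- if (length(hdr) > 9) hdr[-(1:9)] else character()
  want_n <- if (length(samples)) 9L + length(samples) else length(hdr)

  data_idx <- setdiff(seq_along(lines), c(which(is_meta), hdr_i))
  data_idx <- data_idx[nzchar(lines[data_idx])]
  n <- length(data_idx)
  chrom <- character(n); pos <- integer(n); id <- character(n)
  ref <- character(n); alts <- vector("list", n)
  a1 <- matrix(NA_integer_, n, length(samples))
  a2 <- matrix(NA_integer_, n, length(samples))
  ph <- matrix(FALSE, n, length(samples))

  for (k in seq_len(n)) {
    ln <- data_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != want_n)
      stop("VCF parse error at line ", ln, ": expected ", want_n,
           " fields, found ", length(f))
    chrom[k] <- f[1]
    pos[k] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[k]))
      stop("VCF parse error at line ", ln, ": bad POS '", f[2], "'")
    id[k] <- if (f[3] == ".") NA_character_ else f[3]
    ref[k] <- toupper(f[4])
    alts[[k]] <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    if (length(samples)) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gi <- match("GT", keys)
      if (is.na(gi))
        stop("VCF format error at line ", ln, ": GT absent from FORMAT")
      for (j in seq_along(samples)) {
        tok <- strsplit(f[9 + j], ":", fixed = TRUE)[[1]][gi]
        g <- parse_gt_token(tok, length(alts[[k]]), ln)
        a1[k, j] <- g[1]; a2[k, j] <- g[2]; ph[k, j] <- g[3] == 1L
      }
    }
  }
  variants <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                         stringsAsFactors = FALSE)
  variants$alts <- alts
  cohort_vcf(variants, samples, a1, a2, ph, meta = lines[is_meta])
}

#' Write a [cohort_vcf()] to disk
#'
#' Emits a minimal VCF v4.2 file. QUAL/FILTER/INFO are written as `.`;
#' FORMAT is `GT`; phased calls use the `|` separator. Reading the
#' result back yields an identical structure for the fields this layer
#' interprets.
#'
#' @param x a `cohort_vcf`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  validate_cohort_vcf(x)
  meta <- x$meta
  if (!any(grepl("^##fileformat=", meta)))
    meta <- c("##fileformat=VCFv4.2", meta)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(x$samples)) hdr <- c(hdr, "FORMAT", x$samples)
  out <- c(meta, paste(hdr, collapse = "\t"))
  v <- x$variants
  for (i in seq_len(nrow(v))) {
    fixed <- c(v$chrom[i], v$pos[i],
               if (is.na(v$id[i])) "." else v$id[i],
               v$ref[i], paste(v$alts[[i]], collapse = ","), ".", ".", ".")
    if (length(x$samples)) {
      gts <- ifelse(is.na(x$a1[i, ]) | is.na(x$a2[i, ]), "./.",
                    paste0(x$a1[i, ], ifelse(x$phased[i, ], "|", "/"), x$a2[i, ]))
      fixed <- c(fixed, "GT", gts)
    }
    out <- c(out, paste(fixed, collapse = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Assemble a cohort from per-record call lists
#'
#' Convenience constructor for callers that build records one at a time.
#' Every record must carry calls for the same sample set (in any order);
#' inconsistent sample sets are an error.
#'
#' @param records list; each element a list with `chrom`, `pos`, `id`,
#'   `ref`, `alts`, and `calls` (a named list, sample id -> list(a =
#'   c(i, j), phased = logical))
#' @return a `cohort_vcf`
#' @export
cohort_vcf_from_records <- function(records) {
  if (length(records) == 0) {
    v <- data.frame(chrom = character(), pos = integer(), id = character(),
                    ref = character(), stringsAsFactors = FALSE)
    v$alts <- list()
    return(cohort_vcf(v, samples = character()))
  }
  samples <- sort(names(records[[1]]$calls))
  for (r in records) {
    if (!identical(sort(names(r$calls)), samples))
      stop("inconsistent sample sets across records")
  }
  n <- length(records)
  variants <- data.frame(
    chrom = vapply(records, function(r) r$chrom, ""),
    pos = vapply(records, function(r) as.integer(r$pos), 1L),
    id = vapply(records, function(r) r$id %||% NA_character_, ""),
    ref = vapply(records, function(r) r$ref, ""),
    stringsAsFactors = FALSE
  )
  variants$alts <- lapply(records, function(r) r$alts)
  a1 <- matrix(NA_integer_, n, length(samples))
  a2 <- matrix(NA_integer_, n, length(samples))
  ph <- matrix(FALSE, n, length(samples))
  for (i in seq_len(n)) {
    for (j in seq_along(samples)) {
      cl <- records[[i]]$calls[[samples[j]]]
      a1[i, j] <- cl$a[1]; a2[i, j] <- cl$a[2]
      ph[i, j] <- isTRUE(cl$phased)
    }
  }
  cohort_vcf(variants, samples, a1, a2, ph)
}
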