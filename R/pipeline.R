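# One-command reproduction pathways: annotate -> comphet -> enrich, and
# the litter-table report. Reports are plain TSV with a one-line
# header; every numeric cell is recomputable from the per-stage tables
# (no hidden state), and identical configs give byte-identical outputs.

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the case/control enrichment pipeline
#'
#' Validates the configuration, then executes three stages: optional
#' isoform annotation of the variant set, compound-het counting in the
#' case and control cohorts, and the enrichment statistics. Emits a
#' per-variant frequency table, a per-individual compound-het table, a
#' one-row enrichment table, and a run log. A stage failure aborts
#' with the failing stage named and removes partial outputs.
#'
#' @param config list with `case_vcf`, `control_vcf` (paths), `sites`
#'   (character vector `"chrom:pos:alt"`), `out_dir`, and optionally
#'   `case_ped`, `control_ped`, `population`, `control_label`,
#'   `transcripts` + `sequences` (paths enabling the annotation stage),
#'   `seed` (echoed into the log)
#' @return invisibly, a list with the in-memory report tables
#' @export
run_enrichment_pipeline <- function(config) {
  for (f in c("case_vcf", "control_vcf")) {
    if (is.null(config[[f]]))
      comphet_validation_error(paste0("config field '", f, "' is required"))
    if (!file.exists(config[[f]]))
      comphet_validation_error(paste0(f, " file not found: ", config[[f]]))
  }
  if (length(config$sites %||% character()) == 0)
    comphet_validation_error("variant set ('sites') must be non-empty")
  if (is.null(config$out_dir))
    comphet_validation_error("config field 'out_dir' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  written <- character()
  log_lines <- character()
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  logmsg("comphet ", as.character(packageVersion("comphet")),
         "; seed=", config$seed %||% "none")

  case_vcf <- stage("load", read_vcf(config$case_vcf))
  ctrl_vcf <- stage("load", read_vcf(config$control_vcf))
  if (length(case_vcf$samples) == 0)
    comphet_validation_error("case cohort is empty")
  if (length(ctrl_vcf$samples) == 0)
    comphet_validation_error("control cohort is empty")
  case_ped <- if (!is.null(config$case_ped)) read_pedigree(config$case_ped)
  ctrl_ped <- if (!is.null(config$control_ped)) read_pedigree(config$control_ped)

  consequences <- NULL
  if (!is.null(config$transcripts)) {
    consequences <- stage("annotate", {
      tx <- read_transcript_table(config$transcripts, config$sequences)
      rs <- resolve_sites(case_vcf, config$sites)
      rows <- lapply(seq_along(rs$row), function(i) {
        v <- case_vcf$variants[rs$row[i], ]
        ann <- annotate_variant(list(pos = v$pos, ref = v$ref,
                                     alts = v$alts[[1]]), tx, rs$alt[i])
        cbind(data.frame(chrom = v$chrom, pos = v$pos,
                         alt = v$alts[[1]][rs$alt[i]],
                         stringsAsFactors = FALSE), ann)
      })
      do.call(rbind, rows)
    })
    written <- c(written, write_tsv(consequences, out("consequences.tsv")))
  } else {
    logmsg("stage annotate: skipped (no transcript models configured)")
  }

  comphet_tables <- stage("comphet", {
    cc_case <- count_compound_hets(case_vcf, config$sites, case_ped,
                                   config$population)
    cc_ctrl <- count_compound_hets(ctrl_vcf, config$sites, ctrl_ped,
                                   config$population)
    list(case = cc_case, ctrl = cc_ctrl)
  })
  per_ind <- rbind(
    cbind(cohort = "case", comphet_tables$case$individuals),
    cbind(cohort = "control", comphet_tables$ctrl$individuals)
  )
  written <- c(written, write_tsv(per_ind, out("comphet_calls.tsv")))

  freq_table <- stage("comphet", {
    rs <- resolve_sites(case_vcf, config$sites)
    rows <- lapply(seq_along(rs$row), function(i) {
      v <- case_vcf$variants[rs$row[i], ]
      maf_for <- function(vcf) {
        rs2 <- resolve_sites(vcf, sprintf("%s:%d:%s", v$chrom, v$pos,
                                          v$alts[[1]][rs$alt[i]]))
        calls <- lapply(vcf$samples, function(s)
          genotype_call(vcf, rs2$row[1], s))
        allele_frequency(calls, rs2$alt[1])
      }
      data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                 ref = v$ref, alt = v$alts[[1]][rs$alt[i]],
                 case_maf = maf_for(case_vcf),
                 control_maf = maf_for(ctrl_vcf),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  written <- c(written, write_tsv(freq_table, out("variant_frequencies.tsv")))

  enrich_row <- stage("enrich", enrichment_report(
    comphet_tables$case$count, comphet_tables$case$n,
    comphet_tables$ctrl$count, comphet_tables$ctrl$n,
    population = config$population %||% "all",
    control_label = config$control_label %||% "controls"
  ))
  written <- c(written, write_tsv(enrich_row, out("enrichment.tsv")))

  logmsg("pipeline complete; outputs in ", config$out_dir)
  writeLines(log_lines, out("run_log.txt"))
  invisible(list(consequences = consequences, frequencies = freq_table,
                 individuals = per_ind, enrichment = enrich_row))
}

#' Litter segregation report
#'
#' For each column of observed genotype counts (classes x columns),
#' reports the total genotyped, real and rounded expected counts under
#' the cross ratio, the goodness-of-fit chi-square, and the exact
#' binomial depletion probability of each class.
#'
#' @param observed numeric matrix (rows: genotype classes, columns:
#'   litters/conditions) or a vector for a single column
#' @param ratio segregation ratio (e.g. `c(1, 2, 1)` or `"1:2:1"`)
#' @return data.frame, one row per column
#' @export
run_table1_report <- function(observed, ratio = c(1, 2, 1)) {
  if (is.null(dim(observed))) observed <- matrix(observed, ncol = 1)
  r <- parse_ratio(ratio)
  if (nrow(observed) != length(r))
    comphet_validation_error("observed rows must match ratio classes")
  if (any(colSums(observed) == 0))
    comphet_validation_error("all-zero observed column")
  p0 <- r / sum(r)
  rows <- lapply(seq_len(ncol(observed)), function(j) {
    obs <- observed[, j]
    total <- sum(obs)
    ec <- expected_counts(total, r)
    gg <- gof_chisq(obs, r)
    row <- data.frame(column = colnames(observed)[j] %||% as.character(j),
                      total = total, chisq = gg$statistic, df = gg$df,
                      p = gg$p, stringsAsFactors = FALSE)
    for (i in seq_along(obs)) {
      row[[paste0("obs", i)]] <- obs[i]
      row[[paste0("exp", i)]] <- ec$expected[i]
      row[[paste0("exp_rounded", i)]] <- ec$rounded[i]
      row[[paste0("absence_p", i)]] <- absence_probability(obs[i], total, p0[i])
    }
    row
  })
  do.call(rbind, rows)
}
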