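# Protein domain classification. Boundaries are config-driven: the killer
# four-helix bundle (4HB), the two-helix brace that restrains it, and the
# pseudokinase domain. Shipped defaults follow the mouse construct
# boundaries (4HB 1-125, 4HB+brace 1-180); the human boundaries are
# configurable approximations, not literature-exact.

#' Build a domain map
#'
#' @param ranges data.frame with `name`, `start`, `end` (1-based
#'   inclusive residue numbers, non-overlapping)
#' @param protein_length total protein length the map applies to
#' @return object of class `domain_map`
#' @export
domain_map <- function(ranges, protein_length) {
  ranges <- ranges[order(ranges$start), , drop = FALSE]
  if (any(ranges$start < 1) || any(ranges$end > protein_length))
    stop("domain ranges must lie within [1, ", protein_length, "]")
  if (any(ranges$end < ranges$start)) stop("domain end < start")
  if (nrow(ranges) > 1 && any(ranges$start[-1] <= ranges$end[-nrow(ranges)]))
    stop("domain ranges overlap")
  structure(list(ranges = ranges, protein_length = as.integer(protein_length)),
            class = "domain_map")
}

#' Default MLKL domain maps
#'
#' Mouse boundaries (4HB 1-125, brace 126-180, pseudokinase 181-464)
#' follow the construct definitions used for the mouse protein; human
#' boundaries (471 aa canonical protein) are configurable approximations
#' of the equivalent regions.
#'
#' @param species `"mouse"` or `"human"`
#' @return a [domain_map()]
#' @export
mlkl_domain_map <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  if (species == "mouse") {
    domain_map(data.frame(name = c("4HB", "brace", "pseudokinase"),
                          start = c(1L, 126L, 181L),
                          end = c(125L, 180L, 464L)), 464L)
  } else {
    domain_map(data.frame(name = c("4HB", "brace", "pseudokinase"),
                          start = c(1L, 126L, 183L),
                          end = c(125L, 182L, 471L)), 471L)
  }
}

#' Classify a residue into its domain
#'
#' @param protein_pos residue number (1-based)
#' @param dm a [domain_map()]
#' @return the containing range's name, or `"unassigned"`
#' @export
classify_domain <- function(protein_pos, dm) {
  if (protein_pos < 1 || protein_pos > dm$protein_length)
    stop("residue ", protein_pos, " outside protein [1, ",
         dm$protein_length, "]")
  hit <- dm$ranges$name[protein_pos >= dm$ranges$start &
                          protein_pos <= dm$ranges$end]
  if (length(hit)) hit[1] else "unassigned"
}

#' Read a domain map from a key-value config file
#'
#' Format: one `name=start-end` pair per line, plus a mandatory
#' `length=N` line; `#` comments and blank lines ignored.
#'
#' @param path config file
#' @return a [domain_map()]
#' @export
read_domain_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  li <- match("length", keys)
  if (is.na(li)) stop("domain map config must contain a 'length=' line")
  plen <- as.integer(vals[li])
  keys <- keys[-li]; vals <- vals[-li]
  iv <- do.call(rbind, lapply(strsplit(vals, "-", fixed = TRUE),
                              function(x) as.integer(x)))
  domain_map(data.frame(name = keys, start = iv[, 1], end = iv[, 2]), plen)
}
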