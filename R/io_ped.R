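# 6-column PED dialect: FAM IID PAT MAT SEX PHENO, whitespace-delimited,
# "0" = unknown parent, PHENO 2 = affected. The family column doubles as
# the population/ancestry label for cohort stratification (ancestry labels
# are inputs to this pipeline, never inferred).

#' Read a pedigree file
#'
#' @param path 6+ column whitespace-delimited PED file
#' @return data.frame of class `pedigree` with columns `family`, `id`,
#'   `father`, `mother` (`NA` = unknown), `sex`, `phenotype`, `affected`
#'   and `population` (copied from `family`).
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(d) < 6)
    stop("PED parse error: expected >= 6 columns, found ", ncol(d))
  ped <- data.frame(
    family = d[[1]], id = d[[2]],
    father = ifelse(d[[3]] == "0", NA_character_, d[[3]]),
    mother = ifelse(d[[4]] == "0", NA_character_, d[[4]]),
    sex = d[[5]], phenotype = d[[6]],
    stringsAsFactors = FALSE
  )
  ped$affected <- ped$phenotype == "2"
  ped$population <- ped$family
  if (anyDuplicated(ped$id))
    stop("PED error: duplicate individual id '",
         ped$id[duplicated(ped$id)][1], "'")
  check_pedigree_cycles(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

check_pedigree_cycles <- function(ped) {
  # walk parent links from every individual; an individual reachable from
  # itself (incl. listed as its own parent) is a cycle
  parent_map <- setNames(
    mapply(function(f, m) c(f, m), ped$father, ped$mother, SIMPLIFY = FALSE),
    ped$id
  )
  for (start in ped$id) {
    frontier <- parent_map[[start]]
    seen <- character()
    while (length(frontier)) {
      frontier <- unique(frontier[!is.na(frontier)])
      if (start %in% frontier)
        stop("PED error: individual '", start, "' is its own ancestor")
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unlist(parent_map[intersect(frontier, names(parent_map))])
    }
  }
  invisible(TRUE)
}

#' Write a pedigree back out as 6-column PED
#' @param ped a [read_pedigree()] result (or compatible data.frame)
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    ped$sex, ped$phenotype
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up the parents of one individual
#' @param ped pedigree
#' @param id individual id
#' @return list(father =, mother =) with `NA` for unknown
#' @export
parents_of <- function(ped, id) {
  i <- match(id, ped$id)
  if (is.na(i)) return(list(father = NA_character_, mother = NA_character_))
  list(father = ped$father[i], mother = ped$mother[i])
}
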