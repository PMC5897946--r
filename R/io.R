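#' Read a per-fish cohort table
#'
#' Delimited text (comma for `.csv`, tab for `.tsv`/`.txt`), one header
#' line, missing values empty or `NA`.  Mandatory columns are checked by
#' name, unknown columns are preserved, duplicate fish ids are an error.
#'
#' @param path File path.
#' @param required Character vector of mandatory columns
#'   (default `c("id", "strain", "family")`).
#' @return A tibble.
#' @export
read_cohort <- function(path, required = c("id", "strain", "family")) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if ("id" %in% names(tab) && anyDuplicated(tab$id))
    stop("duplicate fish id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  tibble::as_tibble(tab)
}

#' Write a cohort (or any) table as CSV/TSV
#'
#' @param table Data frame.
#' @param path Output path; `.csv` gets commas, anything else tabs.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write pedigree files
#'
#' CSV with columns `id`, `sire`, `dam` and optionally `strain`, `sex`;
#' unknown parents empty or `NA`.  Reading validates the pedigree.
#'
#' @param path File path.
#' @return `read_pedigree` returns a validated tibble.
#' @export
read_pedigree <- function(path) {
  ped <- read_cohort(path, required = c("id", "sire", "dam"))
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped Pedigree data frame.
#' @export
write_pedigree <- function(ped, path) write_cohort(ped, path)

#' Read a genotype matrix
#'
#' Rows are individuals (first column `id`), remaining columns are
#' markers.  Two dialects: unphased allele-1 dosage `0/1/2`, or phased
#' `"A|B"` pairs (dosage = number of `B` alleles; the phase itself is
#' returned in attribute `phased` as two character matrices).
#'
#' @param path CSV/TSV path.
#' @return Integer dosage matrix with rownames = ids.
#' @export
read_genotypes <- function(path) {
  tab <- read_cohort(path, required = "id")
  ids <- as.character(tab$id)
  cols <- setdiff(names(tab), "id")
  raw <- as.matrix(tab[, cols, drop = FALSE])
  if (any(grepl("|", raw, fixed = TRUE))) {
    a1 <- sub("\\|.*", "", raw)
    a2 <- sub(".*\\|", "", raw)
    g <- (a1 == "B") + (a2 == "B")
    mode(g) <- "integer"
    dimnames(g) <- list(ids, cols)
    attr(g, "phased") <- list(hap1 = matrix(a1, nrow(g),
                                            dimnames = dimnames(g)),
                              hap2 = matrix(a2, nrow(g),
                                            dimnames = dimnames(g)))
    return(g)
  }
  g <- raw
  mode(g) <- "integer"
  if (any(is.na(g) != is.na(raw)) || any(!g %in% c(0:2, NA)))
    stop("genotype values must be 0/1/2 or phased A|B")
  dimnames(g) <- list(ids, cols)
  g
}

#' @rdname read_genotypes
#' @param genotypes Dosage matrix (individuals x markers).
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- data.frame(id = rownames(genotypes), genotypes,
                    check.names = FALSE)
  write_cohort(tab, path)
}

#' Read / write a genetic map
#'
#' TSV with columns `linkage_group`, `marker_id`, `position_cM`
#' (internal names `marker` and `pos_cM` are accepted too).
#'
#' @param path File path.
#' @return Validated map tibble (`linkage_group`, `marker`, `pos_cM`).
#' @export
read_map <- function(path) {
  tab <- read_cohort(path, required = "linkage_group")
  nm <- names(tab)
  nm[nm == "marker_id"] <- "marker"
  nm[nm == "position_cM"] <- "pos_cM"
  names(tab) <- nm
  validate_map(tab)
  tibble::as_tibble(tab)
}

#' @rdname read_map
#' @param map Map table.
#' @export
write_map <- function(map, path) {
  out <- data.frame(linkage_group = map$linkage_group,
                    marker_id = map$marker, position_cM = map$pos_cM)
  write_cohort(out, path)
}

#' Write genome-scan results
#'
#' TSV with `linkage_group`, `position_cM`, `LRT` and, when a permutation
#' threshold has been attached, `genomewide_p` per position.
#'
#' @param scan A `scan_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  tab <- data.frame(linkage_group = scan$table$linkage_group,
                    position_cM = scan$table$pos_cM,
                    LRT = scan$table$lrt)
  if (!is.null(scan$perm_max))
    tab$genomewide_p <- vapply(tab$LRT, function(l)
      (1 + sum(scan$perm_max >= l)) / (length(scan$perm_max) + 1),
      numeric(1))
  write_cohort(tab, path)
  invisible(path)
}
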