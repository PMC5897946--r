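#' Validate a two-generation pedigree table
#'
#' Checks id uniqueness, that every recorded parent exists, that no
#' individual is its own ancestor (acyclicity, via Kahn's algorithm) and
#' that non-founders have both a sire and a dam.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (parents `NA`
#'   for founders) and optionally `strain`, `sex`.
#' @return The pedigree, invisibly, ordered so parents precede offspring.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("missing pedigree columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  par <- c(ped$sire, ped$dam)
  unknown <- setdiff(par[!is.na(par)], ped$id)
  if (length(unknown)) stop("parents not in pedigree: ",
                            paste(unique(unknown), collapse = ", "))
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent))
    stop("individuals with exactly one known parent: ",
         paste(ped$id[one_parent], collapse = ", "))
  # topological sort: repeatedly emit individuals whose parents are emitted
  remaining <- ped
  ordered <- ped[0, , drop = FALSE]
  done <- character(0)
  while (nrow(remaining)) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% done) &
             (is.na(remaining$dam) | remaining$dam %in% done)
    if (!any(ready)) stop("pedigree contains a cycle")
    ordered <- rbind(ordered, remaining[ready, , drop = FALSE])
    done <- c(done, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(ordered) <- NULL
  invisible(ordered)
}

#' Simulate a two-generation multi-strain half-sib pedigree
#'
#' Emulates a cross design in which each strain (or cross type)
#' contributes several full-sib families, with optional half-sib links:
#' consecutive families within a cross share a sire, so some parents
#' appear in two or more families — the structure that powers
#' half-sib variance-component QTL mapping.
#'
#' @param strains Character vector of strain/cross labels.
#' @param n_families_per_cross Families per strain (>= 1).
#' @param n_offspring_per_family Offspring per family (>= 1).
#' @param half_sib Share sires between consecutive families of a cross
#'   (default `TRUE`).
#' @param seed Optional integer seed (labels are deterministic anyway).
#' @return A tibble pedigree: `id`, `sire`, `dam`, `strain`, `sex`,
#'   `family` (`NA` for founders), `generation` (0 founders, 1 offspring),
#'   ordered parents-first.
#' @export
gen_pedigree <- function(strains, n_families_per_cross = 6,
                         n_offspring_per_family = 20, half_sib = TRUE,
                         seed = NULL) {
  if (length(strains) < 2) stop("at least 2 strains are required")
  if (n_families_per_cross < 1 || n_offspring_per_family < 1)
    stop("family and offspring counts must be >= 1")
  rows <- list()
  for (s in strains) {
    nf <- n_families_per_cross
    n_sires <- if (half_sib) max(1L, ceiling(nf / 2)) else nf
    sires <- sprintf("%s_S%d", s, seq_len(n_sires))
    dams <- sprintf("%s_D%d", s, seq_len(nf))
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = c(sires, dams), sire = NA_character_, dam = NA_character_,
      strain = s, sex = rep(c("M", "F"), c(n_sires, nf)),
      family = NA_character_, generation = 0L)
    for (f in seq_len(nf)) {
      fam <- sprintf("%s_F%d", s, f)
      sire_f <- sires[if (half_sib) (f - 1L) %/% 2L + 1L else f]
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("%s_O%d", fam, seq_len(n_offspring_per_family)),
        sire = sire_f, dam = dams[f], strain = s, sex = NA_character_,
        family = fam, generation = 1L)
    }
  }
  ped <- do.call(rbind, rows)
  validate_pedigree(ped)
  ped
}

#' Numerator (additive) relationship matrix from a pedigree
#'
#' Tabular method: individuals are processed parents-first;
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2`,
#' unknown parents contributing zero.  For non-inbred pedigrees the
#' diagonal is 1, parent-offspring and full sibs are 0.5, half sibs 0.25.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`); validated and
#'   topologically sorted internally.
#' @return Symmetric PSD matrix with dimnames = ids, in the input id
#'   order.
#' @export
additive_relationship <- function(ped) {
  ord <- validate_pedigree(ped)
  n <- nrow(ord)
  ids <- ord$id
  si <- match(ord$sire, ids)
  di <- match(ord$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                    (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(s) || is.na(d)) 0 else A[s, d])
  }
  A[ped$id, ped$id]
}
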