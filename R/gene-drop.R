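#' Build a regular sparse linkage map
#'
#' Markers placed at regular intervals on each linkage group, emulating a
#' sparse genome-wide SNP panel (the default approximates ~100 markers at
#' 25 cM spacing).
#'
#' @param n_lg Number of linkage groups.
#' @param markers_per_lg Markers per linkage group.
#' @param spacing_cM Distance between adjacent markers (cM).
#' @return Tibble `linkage_group`, `marker`, `pos_cM`.
#' @export
gen_map <- function(n_lg = 15, markers_per_lg = 7, spacing_cM = 25) {
  do.call(rbind, lapply(seq_len(n_lg), function(g) {
    tibble::tibble(
      linkage_group = sprintf("LG%02d", g),
      marker = sprintf("LG%02d_M%d", g, seq_len(markers_per_lg)),
      pos_cM = (seq_len(markers_per_lg) - 1) * spacing_cM)
  }))
}

validate_map <- function(map) {
  need <- c("linkage_group", "marker", "pos_cM")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("missing map columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$marker)) stop("duplicate marker ids in map")
  for (g in unique(map$linkage_group)) {
    p <- map$pos_cM[map$linkage_group == g]
    if (any(diff(p) <= 0))
      stop("map positions must be strictly increasing within ", g)
  }
  invisible(map)
}

#' Haldane map function
#'
#' Recombination fraction for a map distance `d` in cM, assuming no
#' interference: `(1 - exp(-2 * d / 100)) / 2`.
#'
#' @param d_cM Map distance in centimorgans (>= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn independently per marker from the
#' stated allele frequencies; each meiosis transmits a mosaic of the
#' parent's two haplotypes, switching between adjacent markers with the
#' Haldane recombination fraction for their map distance.  The parental
#' origin of every transmitted allele is recorded as ground truth.
#'
#' @param ped Two-generation pedigree (founders then offspring), as from
#'   [gen_pedigree()].
#' @param map Genetic map (see [gen_map()]); positions strictly
#'   increasing within linkage group.
#' @param founder_freqs Allele-1 frequency per marker: scalar recycled, or
#'   vector (optionally named by marker) of length `nrow(map)`.
#' @param seed Optional integer seed.
#' @return List of class `gene_drop`: `genotypes` (integer matrix,
#'   individuals x markers, allele-1 dosage 0/1/2), and `truth` with
#'   `sire_origin` / `dam_origin` (offspring x markers, 1 or 2 = which
#'   parental haplotype was transmitted) and the founder haplotypes.
#' @export
gen_genotypes <- function(ped, map, founder_freqs = 0.5, seed = NULL) {
  ord <- validate_pedigree(ped)
  validate_map(map)
  M <- nrow(map)
  freqs <- if (length(founder_freqs) == 1) rep(founder_freqs, M)
           else if (!is.null(names(founder_freqs)))
             founder_freqs[map$marker]
           else founder_freqs
  if (length(freqs) != M || any(is.na(freqs)) || any(freqs < 0 | freqs > 1))
    stop("founder_freqs must give a frequency in [0, 1] for every marker")
  run <- function() {
    ids <- ord$id
    n <- length(ids)
    founder <- is.na(ord$sire)
    # H1 = allele on the paternally-derived haplotype, H2 maternal
    H1 <- matrix(0L, n, M, dimnames = list(ids, map$marker))
    H2 <- H1
    nf <- sum(founder)
    H1[founder, ] <- matrix(stats::rbinom(nf * M, 1, rep(freqs, each = nf)),
                            nf, M)
    H2[founder, ] <- matrix(stats::rbinom(nf * M, 1, rep(freqs, each = nf)),
                            nf, M)
    offs <- which(!founder)
    lg_index <- split(seq_len(M), map$linkage_group)
    sire_origin <- matrix(NA_integer_, length(offs), M,
                          dimnames = list(ids[offs], map$marker))
    dam_origin <- sire_origin
    drop_origins <- function() {
      # one origin chain per meiosis per linkage group
      out <- matrix(NA_integer_, length(offs), M)
      for (cols in lg_index) {
        m <- length(cols)
        r <- haldane(diff(map$pos_cM[cols]))
        o <- matrix(0L, length(offs), m)
        o[, 1] <- stats::rbinom(length(offs), 1, 0.5)
        if (m > 1) {
          sw <- matrix(stats::rbinom(length(offs) * (m - 1), 1,
                                     rep(r, each = length(offs))),
                       length(offs), m - 1)
          o[, -1] <- sw
          o <- t(apply(o, 1, cumsum)) %% 2L
        }
        out[, cols] <- o + 1L
      }
      out
    }
    sire_origin[] <- drop_origins()
    dam_origin[] <- drop_origins()
    si <- match(ord$sire[offs], ids)
    di <- match(ord$dam[offs], ids)
    for (k in seq_along(offs)) {
      so <- sire_origin[k, ]
      H1[offs[k], ] <- ifelse(so == 1L, H1[si[k], ], H2[si[k], ])
      do <- dam_origin[k, ]
      H2[offs[k], ] <- ifelse(do == 1L, H1[di[k], ], H2[di[k], ])
    }
    structure(list(
      genotypes = (H1 + H2)[ped$id, , drop = FALSE],
      truth = list(sire_origin = sire_origin, dam_origin = dam_origin,
                   hap_paternal = H1, hap_maternal = H2,
                   founder_freqs = stats::setNames(freqs, map$marker))),
      class = "gene_drop")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
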