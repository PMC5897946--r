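#' Reconstruct parental-origin probabilities for every meiosis
#'
#' For each offspring and each parent (one meiosis per parent), infers the
#' probability that the transmitted allele came from the parent's first
#' haplotype, at every marker.  Single-marker rules first: when the parent
#' is heterozygous and the transmitted allele is resolvable from the trio
#' genotypes, the marker is informative (origin 0 or 1 relative to the
#' parent's reconstructed phase); otherwise it carries probability 0.5 in
#' isolation.  Origins are then propagated along each linkage group as a
#' two-state Markov chain with Haldane transition probabilities: an
#' uninformative marker takes the origin probability implied by its
#' nearest informative flanking markers.
#'
#' Parental phase is reconstructed per linkage group by chaining
#' heterozygous markers: adjacent het markers are oriented to maximize the
#' concordance of transmitted origins across all of the parent's meioses
#' (in a half-sib design a parent's meioses pool across its families).
#' Mendelian-inconsistent trios are flagged, the marker is set
#' uninformative for that meiosis, and a single summary warning is issued.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`).
#' @param genotypes Integer matrix of allele-1 dosage (0/1/2), rownames =
#'   ids, colnames = markers; must cover parents and offspring.
#' @param map Genetic map covering all genotype columns.
#' @return An object of class `haplo_assignment`: posterior origin
#'   matrices `p_sire`, `p_dam` (offspring x markers, `P(haplotype 1)`),
#'   logical `informative_sire` / `informative_dam`, `mendel_error`
#'   matrices, parent phases, and the per-meiosis informative-marker lists
#'   used for arbitrary-position queries by [origin_probs()].
#' @export
phase_offspring <- function(ped, genotypes, map) {
  ord <- validate_pedigree(ped)
  validate_map(map)
  markers <- map$marker
  if (!all(markers %in% colnames(genotypes)))
    stop("genotypes missing mapped markers")
  G <- genotypes[, markers, drop = FALSE]
  offs <- ord$id[!is.na(ord$sire)]
  if (!all(c(offs, ord$sire[!is.na(ord$sire)]) %in% rownames(G)))
    stop("genotypes missing pedigree individuals")
  M <- length(markers)
  lg_index <- split(seq_len(M), map$linkage_group)

  empty <- function(v) matrix(v, length(offs), M,
                              dimnames = list(offs, markers))
  res <- list(p_sire = empty(0.5), p_dam = empty(0.5),
              informative_sire = empty(FALSE), informative_dam = empty(FALSE),
              mendel_error = empty(FALSE))

  sire_of <- stats::setNames(ord$sire, ord$id)[offs]
  dam_of <- stats::setNames(ord$dam, ord$id)[offs]

  # -- transmitted alleles (NA = unresolvable), with Mendelian checks -----
  go <- G[offs, , drop = FALSE]
  gs <- G[sire_of, , drop = FALSE]
  gd <- G[dam_of, , drop = FALSE]
  t_s <- matrix(NA_integer_, length(offs), M)
  t_d <- t_s
  t_s[go == 0] <- 0L; t_d[go == 0] <- 0L
  t_s[go == 2] <- 1L; t_d[go == 2] <- 1L
  het <- go == 1
  t_s[het & gs == 0] <- 0L; t_d[het & gs == 0] <- 1L
  t_s[het & gs == 2] <- 1L; t_d[het & gs == 2] <- 0L
  amb <- het & gs == 1
  t_d[amb & gd == 0] <- 0L; t_s[amb & gd == 0] <- 1L
  t_d[amb & gd == 2] <- 1L; t_s[amb & gd == 2] <- 0L
  # impossible transmissions: required allele absent from the parent
  bad <- (!is.na(t_s) & ((t_s == 1 & gs == 0) | (t_s == 0 & gs == 2))) |
         (!is.na(t_d) & ((t_d == 1 & gd == 0) | (t_d == 0 & gd == 2)))
  if (any(bad)) {
    warning(sum(bad), " Mendelian-inconsistent trio genotype(s); ",
            "markers set uninformative for those meioses")
    res$mendel_error[bad] <- TRUE
    t_s[bad] <- NA_integer_
    t_d[bad] <- NA_integer_
  }

  # -- parent phase per linkage group -------------------------------------
  parents <- unique(c(sire_of, dam_of))
  phase <- matrix(NA_integer_, length(parents), M,
                  dimnames = list(parents, markers))
  for (p in parents) {
    gp <- G[p, ]
    as_sire <- which(sire_of == p)
    as_dam <- which(dam_of == p)
    # transmitted alleles over all of this parent's meioses
    tt <- rbind(t_s[as_sire, , drop = FALSE], t_d[as_dam, , drop = FALSE])
    for (cols in lg_index) {
      hets <- cols[gp[cols] == 1]
      if (!length(hets)) next
      ph <- integer(length(hets))
      ph[1] <- 1L
      if (length(hets) > 1) {
        for (k in 2:length(hets)) {
          # orient against the nearest previous het with shared data
          ph[k] <- 1L
          for (prev in rev(seq_len(k - 1))) {
            both <- !is.na(tt[, hets[prev]]) & !is.na(tt[, hets[k]])
            if (!any(both)) next
            conc <- mean((tt[both, hets[prev]] == ph[prev]) ==
                         (tt[both, hets[k]] == 1L))
            if (conc < 0.5) ph[k] <- 0L
            break
          }
        }
      }
      phase[p, hets] <- ph
    }
  }

  # -- origins at informative markers, then Markov interpolation ----------
  fill_role <- function(t_mat, parent_of, p_slot, inf_slot) {
    info_list <- vector("list", length(offs))
    names(info_list) <- offs
    for (k in seq_along(offs)) {
      p <- parent_of[k]
      orig <- ifelse(G[p, ] == 1 & !is.na(t_mat[k, ]),
                     as.integer(t_mat[k, ] == phase[p, ]), NA_integer_)
      res[[inf_slot]][k, ] <<- !is.na(orig)
      per_lg <- vector("list", length(lg_index))
      names(per_lg) <- names(lg_index)
      for (g in names(lg_index)) {
        cols <- lg_index[[g]]
        pos <- map$pos_cM[cols]
        inf <- which(!is.na(orig[cols]))
        per_lg[[g]] <- list(pos = pos[inf],
                            origin = orig[cols][inf])
        res[[p_slot]][k, cols] <<-
          .origin_interp(pos, pos[inf], orig[cols][inf])
      }
      info_list[[k]] <- per_lg
    }
    info_list
  }
  info_sire <- fill_role(t_s, sire_of, "p_sire", "informative_sire")
  info_dam <- fill_role(t_d, dam_of, "p_dam", "informative_dam")

  structure(c(res, list(info_sire = info_sire, info_dam = info_dam,
                        phase = phase, map = map,
                        offspring = offs, sire = sire_of, dam = dam_of)),
            class = "haplo_assignment")
}

# Posterior P(haplotype 1) at query positions, given informative markers
# (positions `ipos`, origins `iorig` in {0,1}) on one linkage group:
# two-state Markov chain under Haldane recombination; only the nearest
# informative marker on each side matters.
.origin_interp <- function(query, ipos, iorig) {
  if (!length(ipos)) return(rep(0.5, length(query)))
  li <- findInterval(query, ipos)                # nearest informative left
  ri <- length(ipos) - findInterval(-query, rev(-ipos))  # index - 1 of right
  p <- numeric(length(query))
  for (k in seq_along(query)) {
    L <- li[k]; R <- ri[k] + 1L
    has_l <- L >= 1
    has_r <- R <= length(ipos)
    if (has_l && has_r) {
      r1 <- haldane(query[k] - ipos[L])
      r2 <- haldane(ipos[R] - query[k])
      a1 <- if (iorig[L] == 1) 1 - r1 else r1
      b1 <- if (iorig[R] == 1) 1 - r2 else r2
      p[k] <- a1 * b1 / (a1 * b1 + (1 - a1) * (1 - b1))
    } else if (has_l) {
      r1 <- haldane(query[k] - ipos[L])
      p[k] <- if (iorig[L] == 1) 1 - r1 else r1
    } else if (has_r) {
      r2 <- haldane(ipos[R] - query[k])
      p[k] <- if (iorig[R] == 1) 1 - r2 else r2
    } else p[k] <- 0.5
  }
  p
}

#' Parental-origin probabilities at an arbitrary genomic position
#'
#' @param assignment A `haplo_assignment` from [phase_offspring()].
#' @param linkage_group Linkage group id.
#' @param pos_cM Position in cM, within the group's map range.
#' @return Matrix (offspring x 2, columns `p_sire`, `p_dam`) of posterior
#'   probabilities that the transmitted allele came from each parent's
#'   haplotype 1.
#' @export
origin_probs <- function(assignment, linkage_group, pos_cM) {
  stopifnot(inherits(assignment, "haplo_assignment"))
  map <- assignment$map
  sel <- map$linkage_group == linkage_group
  if (!any(sel)) stop("unknown linkage group: ", linkage_group)
  rng <- range(map$pos_cM[sel])
  if (pos_cM < rng[1] || pos_cM > rng[2])
    stop("position ", pos_cM, " cM is off the map of ", linkage_group)
  offs <- assignment$offspring
  out <- matrix(0.5, length(offs), 2,
                dimnames = list(offs, c("p_sire", "p_dam")))
  for (k in seq_along(offs)) {
    is <- assignment$info_sire[[k]][[linkage_group]]
    id <- assignment$info_dam[[k]][[linkage_group]]
    out[k, 1] <- .origin_interp(pos_cM, is$pos, is$origin)
    out[k, 2] <- .origin_interp(pos_cM, id$pos, id$origin)
  }
  out
}

#' Identity-by-descent matrix at a genomic position
#'
#' Expected proportion of alleles shared identical-by-descent between
#' every pair of individuals at a position, from the parental-origin
#' probabilities of [phase_offspring()].  Each shared parent contributes
#' one half times the probability that the two offspring inherited the
#' same parental haplotype; founders are assumed unrelated and non-inbred
#' (off-diagonal 0, diagonal 1), and a parent-offspring pair shares 1/2.
#'
#' @param assignment A `haplo_assignment`.
#' @param ped The pedigree used for phasing.
#' @param linkage_group,pos_cM Genomic position (must be on the map).
#' @param ids Individuals to include (default: the phased offspring).
#' @return Symmetric matrix with entries in `[0, 1]`, dimnames = `ids`.
#' @export
ibd_matrix <- function(assignment, ped, linkage_group, pos_cM,
                       ids = assignment$offspring) {
  op <- origin_probs(assignment, linkage_group, pos_cM)
  n <- length(ids)
  sire <- stats::setNames(ped$sire, ped$id)[ids]
  dam <- stats::setNames(ped$dam, ped$id)[ids]
  ps <- rep(NA_real_, n); pd <- rep(NA_real_, n)
  in_op <- ids %in% rownames(op)
  ps[in_op] <- op[ids[in_op], "p_sire"]
  pd[in_op] <- op[ids[in_op], "p_dam"]
  same <- function(p) {
    p0 <- ifelse(is.na(p), 0.5, p)
    outer(p0, p0) + outer(1 - p0, 1 - p0)
  }
  share_s <- outer(sire, sire, `==`)
  share_s[is.na(share_s)] <- FALSE
  share_d <- outer(dam, dam, `==`)
  share_d[is.na(share_d)] <- FALSE
  pi_mat <- 0.5 * same(ps) * share_s + 0.5 * same(pd) * share_d
  # parent-offspring pairs among the included ids
  po <- outer(ids, sire, `==`) | outer(ids, dam, `==`)
  po[is.na(po)] <- FALSE
  pi_mat[po | t(po)] <- 0.5
  diag(pi_mat) <- 1
  dimnames(pi_mat) <- list(ids, ids)
  pi_mat
}

#' IBD matrix from simulation ground truth
#'
#' Builds the position-wise IBD matrix from the true parental-origin
#' indicators recorded by [gen_genotypes()] — the fully informative
#' counterpart of [ibd_matrix()], used to separate the behaviour of the
#' variance-component estimator from haplotype-reconstruction noise in
#' parameter-recovery studies.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()] (or a list with
#'   `truth` and `pedigree`).
#' @param marker Marker id (default: the simulated QTL marker).
#' @param ids Individuals to include (default: the phenotyped cohort).
#' @return Symmetric IBD matrix, entries in `[0, 1]`, diagonal 1.
#' @export
true_ibd_matrix <- function(sim, marker = sim$truth$qtl_marker,
                            ids = sim$cohort$id) {
  so <- sim$truth$sire_origin
  do <- sim$truth$dam_origin
  if (!marker %in% colnames(so)) stop("unknown marker: ", marker)
  ped <- sim$pedigree
  sire <- stats::setNames(ped$sire, ped$id)[ids]
  dam <- stats::setNames(ped$dam, ped$id)[ids]
  ps <- 2 - so[ids, marker]  # P(haplotype 1) is exactly 0 or 1
  pd <- 2 - do[ids, marker]
  same <- function(p) outer(p, p) + outer(1 - p, 1 - p)
  share_s <- outer(sire, sire, `==`); share_s[is.na(share_s)] <- FALSE
  share_d <- outer(dam, dam, `==`); share_d[is.na(share_d)] <- FALSE
  m <- 0.5 * same(ps) * share_s + 0.5 * same(pd) * share_d
  po <- outer(ids, sire, `==`) | outer(ids, dam, `==`)
  po[is.na(po)] <- FALSE
  m[po | t(po)] <- 0.5
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}
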