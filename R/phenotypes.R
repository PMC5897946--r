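#' Simulate phenotypes on a pedigree with a known variance decomposition
#'
#' Phenotype model: strain effect + polygenic breeding value + additive
#' QTL effect + independent residual, with total variance 1 by
#' construction.  Founder breeding values are N(0, v_polygenic); each
#' offspring receives the parent average plus a Mendelian-sampling
#' deviate N(0, v_polygenic / 2), so the polygenic covariance equals
#' `v_polygenic * A` for non-inbred pedigrees.  The QTL effect is
#' `alpha * (g - 2p)` with `g` the allele-1 dosage at the QTL marker and
#' `alpha` chosen so the QTL variance is `v_qtl` at the founder frequency
#' `p`.  Strain effects are fixed shifts scaled so their population
#' variance over phenotyped fish equals `v_strain` (or drawn
#' N(0, v_strain) per strain when `strain_random = TRUE`).
#'
#' @param ped Pedigree from [gen_pedigree()].
#' @param drop A `gene_drop` from [gen_genotypes()] (provides the QTL
#'   genotypes); may be `NULL` when `v_qtl = 0`.
#' @param variance_fractions Named numeric
#'   `c(strain =, polygenic =, qtl =, residual =)`, non-negative, summing
#'   to 1 (tolerance 1e-9).
#' @param strain_effects Numeric pattern of strain shifts named by strain
#'   (any location/scale; re-scaled to hit `v_strain`).  Defaults to an
#'   equally spaced pattern.
#' @param qtl_marker Marker id carrying the QTL (required if `v_qtl > 0`).
#' @param strain_random Draw strain effects as a random component instead
#'   of fixed shifts.
#' @param trait Name of the phenotype column (default `"phenotype"`).
#' @param seed Optional integer seed.
#' @return List: `cohort` (tibble of phenotyped generation-1 fish: `id`,
#'   `strain`, `family`, `environment`, `weight`, trait column) and
#'   `truth` (per-fish breeding value, QTL genotype and effect, residual;
#'   realized variance components).
#' @export
gen_phenotypes <- function(ped, drop = NULL, variance_fractions,
                           strain_effects = NULL, qtl_marker = NULL,
                           strain_random = FALSE, trait = "phenotype",
                           seed = NULL) {
  vf <- variance_fractions
  need <- c("strain", "polygenic", "qtl", "residual")
  if (is.null(names(vf)) || !all(need %in% names(vf)))
    stop("variance_fractions must be named: ", paste(need, collapse = ", "))
  vf <- vf[need]
  if (any(vf < 0)) stop("variance fractions must be non-negative")
  if (abs(sum(vf) - 1) > 1e-9) stop("variance fractions must sum to 1")
  if (vf["qtl"] > 0 && (is.null(drop) || is.null(qtl_marker)))
    stop("a gene_drop and qtl_marker are required when v_qtl > 0")
  ord <- validate_pedigree(ped)
  run <- function() {
    ids <- ord$id
    n <- length(ids)
    si <- match(ord$sire, ids)
    di <- match(ord$dam, ids)
    s2a <- unname(vf["polygenic"])
    bv <- numeric(n)
    for (i in seq_len(n)) {
      bv[i] <- if (is.na(si[i])) stats::rnorm(1, 0, sqrt(s2a))
               else 0.5 * (bv[si[i]] + bv[di[i]]) +
                    stats::rnorm(1, 0, sqrt(s2a / 2))
    }
    names(bv) <- ids
    pheno_ids <- ord$id[!is.na(ord$sire)]
    k <- length(pheno_ids)
    strain <- ord$strain[match(pheno_ids, ord$id)]
    ustr <- unique(ord$strain)
    if (strain_random) {
      eff <- stats::setNames(stats::rnorm(length(ustr), 0,
                                          sqrt(vf["strain"])), ustr)
    } else {
      pat <- if (is.null(strain_effects))
        stats::setNames(seq_along(ustr), ustr) else strain_effects
      e <- pat[strain]
      v <- stats::var(e) * (k - 1) / k
      eff <- if (vf["strain"] == 0 || v == 0) stats::setNames(0 * pat,
                                                              names(pat))
             else (pat - mean(e)) * sqrt(vf["strain"] / v)
    }
    qg <- rep(NA_integer_, k)
    qeff <- numeric(k)
    if (vf["qtl"] > 0) {
      g <- drop$genotypes[pheno_ids, qtl_marker]
      p <- drop$truth$founder_freqs[qtl_marker]
      if (p <= 0 || p >= 1)
        stop("QTL marker founder frequency must be in (0, 1)")
      alpha <- sqrt(unname(vf["qtl"]) / (2 * p * (1 - p)))
      qg <- as.integer(g)
      qeff <- alpha * (g - 2 * p)
    }
    resid <- stats::rnorm(k, 0, sqrt(vf["residual"]))
    y <- unname(eff[strain]) + bv[pheno_ids] + qeff + resid
    cohort <- tibble::tibble(
      id = pheno_ids, strain = strain,
      family = ord$family[match(pheno_ids, ord$id)],
      environment = "hatchery",
      weight = round(stats::rlnorm(k, log(2500), 0.25)))
    cohort[[trait]] <- unname(y)
    # second moments about the construction mean (zero): unbiased for the
    # generative variances even though relatives shrink the in-cohort
    # sample variance
    truth <- list(
      breeding_value = bv, qtl_genotype = stats::setNames(qg, pheno_ids),
      qtl_effect = stats::setNames(qeff, pheno_ids),
      strain_effects = eff,
      realized_fractions = c(
        strain = mean(unname(eff[strain])^2),
        polygenic = mean(unname(bv[pheno_ids])^2),
        qtl = mean(qeff^2),
        residual = mean(resid^2)))
    list(cohort = cohort, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Specify a simulated multi-strain half-sib cohort
#'
#' Bundles the pieces of the default study design: strains with fixed
#' effects, families per cross, offspring per family, a sparse regular
#' linkage map, founder allele frequencies, a single biallelic QTL and the
#' variance decomposition.  The default emulates a hatchery-scale
#' experiment: 6 crosses x 6 families x 20 offspring = 720 fish on a
#' ~100-marker, 25 cM-spaced map.
#'
#' @param strains Strain labels.
#' @param n_families_per_cross,n_offspring_per_family Design sizes.
#' @param map Genetic map (default [gen_map()]).
#' @param founder_freq Founder allele-1 frequency (scalar or per marker).
#' @param qtl List `(linkage_group =, pos_cM =)` locating the QTL; by
#'   default the middle marker of the first linkage group.  A position
#'   that is not a marker simulates a hidden between-marker locus.
#' @param variance_fractions Named fractions
#'   `c(strain, polygenic, qtl, residual)` summing to 1.
#' @param strain_random,strain_effects,trait Passed to
#'   [gen_phenotypes()].
#' @param seed Integer seed for the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(strains = c("Dom", "HybDF", "HybFD",
                                    "WildA", "WildB", "WildC"),
                        n_families_per_cross = 6,
                        n_offspring_per_family = 20,
                        map = gen_map(), founder_freq = 0.5,
                        qtl = NULL,
                        variance_fractions = c(strain = 0.11,
                                               polygenic = 0.06,
                                               qtl = 0.013,
                                               residual = 0.817),
                        strain_random = FALSE, strain_effects = NULL,
                        trait = "phenotype", seed = NULL) {
  validate_map(map)
  if (is.null(qtl)) {
    g1 <- map[map$linkage_group == map$linkage_group[1], ]
    qtl <- list(linkage_group = g1$linkage_group[1],
                pos_cM = g1$pos_cM[ceiling(nrow(g1) / 2)])
  }
  if (!qtl$linkage_group %in% map$linkage_group)
    stop("QTL linkage group is not on the map")
  rng <- range(map$pos_cM[map$linkage_group == qtl$linkage_group])
  if (qtl$pos_cM < rng[1] || qtl$pos_cM > rng[2])
    stop("QTL position lies outside its linkage group's map")
  structure(list(strains = strains,
                 n_families_per_cross = n_families_per_cross,
                 n_offspring_per_family = n_offspring_per_family,
                 map = map, founder_freq = founder_freq, qtl = qtl,
                 variance_fractions = variance_fractions,
                 strain_random = strain_random,
                 strain_effects = strain_effects,
                 trait = trait, seed = seed),
            class = "cohort_spec")
}

#' Simulate a full cohort: pedigree, genotypes, phenotypes, truth
#'
#' @param spec A [cohort_spec()].
#' @return List of class `sim_cohort`: `pedigree`, `genotypes` (released
#'   marker matrix), `map`, `cohort` (phenotype table), `truth`, `spec`.
#'   When the QTL sits between markers its genotypes are gene-dropped at a
#'   hidden locus and withheld from the released matrix.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- spec$seed
  ped <- gen_pedigree(spec$strains, spec$n_families_per_cross,
                      spec$n_offspring_per_family)
  map <- spec$map
  on_marker <- map$linkage_group == spec$qtl$linkage_group &
               map$pos_cM == spec$qtl$pos_cM
  hidden <- !any(on_marker)
  if (hidden) {
    extra <- tibble::tibble(linkage_group = spec$qtl$linkage_group,
                            marker = ".QTL", pos_cM = spec$qtl$pos_cM)
    map <- rbind(map, extra)
    map <- map[order(map$linkage_group, map$pos_cM), ]
    qtl_marker <- ".QTL"
  } else qtl_marker <- map$marker[on_marker][1]
  drop <- gen_genotypes(ped, map, spec$founder_freq,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  ph <- gen_phenotypes(ped, drop, spec$variance_fractions,
                       strain_effects = spec$strain_effects,
                       qtl_marker = qtl_marker,
                       strain_random = spec$strain_random,
                       trait = spec$trait,
                       seed = if (is.null(seed)) NULL else seed + 2L)
  geno <- drop$genotypes
  truth <- c(drop$truth, ph$truth,
             list(qtl_marker = qtl_marker, qtl = spec$qtl))
  if (hidden) {
    truth$qtl_genotypes_hidden <- geno[, ".QTL"]
    geno <- geno[, colnames(geno) != ".QTL", drop = FALSE]
    truth$sire_origin <- truth$sire_origin[, colnames(geno), drop = FALSE]
    truth$dam_origin <- truth$dam_origin[, colnames(geno), drop = FALSE]
  }
  structure(list(pedigree = ped, genotypes = geno, map = spec$map,
                 cohort = ph$cohort, truth = truth, spec = spec),
            class = "sim_cohort")
}
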