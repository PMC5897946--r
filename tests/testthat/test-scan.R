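sim_scan_fixture <- function(seed, vf = c(strain = 0, polygenic = 0.3,
                                          qtl = 0.15, residual = 0.55)) {
  spec <- cohort_spec(strains = c("A", "B"), n_families_per_cross = 4,
                      n_offspring_per_family = 15, map = gen_map(3, 3, 25),
                      variance_fractions = vf, seed = seed)
  simulate_cohort(spec)
}

test_that("a QTL structure equal to the kinship is non-identifiable", {
  sim <- sim_scan_fixture(23)
  A <- additive_relationship(sim$pedigree)[sim$cohort$id, sim$cohort$id]
  X <- model.matrix(~strain, sim$cohort)
  l <- lrt_at_position(sim$cohort$phenotype, X, A, A)
  expect_lt(l$lrt, 1e-3)
})

test_that("the full model never falls below the null beyond tolerance", {
  for (s in 1:3) {
    sim <- sim_scan_fixture(30 + s, vf = c(strain = 0, polygenic = 0.2,
                                           qtl = 0, residual = 0.8))
    ph <- phase_offspring(sim$pedigree, sim$genotypes, sim$map)
    A <- additive_relationship(sim$pedigree)[sim$cohort$id, sim$cohort$id]
    X <- model.matrix(~strain, sim$cohort)
    P <- ibd_matrix(ph, sim$pedigree, "LG02", 25, ids = sim$cohort$id)
    l <- lrt_at_position(sim$cohort$phenotype, X, A, P)
    expect_gte(2 * (l$fit_full$loglik - l$fit_null$loglik), -1e-6)
    expect_gte(l$lrt, 0)
  }
})

test_that("the scan grid contains all markers plus regular steps", {
  map <- gen_map(2, 3, 25)
  g <- salmospot:::scan_grid(map, 5)
  expect_true(all(map$pos_cM %in% g$pos_cM[g$linkage_group == "LG01"]))
  expect_true(all(seq(0, 50, 5) %in% g$pos_cM[g$linkage_group == "LG01"]))
  g1 <- salmospot:::scan_grid(data.frame(linkage_group = c("c1", "c2"),
                                         marker = c("m1", "m2"),
                                         pos_cM = c(0, 0)), Inf)
  expect_equal(nrow(g1), 2)  # single-marker map: one test per group
})

test_that("the scan localizes a planted QTL", {
  hits <- vapply(1:3, function(s) {
    sim <- sim_scan_fixture(40 + s)
    sc <- scan_genome(sim$cohort, sim$genotypes, sim$map, sim$pedigree,
                      step_cM = Inf)
    qtl_lrt <- sc$table$lrt[sc$table$linkage_group == "LG01" &
                            sc$table$pos_cM == sim$truth$qtl$pos_cM]
    other <- max(sc$table$lrt[sc$table$linkage_group == "LG03"])
    qtl_lrt >= other
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("cohort individuals missing genotypes are reported by id", {
  sim <- sim_scan_fixture(55)
  geno <- sim$genotypes[-match(sim$cohort$id[3], rownames(sim$genotypes)), ]
  expect_error(scan_genome(sim$cohort, geno, sim$map, sim$pedigree),
               sim$cohort$id[3])
})

test_that("permutation thresholds are monotone, seeded, and validated", {
  sim <- sim_scan_fixture(60, vf = c(strain = 0, polygenic = 0, qtl = 0,
                                     residual = 1))
  sc <- scan_genome(sim$cohort, sim$genotypes, sim$map, sim$pedigree,
                    step_cM = Inf)
  p1 <- permutation_threshold(sc, n_perm = 100, alpha = 0.05, seed = 4)
  p2 <- permutation_threshold(sc, n_perm = 100, alpha = 0.01, seed = 4)
  expect_identical(p1$perm_max, p2$perm_max)
  expect_gte(p2$threshold, p1$threshold)
  p3 <- permutation_threshold(sc, n_perm = 100, alpha = 0.05, seed = 4)
  expect_identical(p1$threshold, p3$threshold)
  expect_error(permutation_threshold(sc, n_perm = 50), "at least 100")
  expect_error(permutation_threshold(sc, n_perm = 100, alpha = 0.005),
               "too small")
  # threshold definition: smallest maximum with exceedance <= alpha
  expect_equal(p1$threshold, sort(p1$perm_max, decreasing = TRUE)[5])
})

test_that("allele contrasts group offspring by inherited haplotype", {
  sim <- sim_scan_fixture(70, vf = c(strain = 0, polygenic = 0.1,
                                     qtl = 0.35, residual = 0.55))
  ph <- phase_offspring(sim$pedigree, sim$genotypes, sim$map)
  # pick a sire heterozygous at the QTL marker
  qm <- sim$truth$qtl_marker
  sires <- unique(sim$pedigree$sire[!is.na(sim$pedigree$sire)])
  het <- sires[sim$genotypes[sires, qm] == 1]
  expect_gt(length(het), 0)  # fixture guarantees an informative sire
  ac <- allele_contrast(sim$cohort, ph, sim$pedigree, het[1],
                        sim$truth$qtl$linkage_group, sim$truth$qtl$pos_cM)
  expect_equal(sort(unique(ac$haplotype)), c(1, 2))
  expect_true(all(ac$n >= 1))
  # balanced transmission: group sizes split binomially around half
  n_tot <- sum(ac$n)
  expect_lt(abs(ac$n[1] - n_tot / 2), 4 * sqrt(n_tot / 4))
  # groups differ in the direction of the planted allele effect
  expect_true(is.numeric(attr(ac, "t")) || nrow(ac) > 2)
  # a parent homozygous across the whole linkage group carries no origin
  # information anywhere on it
  lg1 <- sim$map$marker[sim$map$linkage_group == "LG01"]
  geno_blind <- sim$genotypes
  geno_blind[het[1], lg1] <- 0L
  offs_of <- sim$pedigree$id[!is.na(sim$pedigree$sire) &
                             (sim$pedigree$sire == het[1] |
                              sim$pedigree$dam == het[1])]
  geno_blind[offs_of, lg1] <- 1L  # keep trios Mendelian-consistent
  ph_blind <- suppressWarnings(
    phase_offspring(sim$pedigree, geno_blind, sim$map))
  expect_error(
    allele_contrast(sim$cohort, ph_blind, sim$pedigree, het[1],
                    "LG01", sim$truth$qtl$pos_cM),
    "uninformative")
})

test_that("scan results serialize with genome-wide p-values", {
  sim <- sim_scan_fixture(80, vf = c(strain = 0, polygenic = 0, qtl = 0,
                                     residual = 1))
  sc <- scan_genome(sim$cohort, sim$genotypes, sim$map, sim$pedigree,
                    step_cM = Inf)
  sc <- permutation_threshold(sc, n_perm = 100, alpha = 0.05, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_scan_results(sc, path)
  tab <- read.delim(path)
  expect_setequal(names(tab),
                  c("linkage_group", "position_cM", "LRT", "genomewide_p"))
  expect_equal(nrow(tab), nrow(sc$table))
  expect_true(all(tab$genomewide_p >= 0 & tab$genomewide_p <= 1))
  unlink(path)
})
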