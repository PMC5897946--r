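# a one-family fixture: sire x dam with three offspring
fam_ped <- data.frame(id = c("S", "D", "o1", "o2", "o3"),
                      sire = c(NA, NA, "S", "S", "S"),
                      dam = c(NA, NA, "D", "D", "D"))

test_that("a heterozygous parent with resolvable offspring is informative", {
  map <- data.frame(linkage_group = "LG1", marker = "m1", pos_cM = 0)
  G <- rbind(S = 1, D = 0, o1 = 1, o2 = 0, o3 = 1)
  colnames(G) <- "m1"
  ph <- phase_offspring(fam_ped, G, map)
  expect_true(all(ph$informative_sire[, "m1"]))
  # o1/o3 received the sire's "1" allele, o2 the "0": opposite haplotypes
  expect_true(ph$p_sire["o1", "m1"] %in% c(0, 1))
  expect_equal(ph$p_sire["o1", "m1"], ph$p_sire["o3", "m1"])
  expect_equal(ph$p_sire["o2", "m1"], 1 - ph$p_sire["o1", "m1"])
  # dam homozygous: uninformative, probability 1/2
  expect_false(any(ph$informative_dam[, "m1"]))
  expect_true(all(ph$p_dam[, "m1"] == 0.5))
})

test_that("a double-heterozygous trio is uninformative in isolation", {
  map <- data.frame(linkage_group = "LG1", marker = "m1", pos_cM = 0)
  G <- rbind(S = 1, D = 1, o1 = 1, o2 = 1, o3 = 1)
  colnames(G) <- "m1"
  ph <- phase_offspring(fam_ped, G, map)
  expect_false(any(ph$informative_sire[, "m1"]))
  expect_true(all(ph$p_sire[, "m1"] == 0.5))
})

test_that("uninformative markers interpolate under the Haldane chain", {
  map <- data.frame(linkage_group = "LG1",
                    marker = c("m1", "m2", "m3"), pos_cM = c(0, 10, 20))
  # sire het at m1 and m3, hom at m2; dam always hom 0
  G <- rbind(S = c(1, 0, 1), D = c(0, 0, 0),
             o1 = c(1, 0, 1), o2 = c(1, 0, 1), o3 = c(0, 0, 0))
  colnames(G) <- c("m1", "m2", "m3")
  ph <- phase_offspring(fam_ped, G, map)
  r <- haldane(10)
  expected <- (1 - r)^2 / ((1 - r)^2 + r^2)
  p_mid <- ph$p_sire["o1", "m2"]
  # flanking origins agree, so the midpoint favours that origin
  expect_equal(max(p_mid, 1 - p_mid), expected, tolerance = 1e-12)
  # and the same number falls out of the arbitrary-position query
  op <- origin_probs(ph, "LG1", 10)
  expect_equal(unname(op["o1", "p_sire"]), unname(p_mid))
})

test_that("Mendelian inconsistencies are flagged and silenced", {
  map <- data.frame(linkage_group = "LG1", marker = "m1", pos_cM = 0)
  G <- rbind(S = 0, D = 0, o1 = 2, o2 = 0, o3 = 0)
  colnames(G) <- "m1"
  expect_warning(ph <- phase_offspring(fam_ped, G, map), "Mendelian")
  expect_true(ph$mendel_error["o1", "m1"])
  expect_equal(ph$p_sire["o1", "m1"], 0.5)
  expect_false(ph$informative_sire["o1", "m1"])
})

test_that("IBD entries are definitional for informative half sibs", {
  ped <- data.frame(id = c("S", "D1", "D2", "h1", "h2"),
                    sire = c(NA, NA, NA, "S", "S"),
                    dam = c(NA, NA, NA, "D1", "D2"))
  map <- data.frame(linkage_group = "LG1", marker = "m1", pos_cM = 0)
  G <- rbind(S = 1, D1 = 0, D2 = 0, h1 = 1, h2 = 1)
  colnames(G) <- "m1"
  ph <- phase_offspring(ped, G, map)
  P <- ibd_matrix(ph, ped, "LG1", 0)
  expect_equal(unname(P["h1", "h2"]), 0.5)  # same sire haplotype
  expect_equal(unname(diag(P)), c(1, 1))
  G2 <- G; G2["h2", ] <- 0
  ph2 <- phase_offspring(ped, G2, map)
  P2 <- ibd_matrix(ph2, ped, "LG1", 0)
  expect_equal(unname(P2["h1", "h2"]), 0)   # opposite sire haplotypes
  # include the sire: parent-offspring shares one allele
  P3 <- ibd_matrix(ph, ped, "LG1", 0, ids = c("S", "h1"))
  expect_equal(unname(P3["S", "h1"]), 0.5)
})

test_that("a fully informative marker gives half-sib IBD exactly in {0, 1/2}", {
  # one sire het, two hom dams: every sire meiosis is resolvable
  off <- paste0("o", 1:16)
  ped <- data.frame(id = c("S", "D1", "D2", off),
                    sire = c(NA, NA, NA, rep("S", 16)),
                    dam = c(NA, NA, NA, rep(c("D1", "D2"), each = 8)))
  map <- data.frame(linkage_group = "LG1", marker = "m1", pos_cM = 0)
  set.seed(12)
  transmitted <- rbinom(16, 1, 0.5)
  G <- matrix(c(1L, 0L, 0L, transmitted), ncol = 1,
              dimnames = list(ped$id, "m1"))
  ph <- phase_offspring(ped, G, map)
  P <- ibd_matrix(ph, ped, "LG1", 0)
  half <- P[paste0("o", 1:8), paste0("o", 9:16)]
  expect_true(all(half == 0 | half == 0.5))
  same_allele <- outer(transmitted[1:8], transmitted[9:16], `==`)
  expect_equal(unname(half), unname(0.5 * same_allele))
  expect_true(all(diag(P) == 1))
})

test_that("IBD matrices are symmetric PSD and average to the kinship", {
  spec <- cohort_spec(strains = c("A", "B"), n_families_per_cross = 3,
                      n_offspring_per_family = 10, map = gen_map(2, 4, 25),
                      variance_fractions = c(strain = 0, polygenic = 0,
                                             qtl = 0, residual = 1),
                      seed = 50)
  acc <- 0
  nrep <- 60
  pos <- c(0, 25, 50, 75)
  for (s in seq_len(nrep)) {
    spec$seed <- 50 + s
    sim <- simulate_cohort(spec)
    ph <- phase_offspring(sim$pedigree, sim$genotypes, sim$map)
    for (x in pos) {
      P <- ibd_matrix(ph, sim$pedigree, "LG01", x, ids = sim$cohort$id)
      acc <- acc + P / (nrep * length(pos))
    }
    if (s <= 3) {
      expect_true(isSymmetric(P))
      expect_true(all(P >= 0 & P <= 1))
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
    }
  }
  A <- additive_relationship(sim$pedigree)[sim$cohort$id, sim$cohort$id]
  expect_lt(mean(abs(acc - A)), 0.02)
  expect_lt(max(abs(acc - A)), 0.12)
})

test_that("reconstructed origins agree with the simulation truth", {
  spec <- cohort_spec(strains = c("A", "B"), n_families_per_cross = 4,
                      n_offspring_per_family = 15, map = gen_map(2, 4, 25),
                      seed = 61)
  sim <- simulate_cohort(spec)
  ph <- phase_offspring(sim$pedigree, sim$genotypes, sim$map)
  offs <- rownames(sim$truth$sire_origin)
  lg1 <- sim$map$marker[sim$map$linkage_group == "LG01"]
  truth1 <- sim$truth$sire_origin[, lg1] == 1L
  confident <- abs(ph$p_sire[offs, lg1] - 0.5) > 0.4
  called1 <- ph$p_sire[offs, lg1] > 0.5
  # phase labels are arbitrary per parent and linkage group: orient each
  acc <- vapply(unique(ph$sire), function(p) {
    rows <- which(ph$sire == p)
    m <- confident[rows, , drop = FALSE]
    if (!any(m)) return(NA_real_)
    agree <- mean(called1[rows, , drop = FALSE][m] ==
                  truth1[rows, , drop = FALSE][m])
    max(agree, 1 - agree)
  }, numeric(1))
  expect_gt(mean(acc, na.rm = TRUE), 0.95)
})

test_that("off-map queries are rejected", {
  spec <- cohort_spec(strains = c("A", "B"), n_families_per_cross = 2,
                      n_offspring_per_family = 5, map = gen_map(1, 3, 25),
                      seed = 3)
  sim <- simulate_cohort(spec)
  ph <- phase_offspring(sim$pedigree, sim$genotypes, sim$map)
  expect_error(origin_probs(ph, "LG01", 75), "off the map")
  expect_error(origin_probs(ph, "LG99", 10), "unknown linkage group")
  expect_error(ibd_matrix(ph, sim$pedigree, "LG01", -5), "off the map")
})
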