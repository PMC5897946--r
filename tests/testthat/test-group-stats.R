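sim_shares_table <- function(seed, v_strain = 0.11, v_family = 0.073,
                             n_strain = 6, n_fam = 6, n_off = 20) {
  set.seed(seed)
  strains <- paste0("S", seq_len(n_strain))
  rows <- do.call(rbind, lapply(strains, function(s) {
    fams <- paste0(s, "_F", seq_len(n_fam))
    data.frame(strain = s, family = rep(fams, each = n_off))
  }))
  se <- rnorm(n_strain, 0, sqrt(v_strain))
  fe <- rnorm(n_strain * n_fam, 0, sqrt(v_family))
  rows$id <- paste0("f", seq_len(nrow(rows)))
  rows$spot_density <- se[match(rows$strain, strains)] +
    fe[match(rows$family, unique(rows$family))] +
    rnorm(nrow(rows), 0, sqrt(1 - v_strain - v_family))
  rows
}

test_that("variance shares sum to one and recover known structure", {
  est <- t(vapply(1:20, function(s) {
    as.numeric(strain_family_shares(sim_shares_table(1200 + s)))
  }, numeric(3)))
  expect_true(all(abs(rowSums(est) - 1) < 1e-9))
  m <- colMeans(est)
  expect_lt(abs(m[1] - 0.11), 0.03)
  expect_lt(abs(m[2] - 0.073), 0.03)
})

test_that("null data put both shares at the boundary most of the time", {
  zero <- vapply(1:10, function(s) {
    sh <- strain_family_shares(sim_shares_table(1500 + s, 0, 0))
    all(sh[1:2] < 0.02)
  }, logical(1))
  expect_gte(mean(zero), 0.6)
})

test_that("share estimation validates its inputs", {
  tab <- sim_shares_table(1)
  expect_error(strain_family_shares(tab[, c("id", "strain", "spot_density")]),
               "family")
  one <- tab[tab$strain == "S1", ]
  expect_error(strain_family_shares(one), "2 strains")
})

test_that("fold differences follow the printed conventions", {
  expect_equal(fold_difference(1.02, 0.14), 7.2857, tolerance = 1e-4)
  expect_error(fold_difference(1, 0), "positive")
  expect_equal(render_fold(1.02 / 0.14, digits = 0), "sevenfold")
  expect_equal(render_fold(1.5 / 0.23), "6.5-fold")
  expect_equal(render_fold(1.4), "1.4-fold")
  expect_equal(render_fold(13.02, digits = 0), "13-fold")
  r <- fold_difference(1.37, 0.82)
  expect_equal(r * fold_difference(0.82, 1.37), 1, tolerance = 1e-12)
})

test_that("group summaries match hand computation", {
  tab <- data.frame(strain = c("a", "a", "a", "b", "c"),
                    w = c(1, 2, 6, 4, 10))
  s <- group_summaries(tab, "strain", "w")
  a <- s[s$group == "a", ]
  expect_equal(a$n, 3)
  expect_equal(a$mean, 3)
  expect_equal(a$median, 2)
  expect_equal(a$sd, sd(c(1, 2, 6)))
  expect_true(is.na(s$sd[s$group == "b"]))
  expect_error(group_summaries(tab, "strain", "nope"), "trait column")
})

test_that("group tests dispatch to the standard routines", {
  tab <- data.frame(g = rep(c("x", "y"), each = 5), v = rep(1:5, 2))
  t0 <- group_tests(tab, "v", "g", "t")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  set.seed(4)
  big <- data.frame(g = rep(c("x", "y"), each = 1000),
                    v = c(exact_norm(1000, 0, 1), exact_norm(1000, 1, 1)))
  tw <- group_tests(big, "v", "g", "t")
  expect_equal(abs(tw$statistic), 1 / sqrt(2 / 1000), tolerance = 1e-6)
  # Welch statistic flips sign under group relabeling
  big2 <- big
  big2$g <- ifelse(big$g == "x", "y", "x")
  expect_equal(group_tests(big2, "v", "g", "t")$statistic, -tw$statistic)

  set.seed(5)
  nt <- data.frame(g = rep(c("x", "y"), each = 30), v = runif(60))
  kw <- group_tests(nt, "v", "g", "kruskal_wallis")
  mw <- group_tests(nt, "v", "g", "mann_whitney")
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-6)

  r2 <- group_tests(big, "v", "g", "anova_r2")
  lm_r2 <- summary(lm(v ~ g, big))$r.squared
  expect_equal(r2$r_squared, lm_r2, tolerance = 1e-12)

  expect_error(group_tests(tab, "v", "g", "bogus"))
  expect_error(group_tests(tab[tab$g == "x", ], "v", "g", "t"), "2")
})
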