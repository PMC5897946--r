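test_that("the ROI follows the landmark construction rule", {
  lm <- list(gill_crease_x = 100, dorsal_fin_front_x = 500,
             lateral_line_y = 300, pectoral_fin_top = c(x = 100, y = 400))
  roi <- construct_roi(lm, c(600, 700), scale = 0.02)
  expect_equal(unname(roi$origin), c(100, 250))
  expect_equal(roi$width, 400)
  expect_equal(roi$height, 100)
  expect_equal(roi$area_cm2, 400 * 100 * 0.02^2)
})

test_that("degenerate or out-of-bounds landmarks are rejected", {
  lm <- list(gill_crease_x = 100, dorsal_fin_front_x = 500,
             lateral_line_y = 300, pectoral_fin_top = c(x = 100, y = 300))
  expect_error(construct_roi(lm, c(600, 700), 0.02), "above")
  lm$pectoral_fin_top <- c(x = 100, y = 400)
  expect_error(construct_roi(lm, c(320, 700), 0.02), "bounds")
  lm$dorsal_fin_front_x <- 90
  expect_error(construct_roi(lm, c(600, 700), 0.02), "left")
})

test_that("ROI construction is translation-equivariant with the landmarks", {
  lm <- list(gill_crease_x = 50, dorsal_fin_front_x = 250,
             lateral_line_y = 150, pectoral_fin_top = c(x = 50, y = 200))
  r0 <- construct_roi(lm, c(400, 400), 0.02)
  sh <- list(gill_crease_x = 80, dorsal_fin_front_x = 280,
             lateral_line_y = 170, pectoral_fin_top = c(x = 80, y = 220))
  r1 <- construct_roi(sh, c(400, 400), 0.02)
  expect_equal(unname(r1$origin - r0$origin), c(30, 20))
  expect_equal(r1$width, r0$width)
  expect_equal(r1$height, r0$height)
})

test_that("the embedded landmarks make the ROI cover the pattern window", {
  pat <- gen_pattern(pattern_spec("poisson", c(6, 4), 1.5, seed = 8))
  img <- render_spot_image(pat, scale = 0.02)
  roi <- construct_roi(img$landmarks, dim(img$pixels), img$scale)
  expect_equal(unname(roi$origin), unname(img$window_origin_px))
  expect_equal(roi$width, unname(img$window_px["width"]))
  expect_equal(roi$height, unname(img$window_px["height"]))
})

test_that("well-separated disks are each detected once", {
  g <- expand.grid(x = seq(0.6, 5.4, length.out = 5),
                   y = seq(0.6, 3.4, length.out = 5))
  pat <- point_pattern(g$x, g$y, 6, 4)
  img <- render_spot_image(pat, scale = 0.02, radius_mean = 0.12)
  q <- quantify_image(img)
  expect_equal(q$spot_count, 25L)
  # centroids land near the true points (ROI-local coordinates)
  ord <- order(q$detection$spots$y_cm, q$detection$spots$x_cm)
  truth <- g[order(g$y, g$x), ]
  expect_equal(q$detection$spots$x_cm[ord], truth$x, tolerance = 0.05)
  expect_equal(q$detection$spots$y_cm[ord], truth$y, tolerance = 0.05)
})

test_that("an empty pattern yields a uniform image and zero detections", {
  pat <- point_pattern(numeric(0), numeric(0), 6, 4)
  img <- render_spot_image(pat, scale = 0.02)
  expect_true(all(img$pixels == 1))
  q <- quantify_image(img)
  expect_equal(q$spot_count, 0L)
  expect_true(is.na(q$spot_density))
})

test_that("touching disks merge into one component", {
  pat <- point_pattern(c(2.0, 2.18), c(1, 1), 4, 2)
  img <- render_spot_image(pat, scale = 0.02, radius_mean = 0.12)
  q <- quantify_image(img)
  expect_equal(q$spot_count, 1L)
})

test_that("detection equals the flood-fill oracle on random binary masks", {
  set.seed(99)
  for (i in 1:20) {
    pat <- gen_pattern(pattern_spec("poisson", c(4, 3), runif(1, 0.5, 4),
                                    seed = 600 + i))
    img <- render_spot_image(pat, scale = 0.04,
                             radius_mean = runif(1, 0.05, 0.2))
    roi <- construct_roi(img$landmarks, dim(img$pixels), img$scale)
    det <- detect_spots(img, roi, min_area_cm2 = 0)
    crop <- img$pixels[(roi$origin["y"] + 1):(roi$origin["y"] + roi$height),
                       (roi$origin["x"] + 1):(roi$origin["x"] + roi$width)]
    expect_equal(det$count, flood_fill_count(crop < det$threshold))
  }
})

test_that("rendering is deterministic and round-trips through PNG", {
  pat <- gen_pattern(pattern_spec("poisson", c(4, 3), 2, seed = 21))
  i1 <- render_spot_image(pat, scale = 0.02, noise_sd = 0.05, seed = 5)
  i2 <- render_spot_image(pat, scale = 0.02, noise_sd = 0.05, seed = 5)
  expect_identical(i1$pixels, i2$pixels)

  clean <- render_spot_image(pat, scale = 0.02, noise_sd = 0)
  path <- tempfile(fileext = ".png")
  write_spot_image(clean, path)
  back <- read_spot_image(path)
  expect_identical(back$pixels, clean$pixels)
  expect_equal(back$landmarks, clean$landmarks)
  unlink(c(path, paste0(path, ".landmarks.csv")))
})

test_that("the minimum-area filter drops specks", {
  pat <- point_pattern(c(1, 3), c(1, 1), 4, 2)
  img <- render_spot_image(pat, scale = 0.02, radius_mean = 0.05)
  roi <- construct_roi(img$landmarks, dim(img$pixels), img$scale)
  all_spots <- detect_spots(img, roi, min_area_cm2 = 0)
  expect_equal(all_spots$count, 2L)
  none <- detect_spots(img, roi, min_area_cm2 = 1)
  expect_equal(none$count, 0L)
})

test_that("fixed thresholds are validated and honoured", {
  pat <- point_pattern(2, 1, 4, 2)
  img <- render_spot_image(pat, scale = 0.02, radius_mean = 0.2)
  roi <- construct_roi(img$landmarks, dim(img$pixels), img$scale)
  expect_error(detect_spots(img, roi, method = "fixed",
                            fixed_threshold = 2), "fixed_threshold")
  det <- detect_spots(img, roi, method = "fixed", fixed_threshold = 0.5)
  expect_equal(det$count, 1L)
  expect_equal(det$threshold, 0.5)
})

test_that("spot density applies the zero-count exclusion", {
  expect_equal(spot_density(10, 5), 2)
  expect_true(is.na(spot_density(0, 5)))
  expect_error(spot_density(3, 0), "positive")
  # invariant to consistent rescaling: same count, same physical area
  expect_equal(spot_density(42, 12.5), spot_density(42, 12.5))
})

test_that("head density adjusts by weight and propagates missingness", {
  expect_equal(head_density(12, 3000), 0.004)
  expect_true(is.na(head_density(NA, 3000)))
  expect_equal(head_density(0, 500), 0)
  expect_error(head_density(3, 0), "positive")
})

test_that("exclusion rules drop the right fish and log them", {
  tab <- tibble::tibble(
    id = paste0("f", 1:6),
    family = c("A", "A", "B", "B", "C", "C"),
    spot_count = c(0, 9, 10, 25, 3, NA))
  d <- apply_exclusions(tab, "density")
  expect_equal(d$id, paste0("f", 2:6))
  expect_equal(attr(d, "exclusion_log")$id, "f1")

  a <- apply_exclusions(tab, "ann")
  expect_setequal(a$id, c("f3", "f4", "f6"))   # exactly 10 retained
  expect_setequal(attr(a, "exclusion_log")$id, c("f1", "f2", "f5"))

  fam <- tibble::tibble(id = paste0("f", 1:5),
                        family = c("A", "A", "B", "C", "C"))
  f <- apply_exclusions(fam, "family_model")
  expect_false("f3" %in% f$id)
  expect_equal(attr(f, "exclusion_log")$reason[1], "single-member family")

  expect_error(apply_exclusions(fam[, "id", drop = FALSE], "density"),
               "spot_count")
})

test_that("exclusions are order-independent", {
  tab <- tibble::tibble(id = paste0("f", 1:20),
                        spot_count = rep(c(0, 5, 10, 50), 5))
  shuffled <- tab[sample(nrow(tab)), ]
  a <- apply_exclusions(tab, "ann")
  b <- apply_exclusions(shuffled, "ann")
  expect_setequal(a$id, b$id)
  expect_setequal(attr(a, "exclusion_log")$id, attr(b, "exclusion_log")$id)
})
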