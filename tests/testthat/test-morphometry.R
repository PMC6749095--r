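# Morphometry: circularity, aspect ratio, segmentation, volume, overlap
# probability and prevalence summaries.

test_that("circularity of analytic shapes is exact", {
  r <- 0.5
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  a <- 3
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(2 * 1, 2 * (2 + 1)), 8 * pi / 36, tolerance = 1e-12)
  expect_error(circularity(1, 0), "perimeter")
})

test_that("no analytic convex shape beats the circle", {
  # rectangles and regular polygons of unit area
  ratios <- c(1, 1.5, 2, 4, 8)
  cr_rect <- vapply(ratios, function(q) {
    w <- sqrt(1 / q); h <- q * w
    circularity(w * h, 2 * (w + h))
  }, numeric(1))
  n_gon <- c(3, 4, 6, 12, 60)
  cr_poly <- vapply(n_gon, function(n) {
    # regular n-gon, unit circumradius
    area <- 0.5 * n * sin(2 * pi / n)
    per <- 2 * n * sin(pi / n)
    circularity(area, per)
  }, numeric(1))
  expect_true(all(c(cr_rect, cr_poly) <= 1))
  expect_true(all(diff(cr_poly) > 0))   # approaches the circle from below
})

test_that("mask-based circularity of digital discs is near 1", {
  for (r in c(5, 8, 15)) {
    cr <- circularity(disc_mask(r))
    expect_gt(cr, 0.95)
    expect_lt(cr, 1.02)
  }
})

test_that("aspect ratio reads the fitted ellipse", {
  expect_equal(aspect_ratio(disc_mask(8)), 1, tolerance = 0.02)
  # 2:1 digital ellipse
  n <- 61; cx <- 31
  ell <- outer(1:n, 1:n, function(i, j)
    ((i - cx) / 20)^2 + ((j - cx) / 10)^2 <= 1)
  expect_equal(aspect_ratio(ell), 2, tolerance = 0.03)
  expect_error(aspect_ratio(matrix(c(0, 1, 0, 1), 2)), "5 pixels")

  # rendered near-spherical inclusions stay modestly eccentric
  cfg <- acquisition_config(z_spacing = 0.2)
  set.seed(5)
  ar <- vapply(1:5, function(i) {
    ecc <- runif(1, 1, 1.25)
    inc <- list(list(center = c(3.2, 3.2, 1.0),
                     radii = c(0.4 * ecc, 0.4, 0.4), intensity = 1.8))
    zs <- render_cell_zstack(inc, cfg, seed = i, blur = FALSE)
    obj <- segment_objects(zs$stack, 100, 1.2)
    obj$aspect_ratio[1]
  }, numeric(1))
  expect_gte(mean(ar), 1.0)
  expect_lte(mean(ar), 1.3)
})

test_that("threshold segmentation follows the intensity rules", {
  cfg <- acquisition_config(z_spacing = 0.2)
  # uniform stack at cytoplasm level only: no objects
  flat <- image_stack(array(100, dim = c(1, 5, 1, 32, 32)), pixel_size = 0.1,
                      frame_interval = 1, z_spacing = 0.2)
  expect_equal(nrow(segment_objects(flat, 100)), 0)
  expect_error(segment_objects(flat, -1), "cytoplasm_mean")

  # a 1.1x object is below the 1.2x threshold
  dim11 <- list(list(center = c(3.2, 3.2, 1.0), radii = c(0.5, 0.5, 0.5),
                     intensity = 1.1))
  zs11 <- render_cell_zstack(dim11, cfg, seed = 1, blur = FALSE)
  expect_equal(nrow(segment_objects(zs11$stack, 100, 1.2)), 0)

  # raising the threshold never increases object count or area
  bright <- list(list(center = c(2.2, 2.2, 1.0), radii = c(0.4, 0.4, 0.4),
                      intensity = 1.6),
                 list(center = c(4.6, 4.6, 1.0), radii = c(0.25, 0.25, 0.25),
                      intensity = 1.3))
  zsb <- render_cell_zstack(bright, cfg, seed = 2, blur = FALSE)
  ks <- c(1.2, 1.35, 1.5, 1.7)
  segs <- lapply(ks, function(k) segment_objects(zsb$stack, 100, k))
  counts <- vapply(segs, nrow, integer(1))
  areas <- vapply(segs, function(s) sum(s$area_um2), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("object classes follow the counting rules", {
  expect_equal(classify_object(0.008, supra_threshold = TRUE), "small_particle")
  expect_equal(classify_object(0.2, supra_threshold = TRUE), "IB")
  expect_equal(classify_object(0.05, visible_planes = 2,
                               supra_threshold = FALSE), "small_particle")
  # CLI: multi-lobed, or ragged with many peripheral objects
  expect_equal(classify_object(0.5, supra_threshold = TRUE, n_lobes = 3), "CLI")
  expect_equal(classify_object(0.5, supra_threshold = TRUE, cr = 0.7,
                               n_peripheral = 6), "CLI")
  expect_equal(classify_object(0.5, supra_threshold = TRUE, cr = 0.7,
                               n_peripheral = 2), "IB")
})

test_that("apparent volume sums voxels and converges on the analytic sphere", {
  expect_equal(apparent_volume(1, 0.1, 0.2), 0.002, tolerance = 1e-15)
  expect_equal(apparent_volume(array(FALSE, c(2, 2, 2)), 0.1, 0.2), 0)

  vol_true <- 4 / 3 * pi * 0.36^3
  vol_at <- function(ps, zs_um) {
    cfg <- acquisition_config(pixel_size = ps, z_spacing = zs_um,
                              field_px = c(64, 64) * round(0.1 / ps))
    inc <- list(list(center = c(3.2, 3.2, 1.0), radii = rep(0.36, 3),
                     intensity = 1.8))
    zsr <- render_cell_zstack(inc, cfg, seed = 1,
                              n_z = round(2 / zs_um) + 1, blur = FALSE)
    obj <- segment_objects(zsr$stack, 100, 1.2)
    obj$volume_um3[1]
  }
  v1 <- vol_at(0.1, 0.2)
  expect_equal(v1, vol_true, tolerance = 0.25)
  v2 <- vol_at(0.05, 0.1)      # finer sampling comes closer
  expect_lt(abs(v2 - vol_true), abs(v1 - vol_true) + 1e-9)
})

test_that("chance-overlap probability matches its closed form and is monotone", {
  expect_equal(chance_overlap_probability(1.0, 1e-12, 7.853982), 0.1,
               tolerance = 1e-4)
  expect_equal(chance_overlap_probability(0.48, 0.26, 15.7), 0.05,
               tolerance = 0.01)
  expect_equal(chance_overlap_probability(0.73, 0.26, 15.3), 0.08,
               tolerance = 0.01)
  p0 <- chance_overlap_probability(0.5, 0.2, 15)
  expect_gt(chance_overlap_probability(0.6, 0.2, 15), p0)
  expect_gt(chance_overlap_probability(0.5, 0.3, 15), p0)
  expect_lt(chance_overlap_probability(0.5, 0.2, 20), p0)
  expect_warning(p1 <- chance_overlap_probability(5, 2, 10), "available area")
  expect_equal(p1, 1)
})

test_that("prevalence fractions are exact on small populations and unbiased", {
  empty <- data.frame(n_ib = rep(0, 4), n_cli = 0, n_small = 0)
  ps <- prevalence_summary(empty)
  expect_equal(ps$fraction[ps$category == "particles_0"], 1)
  expect_equal(sum(ps$fraction[ps$category %in%
    c("single_IB", "multiple_IB", "CLI")]), 0)

  two_of_four <- data.frame(n_ib = c(1, 1, 0, 0), n_cli = 0, n_small = 0)
  ps2 <- prevalence_summary(two_of_four)
  expect_equal(ps2$fraction[ps2$category == "single_IB"], 0.5)

  # binomial sampling check against generator probabilities
  set.seed(123)
  n <- 500
  p_ib <- 0.45; p_cli <- 0.02
  cells <- data.frame(
    n_ib = rbinom(n, 1, p_ib),
    n_cli = rbinom(n, 1, p_cli),
    n_small = rpois(n, 1.2),
    group = rep(1:5, each = n / 5))
  cells$n_ib[cells$n_cli > 0] <- 0
  ps3 <- prevalence_summary(cells)
  p_single <- mean(cells$n_ib == 1 & cells$n_cli == 0)
  f <- ps3$fraction[ps3$category == "single_IB"]
  expect_equal(f, p_single)          # definitionally exact
  ci <- qbinom(c(0.025, 0.975), n, p_ib * (1 - p_cli)) / n
  expect_gte(f, ci[1]); expect_lte(f, ci[2])
})
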