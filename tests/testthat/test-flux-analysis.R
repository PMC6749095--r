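# FRAP and pulse-chase quantitation: bleach calibration/correction,
# integrated intensities, dilution, regressions, turnover, model fitting.

test_that("exponential bleach fits recover exact and noisy retentions", {
  m <- fit_bleach_decay(c(1, 0.9, 0.81, 0.729))
  expect_equal(m$retention_per_cycle, 0.9, tolerance = 1e-10)
  expect_equal(m$fit_r_squared, 1, tolerance = 1e-10)
  expect_equal(m$decay_rate, -log(0.9), tolerance = 1e-10)

  mc <- fit_bleach_decay(c(1, 1, 1, 1))
  expect_equal(mc$retention_per_cycle, 1, tolerance = 1e-12)

  set.seed(31)
  series <- 0.95^(0:9) * (1 + rnorm(10, 0, 0.01))
  mn <- fit_bleach_decay(series)
  expect_gt(mn$retention_per_cycle, 0.94)
  expect_lt(mn$retention_per_cycle, 0.96)

  expect_error(fit_bleach_decay(c(1, 0.9)), "3 cycles")
  expect_error(fit_bleach_decay(c(1, -0.1, 0.5)), "positive")
})

test_that("bleach correction inverts the geometric decay exactly", {
  model <- fit_bleach_decay(c(1, 0.9, 0.81, 0.729))
  expect_equal(correct_bleaching(0.729, model, cycles_elapsed = 3), 1,
               tolerance = 1e-9)
  x <- c(5, 4, 3)
  expect_equal(correct_bleaching(x, 1, cycles_elapsed = 0:2), x)
  expect_error(correct_bleaching(x, -0.5, cycles_elapsed = 0:2), "retention")
})

test_that("bleached simulations correct back to the unbleached truth", {
  m <- pulse_chase_model()
  cfg_off <- acquisition_config(channels = c("green", "red"),
                                bleach_retention = 1)
  cfg_on <- acquisition_config(channels = c("green", "red"),
                               bleach_retention = c(0.94, 0.92))
  ref <- simulate_pulse_chase(m, cfg_off, 270, 10, seed = 1)
  obs <- simulate_pulse_chase(m, cfg_on, 270, 10, seed = 1)
  corr <- obs
  for (ch in c("green", "red")) {
    model <- structure(list(retention_per_cycle =
                              attr(obs, "bleach_retention")[[ch]],
                            decay_rate = NA, fit_r_squared = 1, channel = ch),
                       class = "bleach_decay_model")
    corr <- correct_bleaching(corr, model)
  }
  rel <- abs(corr$ib_integrated - ref$ib_integrated) /
    pmax(abs(ref$ib_integrated), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("FRAP quantitation measures masks, intensities and diameters", {
  cfg <- acquisition_config(background_level = 0)
  fr <- simulate_frap(0.5, "interior_mixing", exchange_rate = 0.5,
                      bleach_depth = 0.95, config = cfg, duration_min = 10,
                      sampling_interval_min = 1, seed = 1)
  q <- frap_quantify(fr$stack, cyto_mean = 100, k_threshold = 1.4)
  # integrated intensity is area x mean by construction
  expect_equal(q$ib_integrated, q$ib_area_um2 * q$ib_mean, tolerance = 1e-12)
  # pre-bleach reference has ratio 1; ratio is 0 right after a deep bleach,
  # then recovers without ever shrinking
  expect_equal(q$diameter_ratio[1], 1)
  post <- q$diameter_ratio[-1]
  expect_true(all(diff(post) >= -1e-9))
  expect_gt(post[length(post)], 0.9)
  # uniformity statistic stays tight during recovery
  ratios <- vapply(4:dim(fr$stack)[1], function(t)
    shell_core_ratio(stack_frame(fr$stack, t), fr$center_px, fr$radius_px),
    numeric(1))
  expect_true(all(ratios < 1.1))
})

test_that("axis ratios reduce to simple arithmetic", {
  expect_equal(900 / 1100, 0.818, tolerance = 1e-3)
  mask_area_px <- 10; mean_int <- 50
  expect_equal(mask_area_px * mean_int, 500)
})

test_that("pulse-chase union masks and normalised traces behave", {
  # build a tiny two-channel series with disjoint green/red structures
  ny <- 32; nx <- 32
  mk <- function(vals) image_stack(array(vals, c(2, 1, 1, ny, nx)),
                                   pixel_size = 0.1, frame_interval = 600)
  g <- array(10, c(2, 1, 1, ny, nx)); r <- array(10, c(2, 1, 1, ny, nx))
  g[, , , 10:14, 10:14] <- 100   # green-only patch A
  r[, , , 13:17, 13:17] <- 100   # red patch B overlapping A's corner
  gs <- mk(g); rs <- mk(r)
  cyto <- matrix(FALSE, ny, nx); cyto[25:30, 25:30] <- TRUE
  fs <- pulse_chase_quantify(gs, rs, cyto,
                             bleach_models = list(green = 1, red = 1))
  # union mask area: |A| + |B| - |A ∩ B| pixels
  expect_equal(unique(fs$ib_area_um2), (25 + 25 - 4) * 0.01, tolerance = 1e-12)
  # red normalised to its maximum lies in [0, 1]; green starts at 1
  expect_true(all(fs$normalized[fs$channel == "red"] <= 1 + 1e-12))
  expect_equal(fs$normalized[fs$channel == "green"][1], 1)

  # one-way transfer keeps the corrected red trace non-decreasing
  cfg <- acquisition_config(channels = c("green", "red"),
                            bleach_retention = 1)
  m2 <- pulse_chase_model(k_out = 0, k_deg = 0, division_times = numeric(0))
  fs2 <- simulate_pulse_chase(m2, cfg, 300, 10, seed = 1)
  tr <- flux_trace(fs2, "red")
  expect_true(all(diff(tr$value) >= -1e-12))
})

test_that("corrected red traces peak and decline while uncorrected fall faster", {
  cfg <- acquisition_config(channels = c("green", "red"),
                            bleach_retention = 0.94)
  fs <- simulate_pulse_chase(pulse_chase_model(), cfg, 270, 10, seed = 2)
  raw <- flux_trace(fs, "red", corrected = FALSE)
  cor <- flux_trace(fs, "red", corrected = TRUE)
  i_max <- which.max(cor$value)
  expect_gt(i_max, 1); expect_lt(i_max, nrow(cor))
  # uncorrected loses more by the final timepoint
  expect_lt(raw$value[nrow(raw)] / max(raw$value),
            cor$value[nrow(cor)] / max(cor$value))
})

test_that("dilution predictions match the reciprocal rule", {
  expect_equal(predict_dilution(3.7)$percent, 27.03, tolerance = 0.01)
  expect_equal(predict_dilution(1)$remaining_fraction, 1)
  expect_equal(predict_dilution(2)$remaining_fraction, 0.5)
  alt <- predict_dilution(n_cycles = 2.2, daughter_fraction = 0.7)
  expect_equal(alt$derivation, "compounded")
  expect_equal(alt$dilution_factor, 1.7^2.2, tolerance = 1e-12)
  both <- predict_dilution(3.7, n_cycles = 2.2, daughter_fraction = 0.7)
  expect_equal(both$alternative_factor, 1.7^2.2, tolerance = 1e-12)
  expect_error(predict_dilution(0.5), "dilution_factor")
})

test_that("recovery regressions separate source dependence from noise", {
  x <- 1:10
  # exact lines trip summary.lm's perfect-fit warning; that is the point
  exact <- suppressWarnings(
    recovery_regression(2 * x + 1, x, rev(x) * 0 + seq(3, 30, 3)))
  expect_equal(exact$vs_cytoplasm$slope, 2, tolerance = 1e-12)
  expect_equal(exact$vs_cytoplasm$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$vs_cytoplasm$r_squared, 1, tolerance = 1e-12)

  set.seed(12)
  cyto <- runif(12, 50, 150)
  pre <- runif(12, 200, 800)                  # independent of recovery
  recovered <- 3 * cyto * (1 + rnorm(12, 0, 0.2))
  fits <- recovery_regression(recovered, cyto, pre)
  expect_gt(fits$vs_cytoplasm$r_squared, 0.7)
  expect_lt(fits$vs_prebleach$r_squared, 0.2)

  expect_error(recovery_regression(c(1, 2, 3), c(5, 5, 5), c(1, 2, 3)),
               "zero-variance")
})

test_that("turnover summaries locate the maximum and the drop", {
  ts <- turnover_summary(c(1, 2, 1.3), c(0, 60, 210))
  expect_equal(ts$time_of_max, 60)
  expect_equal(ts$percent_drop, 35, tolerance = 1e-12)

  mono <- turnover_summary(c(1, 2, 3), c(0, 10, 20))
  expect_equal(mono$percent_drop, 0)
  expect_equal(mono$time_of_max, 20)

  # against the closed-form two-pool solution (no divisions)
  m <- pulse_chase_model(division_times = numeric(0))
  cfg <- acquisition_config(channels = c("green", "red"), bleach_retention = 1)
  fs <- simulate_pulse_chase(m, cfg, 270, 10, seed = 1)
  tr <- flux_trace(fs, "red")
  sim <- turnover_summary(tr$value, tr$time_min)
  times <- tr$time_min
  pools <- red_pools_closed_form(m$k_in, m$k_out, m$k_deg,
                                 m$init_cyto * m$conversion_fraction,
                                 m$init_ib * m$conversion_fraction, times)
  oracle <- turnover_summary(pools[, 2], times)
  expect_equal(sim$time_of_max, oracle$time_of_max)
  expect_lt(abs(sim$percent_drop - oracle$percent_drop), 5)
})

test_that("two-pool fits recover the generator's rates", {
  cfg <- acquisition_config(channels = c("green", "red"),
                            bleach_retention = 0.94)
  truth <- pulse_chase_model()
  fs <- simulate_pulse_chase(truth, cfg, 270, 10, seed = 77, noise_sd = 0.02)
  fit <- fit_pulse_chase(fs, truth, cfg)
  expect_equal(fit$k_in, truth$k_in, tolerance = 0.15)
  expect_equal(fit$k_out, truth$k_out, tolerance = 0.15)
  expect_equal(fit$k_deg, truth$k_deg, tolerance = 0.15)
})
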