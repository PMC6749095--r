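# Synthetic-data generator: trajectories, rendered movies and z-stacks,
# FRAP and pulse-chase kinetics.

test_that("degenerate motion kinds have their closed-form trajectories", {
  st <- simulate_trajectory(motion_model("stationary"), 10, 0.1, seed = 1)
  expect_true(all(st$x == st$x[1]) && all(st$y == st$y[1]))

  v <- 0.3
  ba <- simulate_trajectory(motion_model("ballistic", drift_speed = v),
                            20, 0.1, seed = 2)
  # displacement over lag t is exactly v * t, so MSD(t) = v^2 t^2
  m <- compute_msd(ba, max_lag = 10)
  expect_equal(m$msd, v^2 * m$dt_s^2, tolerance = 1e-12)
})

test_that("Brownian step variance matches 2 D dt within 5%", {
  D <- 0.05; dt <- 1 / 32
  tr <- simulate_trajectory(motion_model("brownian", D), 1e4, dt, seed = 7)
  # independent accumulation of squared per-axis steps
  v_emp <- (sum(diff(tr$x)^2) + sum(diff(tr$y)^2)) / (2 * (nrow(tr) - 1))
  expect_equal(v_emp, 2 * D * dt, tolerance = 0.05)
})

test_that("ensemble MSD of Brownian tracks is calibrated at lags 1-16", {
  D <- 0.059; dt <- 1 / 32
  model <- motion_model("brownian", D)
  tracks <- simulate_ensemble(model, 1000, 32, dt, seed = 11)
  msum <- Reduce(`+`, lapply(tracks, function(tr) compute_msd(tr, 16)$msd))
  ratio <- (msum / 1000) / (4 * D * (1:16) * dt)
  expect_true(all(ratio > 0.95 & ratio < 1.05))
})

test_that("identical seeds reproduce trajectories and images bit for bit", {
  model <- motion_model("directed", 0.01, drift_speed = 0.2,
                        drift_persistence = 1)
  a <- simulate_trajectory(model, 50, 0.1, seed = 42)
  b <- simulate_trajectory(model, 50, 0.1, seed = 42)
  expect_identical(a, b)

  cfg <- acquisition_config(shot_noise = TRUE, read_noise_sd = 2)
  tr <- simulate_trajectory(motion_model("brownian", 0.05), 5, 1 / 32,
                            seed = 1, origin = c(3.2, 3.2))
  m1 <- render_timelapse(list(tr), cfg, seed = 9)
  m2 <- render_timelapse(list(tr), cfg, seed = 9)
  expect_identical(unclass(m1$stack), unclass(m2$stack))
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_trajectory(motion_model("brownian", 0.05), 1, 0.1, 1),
               "n_frames")
  expect_error(simulate_trajectory(motion_model("brownian", 0.05), 10, 0, 1),
               "frame_interval")
  expect_error(motion_model("brownian", -1), "diffusion_coefficient")
  expect_error(motion_model("stationary", 0.1), "stationary")
})

test_that("noise-free rendering is exact: background, centroid, bleach, photons", {
  cfg <- acquisition_config(background_level = 50)
  # zero-amplitude particle: every pixel at background
  tr0 <- simulate_trajectory(motion_model("stationary"), 4, 1 / 32, seed = 1,
                             origin = c(3.17, 2.83))
  mv <- render_timelapse(list(tr0), cfg, seed = 1, amplitude = 0)
  expect_true(all(stack_frame(mv$stack, 1) == 50))

  # one stationary particle: intensity-weighted centroid within 0.05 px
  mv <- render_timelapse(list(tr0), cfg, seed = 1, amplitude = 500)
  fr <- stack_frame(mv$stack, 1) - 50
  xs <- matrix(seq_len(ncol(fr)) - 0.5, nrow(fr), ncol(fr), byrow = TRUE)
  ys <- matrix(seq_len(nrow(fr)) - 0.5, nrow(fr), ncol(fr))
  cx <- sum(xs * fr) / sum(fr); cy <- sum(ys * fr) / sum(fr)
  expect_lt(abs(cx - 3.17 / 0.1), 0.05)
  expect_lt(abs(cy - 2.83 / 0.1), 0.05)

  # photon conservation: summed spot signal = amplitude * 2 pi sigma_px^2 within 1%
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  expect_equal(sum(fr), 500 * 2 * pi * sigma_px^2, tolerance = 0.01)

  # geometric bleaching: frame 3 peak is retention^3 of frame 0
  cfgb <- acquisition_config(background_level = 0, bleach_retention = 0.9)
  mvb <- render_timelapse(list(tr0), cfgb, seed = 1, amplitude = 500)
  expect_equal(max(stack_frame(mvb$stack, 4)) / max(stack_frame(mvb$stack, 1)),
               0.9^3, tolerance = 1e-12)
})

test_that("tracks leaving the field error unless clipping is requested", {
  cfg <- acquisition_config()
  tr <- simulate_trajectory(motion_model("stationary"), 3, 1 / 32, seed = 1,
                            origin = c(20, 20))   # outside the 6.4 um field
  expect_error(render_timelapse(list(tr), cfg, seed = 1), "clip")
  mv <- render_timelapse(list(tr), cfg, seed = 1, out_of_field = "clip")
  expect_true(all(stack_frame(mv$stack, 1) == cfg$background_level))
})

test_that("rendered z-stack geometry matches the analytic sphere", {
  cfg <- acquisition_config(z_spacing = 0.2)
  inc <- list(list(center = c(3.2, 3.2, 1.0), radii = c(0.5, 0.5, 0.5),
                   intensity = 1.6))
  zs <- render_cell_zstack(inc, cfg, seed = 1, blur = FALSE)
  obj <- segment_objects(zs$stack, cytoplasm_mean = 100, k_threshold = 1.2)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area_um2, pi * 0.5^2, tolerance = 0.10)

  # no inclusions: nothing segmented downstream
  zs0 <- render_cell_zstack(list(), cfg, seed = 1, blur = FALSE)
  expect_equal(nrow(segment_objects(zs0$stack, 100)), 0)

  # ground-truth area rule labels small particles vs IBs
  inc2 <- list(
    list(center = c(1.6, 1.6, 1.0), radii = c(0.05, 0.0509, 0.1),
         intensity = 2),                          # ~0.008 um^2
    list(center = c(4.8, 4.8, 1.0), radii = c(0.252, 0.252, 0.252),
         intensity = 2))                          # ~0.2 um^2
  zs2 <- render_cell_zstack(inc2, cfg, seed = 1, blur = FALSE)
  expect_identical(zs2$ground_truth$objects$class, c("small_particle", "IB"))

  # overlapping specs are rejected
  inc3 <- list(list(center = c(3.2, 3.2, 1), radii = c(0.5, 0.5, 0.5), intensity = 2),
               list(center = c(3.4, 3.2, 1), radii = c(0.5, 0.5, 0.5), intensity = 2))
  expect_error(render_cell_zstack(inc3, cfg, seed = 1), "overlap")
})

test_that("FRAP simulator realises the three recovery regimes", {
  cfg <- acquisition_config(background_level = 0)
  # no exchange, full bleach, no imaging bleach: zero forever
  fr <- simulate_frap(0.5, "no_exchange", exchange_rate = 0, bleach_depth = 1,
                      config = cfg, duration_min = 5, sampling_interval_min = 1,
                      seed = 1)
  for (t in 2:dim(fr$stack)[1])
    expect_equal(max(stack_frame(fr$stack, t)), 0, tolerance = 1e-12)

  # interior mixing: shell/core ratio within [0.9, 1.1] throughout recovery
  fr <- simulate_frap(0.5, "interior_mixing", exchange_rate = 0.3,
                      bleach_depth = 0.9, config = cfg, duration_min = 10,
                      sampling_interval_min = 1, seed = 1)
  ratios <- vapply(3:dim(fr$stack)[1], function(t)
    shell_core_ratio(stack_frame(fr$stack, t), fr$center_px, fr$radius_px),
    numeric(1))
  expect_true(all(ratios > 0.9 & ratios < 1.1))

  # surface accretion: the same statistic exceeds 2 early in recovery
  fr <- simulate_frap(0.5, "surface_accretion", exchange_rate = 0.3,
                      bleach_depth = 0.9, config = cfg, duration_min = 10,
                      sampling_interval_min = 1, seed = 1)
  early <- shell_core_ratio(stack_frame(fr$stack, 3), fr$center_px,
                            fr$radius_px)
  expect_gt(early, 2)

  expect_error(simulate_frap(0.5, "interior_mixing", exchange_rate = -1,
                             bleach_depth = 0.5, config = cfg,
                             duration_min = 5), "exchange_rate")
})

test_that("pulse-chase kinetics conserve, saturate and peak as expected", {
  cfg <- acquisition_config(channels = c("green", "red"))
  # conservation: k_deg = 0, no divisions, bleach off
  m <- pulse_chase_model(k_deg = 0, division_times = numeric(0))
  fs <- simulate_pulse_chase(m, cfg, 100, 5, seed = 1)
  red <- fs[fs$channel == "red", ]
  total <- red$ib_true + red$cyto_true + red$daughters
  expect_equal(max(abs(total - total[1])) / total[1], 0, tolerance = 1e-9)

  # one-way transfer: k_out = k_deg = 0 -> red IB non-decreasing to asymptote
  m2 <- pulse_chase_model(k_out = 0, k_deg = 0, division_times = numeric(0))
  fs2 <- simulate_pulse_chase(m2, cfg, 400, 10, seed = 1)
  r2 <- fs2[fs2$channel == "red", ]
  expect_true(all(diff(r2$ib_true) >= -1e-12))
  # approaches the asymptote (all red ends up in the IB)
  expect_equal(r2$ib_true[nrow(r2)], r2$ib_true[1] + r2$cyto_true[1],
               tolerance = 0.01)

  # k_out, k_deg > 0: rise, maximum, decline
  fs3 <- simulate_pulse_chase(pulse_chase_model(), cfg, 270, 10, seed = 1)
  r3 <- fs3[fs3$channel == "red", ]
  i_max <- which.max(r3$ib_true)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(r3))
  expect_gt(r3$ib_true[i_max], r3$ib_true[1])
  expect_gt(r3$ib_true[i_max], r3$ib_true[nrow(r3)])
})

test_that("pulse-chase mass balance holds across arbitrary division schedules", {
  cfg <- acquisition_config(channels = c("green", "red"))
  for (seed in 1:5) {
    set.seed(seed)
    divs <- sort(runif(sample(1:4, 1), 10, 250))
    m <- pulse_chase_model(k_deg = 0, synthesis_rate = 0,
                           division_times = divs)
    fs <- simulate_pulse_chase(m, cfg, 260, 10, seed = seed)
    for (ch in c("green", "red")) {
      d <- fs[fs$channel == ch, ]
      total <- d$ib_true + d$cyto_true + d$daughters
      expect_equal(max(abs(total - total[1])) / max(total[1], 1e-12), 0,
                   tolerance = 1e-9)
    }
  }
})
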