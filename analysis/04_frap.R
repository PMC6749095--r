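#!/usr/bin/env Rscript
# Stage 4: FRAP recovery analysis.
#
# Simulates photobleaching of a spherical inclusion under the competing
# recovery hypotheses (uniform interior mixing vs surface accretion vs no
# exchange), quantifies each with the 1.4x-threshold pipeline, and runs the
# source-attribution regression over a cohort of bleached inclusions.

suppressMessages(library(incluflux))
dir.create("results", showWarnings = FALSE)
set.seed(20260923)

cfg <- acquisition_config(background_level = 50, shot_noise = TRUE)
modes <- c("interior_mixing", "surface_accretion", "no_exchange")
rows <- list()
for (mode in modes) {
  fr <- simulate_frap(0.5, mode, exchange_rate = 0.3, bleach_depth = 0.9,
                      config = cfg, duration_min = 10,
                      sampling_interval_min = 1, seed = 7)
  q <- frap_quantify(fr$stack, cyto_mean = 100, k_threshold = 1.4,
                     background = 50)
  q$time_min <- fr$time_min
  q$mode <- mode
  q$shell_core <- vapply(seq_len(nrow(q)), function(t)
    shell_core_ratio(stack_frame(fr$stack, t), fr$center_px, fr$radius_px,
                     background = 50), numeric(1))
  rows[[mode]] <- q
  post <- q[q$time_min >= 1, ]   # skip the bleach frame itself
  cat(sprintf("%-17s shell/core %.2f (early) -> %.2f (final); diameter ratio %.2f -> %.2f\n",
              mode, post$shell_core[2], post$shell_core[nrow(post)],
              post$diameter_ratio[1], post$diameter_ratio[nrow(post)]))
}
frap_table <- do.call(rbind, rows)
write.csv(frap_table, "results/frap_timecourses.csv", row.names = FALSE)

mix <- rows$interior_mixing
pre_int <- mix$ib_integrated[1]
t50 <- mix$time_min[mix$time_min > 0 & mix$ib_integrated >= 0.5 * pre_int][1]
cat(sprintf("interior mixing: integrated intensity back to 50%% of pre-bleach by %s min\n",
            format(t50)))

# recovery-source regression over a cohort of 18 bleached inclusions:
# recovered total is generated proportional to the post-bleach cytoplasm
# (with 20% noise) and independent of the pre-bleach IB total
n_coh <- 18
cyto <- runif(n_coh, 30, 180)
pre <- runif(n_coh, 200, 800)
recovered <- 3 * cyto * (1 + rnorm(n_coh, 0, 0.2))
fits <- recovery_regression(recovered, cyto, pre)
cat(sprintf("recovered ~ cytoplasm: r^2 = %.2f; recovered ~ pre-bleach: r^2 = %.2f\n",
            fits$vs_cytoplasm$r_squared, fits$vs_prebleach$r_squared))
write.csv(data.frame(recovered = recovered, post_bleach_cyto = cyto,
                     pre_bleach_total = pre),
          "results/frap_recovery_cohort.csv", row.names = FALSE)
cat("wrote results/frap_timecourses.csv, results/frap_recovery_cohort.csv\n")
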