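# FRAP and photoconversion pulse-chase quantitation: bleach calibration and
# correction, integrated intensities, recovery and turnover summaries.

#' Fit an exponential photobleaching decay
#'
#' Rapid-cycle calibration: intensities acquired back-to-back (no chase time,
#' so the only loss is imaging bleach) are normalised to cycle 0 and fitted
#' with `I(c) = retention^c` by least squares on the log scale.
#'
#' @param intensities per-cycle mean intensities (cycle 0 first; >= 3
#'   cycles, all positive).
#' @param channel channel id recorded in the model.
#' @return a `bleach_decay_model` list: `retention_per_cycle`, `decay_rate`
#'   (`-log(retention)`), `fit_r_squared`, `channel`.
#' @examples
#' fit_bleach_decay(c(1, 0.9, 0.81, 0.729))   # retention 0.9
#' @export
fit_bleach_decay <- function(intensities, channel = "ch1") {
  if (length(intensities) < 3)
    stop("need at least 3 cycles", call. = FALSE)
  if (any(intensities <= 0))
    stop("intensities must be positive", call. = FALSE)
  y <- intensities / intensities[1]
  cyc <- seq_along(y) - 1
  fit <- stats::lm(log(y) ~ 0 + cyc)
  retention <- exp(unname(stats::coef(fit)[1]))
  pred <- retention^cyc
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (r2 < 0.5 && any(diff(y) > 0))
    warning("non-monotone series with poor exponential fit (r^2 < 0.5)",
            call. = FALSE)
  structure(list(retention_per_cycle = retention,
                 decay_rate = -log(retention),
                 fit_r_squared = r2,
                 channel = channel),
            class = "bleach_decay_model")
}

#' @export
print.bleach_decay_model <- function(x, ...) {
  cat(sprintf("<bleach_decay_model> %s: retention %.4f/cycle (r^2 = %.3f)\n",
              x$channel, x$retention_per_cycle, x$fit_r_squared))
  invisible(x)
}

#' Correct a measured series for photobleaching
#'
#' Divides each measured value by the fraction of intensity remaining after
#' the bleaching incurred by its acquisition history:
#' `corrected(t) = measured(t) / retention^cycles_elapsed(t)`.
#'
#' Accepts either a bare numeric vector (with `cycles_elapsed`) or a
#' `flux_series`, in which case the channel matching the model is corrected
#' in place (columns `ib_integrated` and `cyto_mean`) using the series'
#' `cycles` column.
#'
#' @param series numeric vector of measured values, or a `flux_series`.
#' @param model a `bleach_decay_model` from [fit_bleach_decay] (or a bare
#'   retention fraction).
#' @param cycles_elapsed acquisition cycles elapsed at each value (vector
#'   path only).
#' @return the corrected series, same shape as the input.
#' @examples
#' correct_bleaching(c(1, 0.9, 0.81), fit_bleach_decay(c(1, 0.9, 0.81, 0.729)),
#'                   cycles_elapsed = 0:2)
#' @export
correct_bleaching <- function(series, model, cycles_elapsed = NULL) {
  retention <- if (inherits(model, "bleach_decay_model"))
    model$retention_per_cycle else model
  if (!is.numeric(retention) || retention <= 0)
    stop("retention must be > 0", call. = FALSE)
  if (is.numeric(series)) {
    if (is.null(cycles_elapsed))
      stop("cycles_elapsed is required for a numeric series", call. = FALSE)
    return(series / retention^cycles_elapsed)
  }
  stopifnot(inherits(series, "flux_series"))
  ch <- if (inherits(model, "bleach_decay_model")) model$channel else NULL
  sel <- if (is.null(ch) || !ch %in% series$channel) rep(TRUE, nrow(series))
         else series$channel == ch
  fac <- retention^series$cycles[sel]
  series$ib_integrated[sel] <- series$ib_integrated[sel] / fac
  series$cyto_mean[sel] <- series$cyto_mean[sel] / fac
  attr(series, "corrected") <- TRUE
  series
}

#' Quantify FRAP recovery from a rendered time series
#'
#' Per timepoint, on the maximum-intensity projection: background-corrected
#' cytoplasm mean (from a supplied cytoplasmic region distant from the IB
#' and excluding the vacuole), IB mask by thresholding at `k_threshold`
#' times the cytoplasm mean, integrated intensity (area times mean), and
#' the equivalent-circle diameter with its ratio to the pre-bleach value.
#' Timepoints without a supra-threshold IB record a ratio of 0.
#'
#' @param stack an [image_stack] time series (frame 1 = pre-bleach by
#'   default).
#' @param cyto_mask logical matrix selecting the cytoplasmic reference
#'   region, or `NULL` to use the cytoplasm mean supplied in `cyto_mean`.
#' @param cyto_mean cytoplasm mean per timepoint (used when `cyto_mask` is
#'   `NULL`); recycled.
#' @param k_threshold IB threshold multiplier (1.4 for FRAP analysis).
#' @param background camera background to subtract, A.U.
#' @param prebleach 1-based index of the pre-bleach reference frame.
#' @return a data frame with one row per timepoint: `frame` (0-based),
#'   `cyto_mean`, `ib_area_um2`, `ib_mean`, `ib_integrated`,
#'   `diameter_um` and `diameter_ratio`.
#' @export
frap_quantify <- function(stack, cyto_mask = NULL, cyto_mean = NULL,
                          k_threshold = 1.4, background = 0, prebleach = 1) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- attr(stack, "pixel_size")
  n_t <- dim(stack)[1]
  if (is.null(cyto_mask) && is.null(cyto_mean))
    stop("supply cyto_mask or cyto_mean", call. = FALSE)
  if (!is.null(cyto_mean)) cyto_mean <- rep_len(cyto_mean, n_t)
  rows <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    proj <- max_projection(stack, t = t) - background
    cm <- if (!is.null(cyto_mask)) mean(proj[cyto_mask]) else cyto_mean[t]
    mask <- proj > k_threshold * cm
    if (any(mask)) {
      lab <- label_components(mask)
      sizes <- tabulate(lab[lab > 0])
      mask <- lab == which.max(sizes)   # the IB: largest supra-threshold object
      area <- sum(mask) * ps^2
      mn <- mean(proj[mask])
      rows[[t]] <- data.frame(frame = t - 1L, cyto_mean = cm,
                              ib_area_um2 = area, ib_mean = mn,
                              ib_integrated = area * mn,
                              diameter_um = 2 * sqrt(area / pi))
    } else {
      rows[[t]] <- data.frame(frame = t - 1L, cyto_mean = cm,
                              ib_area_um2 = 0, ib_mean = 0, ib_integrated = 0,
                              diameter_um = 0)
    }
  }
  out <- do.call(rbind, rows)
  ref <- out$diameter_um[prebleach]
  out$diameter_ratio <- if (ref > 0) out$diameter_um / ref else 0
  out
}

#' Quantify a two-colour pulse-chase image series
#'
#' Per timepoint: the IB mask is the union of the green and red masks, each
#' thresholded at `k_threshold` times that channel's cytoplasm mean
#' (background-subtracted, on the maximum-intensity projection). Mean and
#' integrated IB intensity are measured within the union mask per channel,
#' corrected for photobleaching with the per-channel decay models, and
#' normalised: red as the fraction of its post-conversion maximum, green
#' relative to its initial value.
#'
#' @param green_stack,red_stack [image_stack] time series (same geometry).
#' @param cyto_mask logical matrix selecting the cytoplasmic reference
#'   region.
#' @param bleach_models list with elements `green` and `red`
#'   (`bleach_decay_model` or bare retention fractions).
#' @param k_threshold threshold multiplier (1.5 for pulse-chase masks).
#' @param background camera background, A.U.
#' @return a `flux_series` data frame (`time_min` taken from the stack
#'   calibration) with measured, corrected and normalised columns.
#' @export
pulse_chase_quantify <- function(green_stack, red_stack, cyto_mask,
                                 bleach_models, k_threshold = 1.5,
                                 background = 0) {
  stopifnot(inherits(green_stack, "image_stack"),
            inherits(red_stack, "image_stack"))
  if (!identical(dim(green_stack), dim(red_stack)))
    stop("green and red series must be registered (same dimensions)",
         call. = FALSE)
  if (!all(c("green", "red") %in% names(bleach_models)))
    stop("bleach_models must have elements green and red", call. = FALSE)
  ps <- attr(green_stack, "pixel_size")
  dt_min <- attr(green_stack, "frame_interval") / 60
  n_t <- dim(green_stack)[1]
  ret <- vapply(bleach_models, function(m)
    if (inherits(m, "bleach_decay_model")) m$retention_per_cycle else m,
    numeric(1))

  rows <- vector("list", 2 * n_t)
  for (t in seq_len(n_t)) {
    pg <- max_projection(green_stack, t = t) - background
    pr <- max_projection(red_stack, t = t) - background
    cg <- mean(pg[cyto_mask]); cr <- mean(pr[cyto_mask])
    mask <- (pg > k_threshold * cg) | (pr > k_threshold * cr)
    area <- sum(mask) * ps^2
    for (ch in c("green", "red")) {
      proj <- if (ch == "green") pg else pr
      cm <- if (ch == "green") cg else cr
      mn <- if (any(mask)) mean(proj[mask]) - cm else 0
      rows[[(t - 1) * 2 + (ch == "red") + 1]] <- data.frame(
        time_min = (t - 1) * dt_min, channel = ch, cycles = t - 1L,
        ib_area_um2 = area, ib_mean = mn, ib_integrated = area * mn,
        cyto_mean = cm)
    }
  }
  fs <- do.call(rbind, rows)
  fs$ib_corrected <- fs$ib_integrated / ret[fs$channel]^fs$cycles
  fs$cyto_corrected <- fs$cyto_mean / ret[fs$channel]^fs$cycles
  red <- fs$channel == "red"
  fs$normalized <- NA_real_
  if (any(red) && max(fs$ib_corrected[red]) > 0)
    fs$normalized[red] <- fs$ib_corrected[red] / max(fs$ib_corrected[red])
  grn <- fs$channel == "green"
  if (any(grn) && fs$ib_corrected[grn][1] > 0)
    fs$normalized[grn] <- fs$ib_corrected[grn] / fs$ib_corrected[grn][1]
  attr(fs, "bleach_retention") <- ret
  attr(fs, "corrected") <- TRUE
  class(fs) <- c("flux_series", "data.frame")
  fs
}

#' Predicted fluorescence remaining after dilution
#'
#' The remaining fraction is the reciprocal of the dilution factor. When the
#' factor is not given directly, the naive compounded factor
#' `(1 + daughter_fraction)^n_cycles` is derived and flagged as an
#' alternative derivation.
#'
#' @param dilution_factor overall dilution factor (>= 1).
#' @param n_cycles number of division cycles (alternative derivation).
#' @param daughter_fraction relative daughter size (alternative derivation).
#' @return list with `remaining_fraction`, `percent`, the factor used, and
#'   (when derived) `derivation = "compounded"`.
#' @examples
#' predict_dilution(3.7)$percent   # 27.03
#' @export
predict_dilution <- function(dilution_factor = NULL, n_cycles = NULL,
                             daughter_fraction = NULL) {
  if (is.null(dilution_factor)) {
    if (is.null(n_cycles) || is.null(daughter_fraction))
      stop("give dilution_factor, or n_cycles with daughter_fraction",
           call. = FALSE)
    dilution_factor <- (1 + daughter_fraction)^n_cycles
    derivation <- "compounded"
  } else derivation <- "given"
  if (dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  out <- list(remaining_fraction = 1 / dilution_factor,
              percent = 100 / dilution_factor,
              dilution_factor = dilution_factor,
              derivation = derivation)
  if (derivation == "given" && !is.null(n_cycles) &&
      !is.null(daughter_fraction)) {
    out$alternative_factor <- (1 + daughter_fraction)^n_cycles
    out$alternative_derivation <- "compounded"
  }
  out
}

#' Regress recovered IB fluorescence on its candidate sources
#'
#' Two ordinary least-squares fits of the total recovered IB fluorescence:
#' against the post-bleach cytoplasmic intensity, and against the pre-bleach
#' IB total. A strong linear dependence on the cytoplasm (and none on the
#' pre-bleach total) indicates that recovery is material entering from the
#' cytoplasm rather than fluorophore dequenching in place.
#'
#' @param recovered_ib_totals recovered IB totals (response).
#' @param post_bleach_cytoplasm post-bleach cytoplasmic intensities.
#' @param pre_bleach_ib_totals pre-bleach IB totals.
#' @return list of two fits (`vs_cytoplasm`, `vs_prebleach`), each with
#'   `slope`, `intercept`, `r_squared`.
#' @export
recovery_regression <- function(recovered_ib_totals, post_bleach_cytoplasm,
                                pre_bleach_ib_totals) {
  n <- length(recovered_ib_totals)
  if (n < 3 || length(post_bleach_cytoplasm) != n ||
      length(pre_bleach_ib_totals) != n)
    stop("need >= 3 paired observations", call. = FALSE)
  one <- function(x, label) {
    if (stats::var(x) == 0)
      stop("not estimable: zero-variance predictor (", label, ")",
           call. = FALSE)
    f <- stats::lm(recovered_ib_totals ~ x)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r_squared = summary(f)$r.squared)
  }
  list(vs_cytoplasm = one(post_bleach_cytoplasm, "cytoplasm"),
       vs_prebleach = one(pre_bleach_ib_totals, "pre-bleach"))
}

#' Locate the maximum of a turnover trace and the drop to the final point
#'
#' @param values corrected intensity trace (>= 3 points).
#' @param time_min timepoints, minutes.
#' @return list with `time_of_max` (min), `max_value`, `final_value` and
#'   `percent_drop` (`100 * (max - final) / max`; 0 for a monotone rise, in
#'   which case `time_of_max` is the final time).
#' @examples
#' turnover_summary(c(1, 2, 1.3), c(0, 60, 210))   # 35% drop at 60 min
#' @export
turnover_summary <- function(values, time_min) {
  if (length(values) < 3) stop("need >= 3 timepoints", call. = FALSE)
  i_max <- which.max(values)
  final <- values[length(values)]
  drop <- 100 * (values[i_max] - final) / values[i_max]
  if (drop <= 0 || i_max == length(values)) {
    return(list(time_of_max = time_min[length(values)],
                max_value = final, final_value = final, percent_drop = 0))
  }
  list(time_of_max = time_min[i_max], max_value = values[i_max],
       final_value = final, percent_drop = drop)
}

#' Extract one channel of a flux series as a turnover trace
#'
#' Convenience accessor: corrected (or measured) IB trace of one channel.
#'
#' @param series a `flux_series`.
#' @param channel `"red"` or `"green"`.
#' @param corrected logical; divide out the recorded observation bleach.
#' @return data frame with `time_min` and `value`.
#' @export
flux_trace <- function(series, channel, corrected = TRUE) {
  stopifnot(inherits(series, "flux_series"))
  sel <- series$channel == channel
  v <- series$ib_integrated[sel]
  if (corrected && !isTRUE(attr(series, "corrected"))) {
    ret <- attr(series, "bleach_retention")[channel]
    v <- v / ret^series$cycles[sel]
  }
  data.frame(time_min = series$time_min[sel], value = v)
}

#' Fit the two-pool pulse-chase model to a measured flux series
#'
#' Recovers the exchange and degradation rates (`k_in`, `k_out`, `k_deg`)
#' from the red-channel cytoplasm and IB time courses of a [flux_series] by
#' least squares against the forward model of [simulate_pulse_chase]
#' (deterministic mode), optimising over log-rates with `optim`
#' (Nelder-Mead, multiple starts). The conversion fraction, initial
#' amounts, division schedule and observation bleach are taken as known
#' (they are measured or calibrated separately in an experiment).
#'
#' @param series a `flux_series` from [simulate_pulse_chase] or
#'   [pulse_chase_quantify] (needs red-channel `ib_integrated` and
#'   `cyto_mean`).
#' @param model a [pulse_chase_model] carrying the known quantities; its
#'   rate entries are ignored (starts are fixed generic values).
#' @param config the [acquisition_config] used for the observations.
#' @param n_starts number of optimiser starts.
#' @return list with `k_in`, `k_out`, `k_deg`, the achieved `sse` and the
#'   refitted model.
#' @export
fit_pulse_chase <- function(series, model, config, n_starts = 3) {
  stopifnot(inherits(series, "flux_series"),
            inherits(model, "pulse_chase_model"))
  red <- series[series$channel == "red", ]
  times <- red$time_min
  obs <- c(red$ib_integrated, red$cyto_mean)
  scale <- mean(abs(obs))
  retention <- rep_len(config$bleach_retention, 2)[2]
  bleach <- retention^red$cycles

  objective <- function(logk) {
    k <- exp(logk)
    m <- model
    m$k_in <- k[1]; m$k_out <- k[2]; m$k_deg <- k[3]
    st <- pc_integrate(m, times)
    pred <- c(st[, "red_ib"] * bleach, st[, "red_cyto"] * bleach)
    sum(((pred - obs) / scale)^2)
  }

  starts <- list(log(c(0.05, 0.02, 0.02)),
                 log(c(0.01, 0.005, 0.005)),
                 log(c(0.1, 0.05, 0.01)))
  best <- NULL
  for (s in starts[seq_len(min(n_starts, length(starts)))]) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  k <- exp(best$par)
  refit <- model
  refit$k_in <- k[1]; refit$k_out <- k[2]; refit$k_deg <- k[3]
  list(k_in = k[1], k_out = k[2], k_deg = k[3], sse = best$value,
       model = refit)
}
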