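# Mean squared displacement and anomalous-diffusion analysis.

#' Compute the mean squared displacement of a track
#'
#' For each lag k (1 to `max_lag` frames) the squared 2-D Euclidean
#' displacement is averaged over every possible (overlapping) start frame.
#' Lag times come from the track's timestamps.
#'
#' @param track a `track` data frame with columns `x`, `y` and `t` (or a
#'   plain data frame with those columns). Units of `x`/`y` carry through.
#' @param max_lag maximum lag in frames (default 16); silently truncated to
#'   `n - 1` for shorter tracks (with a warning).
#' @return an `msd_curve` data frame with columns `lag_frames`, `dt_s`,
#'   `msd` and `n_intervals`.
#' @examples
#' tr <- simulate_trajectory(motion_model("brownian", 0.059), 300, 1/32, seed = 1)
#' head(compute_msd(tr))
#' @export
compute_msd <- function(track, max_lag = 16) {
  if (nrow(track) < 2)
    stop("track must have at least 2 points", call. = FALSE)
  n <- nrow(track)
  if (max_lag > n - 1) {
    warning(sprintf("track has %d frames; max_lag truncated to %d", n, n - 1),
            call. = FALSE)
    max_lag <- n - 1
  }
  dt <- mean(diff(track$t))
  out <- data.frame(
    lag_frames = seq_len(max_lag),
    dt_s = seq_len(max_lag) * dt,
    msd = vapply(seq_len(max_lag), function(k) {
      dx <- track$x[(1 + k):n] - track$x[1:(n - k)]
      dy <- track$y[(1 + k):n] - track$y[1:(n - k)]
      mean(dx^2 + dy^2)
    }, numeric(1)),
    n_intervals = n - seq_len(max_lag))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the anomalous-diffusion exponent
#'
#' Ordinary least squares of `log10(msd)` against `log10(dt)`; the slope is
#' the anomalous-diffusion exponent alpha (1 for free diffusion, > 1 for
#' directed transport, 2 for ballistic motion). Zero-MSD lags are excluded
#' with a warning.
#'
#' @param msd an `msd_curve` from [compute_msd].
#' @return a `motion_estimate` list with `alpha`, `r_squared`,
#'   `n_lags_used` and the fit intercept (log10 scale).
#' @export
fit_alpha <- function(msd) {
  ok <- msd$msd > 0
  if (any(!ok))
    warning(sprintf("%d zero-MSD lag(s) excluded from the log-log fit",
                    sum(!ok)), call. = FALSE)
  if (sum(ok) < 3)
    stop("alpha is not estimable: need >= 3 lags with positive MSD",
         call. = FALSE)
  fit <- stats::lm(log10(msd$msd[ok]) ~ log10(msd$dt_s[ok]))
  structure(
    list(alpha = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n_lags_used = sum(ok)),
    class = "motion_estimate")
}

#' @export
print.motion_estimate <- function(x, ...) {
  cat(sprintf("<motion_estimate> alpha = %.3f (r^2 = %.4f, %d lags)\n",
              x$alpha, x$r_squared, x$n_lags_used))
  invisible(x)
}

#' Estimate the diffusion coefficient
#'
#' For 2-D Brownian motion `MSD = 4 * D * t`; D is estimated as the slope of
#' the zero-intercept least-squares fit of MSD against lag time over the
#' curve's lags, divided by 4. An all-zero curve gives D = 0.
#'
#' @param msd an `msd_curve` from [compute_msd] (MSD in um^2, time in s).
#' @return the diffusion coefficient in um^2/s.
#' @examples
#' m <- data.frame(lag_frames = 1:4, dt_s = 1:4, msd = 4 * 0.05 * (1:4),
#'                 n_intervals = 10)
#' estimate_D(m)   # 0.05
#' @export
estimate_D <- function(msd) {
  if (nrow(msd) < 1) stop("need at least one lag", call. = FALSE)
  if (all(msd$msd == 0)) return(0)
  sum(msd$msd * msd$dt_s) / (4 * sum(msd$dt_s^2))
}

#' Classify motion from the fitted exponent
#'
#' Labels motion by comparing alpha to a boundary (default 1) with a
#' symmetric dead-band: `diffusive` within `boundary +/- dead_band`,
#' `superdiffusive` above, `subdiffusive` below. The dead-band avoids
#' knife-edge labels at measurement precision (reported SEMs are ~0.03-0.06).
#'
#' @param est a `motion_estimate` (or a bare numeric alpha).
#' @param boundary classification boundary for alpha.
#' @param dead_band half-width of the diffusive band.
#' @return `"diffusive"`, `"superdiffusive"` or `"subdiffusive"`.
#' @export
classify_motion <- function(est, boundary = 1, dead_band = 0.05) {
  alpha <- if (inherits(est, "motion_estimate")) est$alpha else est
  if (!is.finite(alpha)) stop("alpha must be finite", call. = FALSE)
  if (alpha > boundary + dead_band) "superdiffusive"
  else if (alpha < boundary - dead_band) "subdiffusive"
  else "diffusive"
}

#' Compare two groups of exponents (Welch's t test)
#'
#' Unpaired two-tailed t test with unequal variances (Satterthwaite degrees
#' of freedom), plus group means and SEMs.
#'
#' @param alphas_a,alphas_b numeric vectors (each n >= 2).
#' @return list with `t`, `p`, `df`, and per-group `mean` and `sem`.
#' @export
compare_groups <- function(alphas_a, alphas_b) {
  if (length(alphas_a) < 2 || length(alphas_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- tryCatch(
    stats::t.test(alphas_a, alphas_b, var.equal = FALSE),
    error = function(e) NULL)
  if (is.null(res)) {
    # degenerate: zero variance in both groups
    if (mean(alphas_a) == mean(alphas_b)) {
      res <- list(statistic = c(t = 0), p.value = 1,
                  parameter = c(df = length(alphas_a) + length(alphas_b) - 2))
    } else {
      res <- list(statistic = c(t = Inf * sign(mean(alphas_a) - mean(alphas_b))),
                  p.value = 0,
                  parameter = c(df = length(alphas_a) + length(alphas_b) - 2))
    }
  }
  list(t = unname(res$statistic), p = res$p.value, df = unname(res$parameter),
       mean_a = mean(alphas_a), sem_a = sem(alphas_a),
       mean_b = mean(alphas_b), sem_b = sem(alphas_b))
}

#' Welch's t from summary statistics
#'
#' @param mean_a,mean_b group means.
#' @param sem_a,sem_b group standard errors of the mean.
#' @param n_a,n_b group sizes.
#' @return list with `t`, `p` and Satterthwaite `df`.
#' @export
compare_groups_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b) {
  se2 <- sem_a^2 + sem_b^2
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (sem_a^4 / (n_a - 1) + sem_b^4 / (n_b - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Per-track motion estimates for an ensemble
#'
#' @param tracks list of tracks.
#' @param max_lag maximum MSD lag, frames.
#' @return data frame with one row per track: `track_id`, `alpha`,
#'   `D_um2_s`, `r2`, `class`.
#' @export
motion_table <- function(tracks, max_lag = 16) {
  rows <- lapply(seq_along(tracks), function(i) {
    m <- compute_msd(tracks[[i]], max_lag = max_lag)
    est <- fit_alpha(m)
    data.frame(track_id = i, alpha = est$alpha, D_um2_s = estimate_D(m),
               r2 = est$r_squared, class = classify_motion(est))
  })
  do.call(rbind, rows)
}
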