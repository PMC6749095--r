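#' Simulate a single-particle trajectory
#'
#' Draws a 2-D trajectory under a [motion_model]. Brownian displacements are
#' drawn per axis with variance `2 * D * frame_interval`; the directed kind
#' adds a drift step of magnitude `drift_speed * frame_interval` whose
#' direction re-orients at random with mean waiting time `drift_persistence`
#' (ballistic motion keeps its initial direction). Positions are in um.
#'
#' @param model a [motion_model].
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame interval, seconds.
#' @param seed integer seed; identical seeds give bit-identical tracks.
#' @param origin starting position `c(x, y)` in um.
#' @param field_um optional field extent `c(width, height)` in um; when given,
#'   positions are reflected at the field edges so desk-scale tracks stay in
#'   frame.
#' @return a `track` data frame with columns `frame` (0-based), `t` (s),
#'   `x`, `y` (um) and `intensity`, carrying `frame_interval` as an attribute.
#' @examples
#' tr <- simulate_trajectory(motion_model("brownian", 0.059), 100, 1/32, seed = 1)
#' head(tr)
#' @export
simulate_trajectory <- function(model, n_frames, frame_interval, seed,
                                origin = c(0, 0), field_um = NULL) {
  stopifnot(inherits(model, "motion_model"))
  if (!is.numeric(n_frames) || n_frames < 2)
    stop("n_frames must be >= 2", call. = FALSE)
  if (frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  n_frames <- as.integer(n_frames)

  xy <- with_seed(seed, {
    nstep <- n_frames - 1L
    step_sd <- sqrt(2 * model$diffusion_coefficient * frame_interval)
    dx <- if (step_sd > 0) stats::rnorm(nstep, 0, step_sd) else numeric(nstep)
    dy <- if (step_sd > 0) stats::rnorm(nstep, 0, step_sd) else numeric(nstep)
    if (model$kind %in% c("directed", "ballistic") && model$drift_speed > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      step_len <- model$drift_speed * frame_interval
      if (model$kind == "ballistic" || !is.finite(model$drift_persistence)) {
        dx <- dx + step_len * cos(theta)
        dy <- dy + step_len * sin(theta)
      } else {
        # direction resamples with per-step probability dt / persistence
        p_flip <- min(1, frame_interval / model$drift_persistence)
        flips <- stats::runif(nstep) < p_flip
        angles <- numeric(nstep)
        cur <- theta
        new_angles <- stats::runif(nstep, 0, 2 * pi)
        for (i in seq_len(nstep)) {
          if (flips[i]) cur <- new_angles[i]
          angles[i] <- cur
        }
        dx <- dx + step_len * cos(angles)
        dy <- dy + step_len * sin(angles)
      }
    }
    cbind(x = origin[1] + cumsum(c(0, dx)),
          y = origin[2] + cumsum(c(0, dy)))
  })

  if (!is.null(field_um)) {
    xy[, 1] <- reflect_into(xy[, 1], field_um[1])
    xy[, 2] <- reflect_into(xy[, 2], field_um[2])
  }

  tr <- data.frame(frame = 0:(n_frames - 1L),
                   t = (0:(n_frames - 1L)) * frame_interval,
                   x = xy[, 1], y = xy[, 2],
                   intensity = 1)
  attr(tr, "frame_interval") <- frame_interval
  attr(tr, "model") <- model
  attr(tr, "seed") <- seed
  class(tr) <- c("track", "data.frame")
  tr
}

# reflect coordinates into [0, L] (triangle-wave folding)
reflect_into <- function(x, L) {
  stopifnot(L > 0)
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' Simulate an ensemble of trajectories
#'
#' Convenience wrapper drawing `n_tracks` independent trajectories with
#' per-track seeds derived from `seed` (seed + track index).
#'
#' @inheritParams simulate_trajectory
#' @param n_tracks number of tracks.
#' @return a list of `track` data frames.
#' @export
simulate_ensemble <- function(model, n_tracks, n_frames, frame_interval, seed,
                              origin = c(0, 0), field_um = NULL) {
  lapply(seq_len(n_tracks), function(i)
    simulate_trajectory(model, n_frames, frame_interval,
                        seed = seed + i, origin = origin, field_um = field_um))
}
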