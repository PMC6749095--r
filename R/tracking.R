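# Dynamic-programming single-particle linking.
#
# One particle per movie: per-frame candidates are linked into the single
# globally optimal path under a hard displacement bound, exactly as a
# shortest-path problem over the frame-ordered candidate graph.

#' Link per-frame candidates into one particle track
#'
#' Finds the path through the per-frame candidates maximising
#'
#' `sum over frames of [ w_intensity * r  +  w_intensity_variation * (1 - |r - r_prev| / max(r_prev, eps))
#'    - w_movement * step / max_displacement  -  w_center * d_center / field_radius ]`
#'
#' where `r` is the candidate's filter response min-max normalised over the
#' whole movie, subject to every step being at most `max_displacement`
#' pixels. The optimum is found exactly by per-frame dynamic programming;
#' ties are broken deterministically (higher response first, then lower
#' candidate index). The first frame of a path contributes its intensity and
#' center terms only.
#'
#' If no feasible transition exists at some frame (a jump above the
#' displacement bound, or a frame without candidates), the track is broken
#' there: the longest feasible segment is returned with a warning and a
#' `broken` attribute recording the break frames.
#'
#' @param candidates data frame of candidates as from [detect_movie]:
#'   columns `frame` (0-based), `x`, `y` (px) and `score`.
#' @param params a [tracking_params].
#' @param start_hint optional `c(x, y)` position; first-frame candidates are
#'   additionally penalised by `w_movement * distance(hint) / max_displacement`.
#' @param field_px optional `c(ny, nx)` image size; required only when
#'   `w_center > 0`.
#' @param calibration optional list with `pixel_size` (um/px) and
#'   `frame_interval` (s) used to add physical columns to the output.
#' @return a `track` data frame (columns `frame`, `t`, `x`, `y`,
#'   `intensity`; positions in px, plus `x_um`/`y_um` when calibrated) with
#'   attributes `score` (the DP objective) and `broken`/`break_frames` when
#'   the path was interrupted.
#' @export
track_particle <- function(candidates, params = tracking_params(),
                           start_hint = NULL, field_px = NULL,
                           calibration = NULL) {
  stopifnot(inherits(params, "tracking_params"))
  if (!all(c("frame", "x", "y", "score") %in% names(candidates)))
    stop("candidates need columns frame, x, y, score", call. = FALSE)
  frames <- sort(unique(candidates$frame))
  if (length(frames) < 2)
    stop("need candidates in at least 2 frames", call. = FALSE)

  # movie-wide min-max normalisation of responses
  rng <- range(candidates$score)
  r_all <- if (diff(rng) > 0) (candidates$score - rng[1]) / diff(rng)
           else rep(1, nrow(candidates))
  cand <- split(
    data.frame(x = candidates$x, y = candidates$y, r = r_all,
               score = candidates$score),
    factor(candidates$frame, levels = frames))

  center <- if (!is.null(field_px)) c(field_px[2], field_px[1]) / 2 else c(0, 0)
  field_radius <- if (!is.null(field_px)) sqrt(sum((field_px / 2)^2)) else 1
  if (params$w_center > 0 && is.null(field_px))
    stop("w_center > 0 requires field_px", call. = FALSE)
  eps <- 1e-9

  node_gain <- function(df) {
    g <- params$w_intensity * df$r
    if (params$w_center > 0) {
      d <- sqrt((df$x - center[1])^2 + (df$y - center[2])^2)
      g <- g - params$w_center * d / field_radius
    }
    g
  }

  # DP over one contiguous run of frames; returns list(path indices, score)
  dp_run <- function(fr_idx) {
    nfr <- length(fr_idx)
    score <- vector("list", nfr)
    back <- vector("list", nfr)
    df1 <- cand[[fr_idx[1]]]
    s <- node_gain(df1)
    if (!is.null(start_hint)) {
      d <- sqrt((df1$x - start_hint[1])^2 + (df1$y - start_hint[2])^2)
      s <- s - params$w_movement * d / params$max_displacement
    }
    score[[1]] <- s
    reached <- 1L
    for (k in 2:nfr) {
      a <- cand[[fr_idx[k - 1]]]
      b <- cand[[fr_idx[k]]]
      sc <- rep(-Inf, nrow(b))
      bk <- rep(NA_integer_, nrow(b))
      gb <- node_gain(b)
      for (j in seq_len(nrow(b))) {
        d <- sqrt((b$x[j] - a$x)^2 + (b$y[j] - a$y)^2)
        ok <- which(d <= params$max_displacement & is.finite(score[[k - 1]]))
        if (!length(ok)) next
        trans <- params$w_intensity_variation *
          (1 - abs(b$r[j] - a$r[ok]) / pmax(a$r[ok], eps)) -
          params$w_movement * d[ok] / params$max_displacement
        tot <- score[[k - 1]][ok] + trans + gb[j]
        # deterministic argmax: best score, then higher predecessor response,
        # then lower predecessor index
        best <- order(-tot, -a$r[ok], ok)[1]
        sc[j] <- tot[best]; bk[j] <- ok[best]
      }
      if (all(!is.finite(sc))) return(list(upto = k - 1L, score = score, back = back))
      score[[k]] <- sc
      back[[k]] <- bk
      reached <- k
    }
    list(upto = reached, score = score, back = back)
  }

  extract <- function(run, fr_idx) {
    upto <- run$upto
    sc <- run$score[[upto]]
    last <- order(-sc, -cand[[fr_idx[upto]]]$r,
                  seq_along(sc))[1]
    path <- integer(upto)
    path[upto] <- last
    if (upto > 1) for (k in upto:2) path[k - 1] <- run$back[[k]][path[k]]
    list(path = path, score = sc[last], frames = fr_idx[seq_len(upto)])
  }

  # split frames at gaps in coverage, run DP per run, break further on
  # infeasible jumps, keep the longest feasible segment
  gap_breaks <- which(diff(frames) > 1)
  run_starts <- c(1, gap_breaks + 1)
  run_ends <- c(gap_breaks, length(frames))
  segments <- list()
  break_frames <- integer(0)
  for (rn in seq_along(run_starts)) {
    lo <- run_starts[rn]
    while (lo <= run_ends[rn]) {
      fr_idx <- lo:run_ends[rn]
      if (length(fr_idx) == 1) {
        j <- order(-cand[[fr_idx]]$r)[1]
        segments[[length(segments) + 1]] <-
          list(path = j, score = node_gain(cand[[fr_idx]])[j], frames = fr_idx)
        break
      }
      run <- dp_run(fr_idx)
      seg <- extract(run, fr_idx)
      segments[[length(segments) + 1]] <- seg
      if (run$upto < length(fr_idx)) {
        break_frames <- c(break_frames, frames[fr_idx[run$upto]])
        lo <- fr_idx[run$upto] + 1L
      } else break
    }
  }
  if (length(gap_breaks))
    break_frames <- c(break_frames, frames[gap_breaks])

  lens <- vapply(segments, function(s) length(s$frames), integer(1))
  seg <- segments[[which.max(lens)]]
  broken <- length(segments) > 1 || length(break_frames) > 0
  if (broken)
    warning(sprintf(
      "no feasible path through all frames; returning longest segment (%d frames), broken at frame(s) %s",
      length(seg$frames), paste(break_frames, collapse = ", ")), call. = FALSE)

  rows <- lapply(seq_along(seg$frames), function(k) {
    df <- cand[[seg$frames[k]]]
    j <- seg$path[k]
    data.frame(frame = frames[seg$frames[k]], x = df$x[j], y = df$y[j],
               intensity = df$score[j])
  })
  tr <- do.call(rbind, rows)
  dtf <- if (!is.null(calibration)) calibration$frame_interval else 1
  tr$t <- tr$frame * dtf
  tr <- tr[, c("frame", "t", "x", "y", "intensity")]
  if (!is.null(calibration)) {
    tr$x_um <- tr$x * calibration$pixel_size
    tr$y_um <- tr$y * calibration$pixel_size
  }
  attr(tr, "score") <- seg$score
  attr(tr, "params") <- params
  if (broken) {
    attr(tr, "broken") <- TRUE
    attr(tr, "break_frames") <- break_frames
  }
  class(tr) <- c("track", "data.frame")
  tr
}
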