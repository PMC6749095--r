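# Readers and writers: TIFF stacks with YAML calibration sidecars, track and
# candidate tables as CSV with calibration headers, and a small pipeline
# driver tying the stages together.
#
# Conventions: axis order TZCYX everywhere; 0-based frame and pixel indices
# in tabular output; physical units um / s / min stated in column names.

#' Write an image stack to TIFF with a YAML sidecar
#'
#' Pixel data go to a multi-page 32-bit float TIFF (pages in T-major, then
#' Z, then C order); dimensions, axis order and physical calibration go to a
#' `<path>.yaml` sidecar.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  pages <- list()
  # normalise to [0,1] for TIFF float storage with recorded scale
  mx <- max(stack, 1e-12)
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3]))
    pages[[length(pages) + 1]] <- stack_frame(stack, t, z, c) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "TZCYX",
               shape = as.integer(d),
               pixel_size_um = attr(stack, "pixel_size"),
               frame_interval_s = attr(stack, "frame_interval"),
               z_spacing_um = attr(stack, "z_spacing"),
               channels = attr(stack, "channels"),
               intensity_scale = mx)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack]
#'
#' Axes are restored to TZCYX from the sidecar. Calibration must come from
#' the sidecar or from the override arguments; a stack without calibration
#' is an error, never a silent default. Overrides win over sidecar values.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,z_spacing optional calibration
#'   overrides (um, s, um).
#' @return an [image_stack].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       z_spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  ps <- pixel_size %||% meta$pixel_size_um
  fi <- frame_interval %||% meta$frame_interval_s
  zs <- z_spacing %||% meta$z_spacing_um
  if (is.null(ps) || is.null(fi))
    stop("missing calibration: supply pixel_size and frame_interval ",
         "or provide the YAML sidecar", call. = FALSE)
  shape <- meta$shape %||% c(length(pages), 1L, 1L, dim(pages[[1]]))
  if (prod(shape[1:3]) != length(pages))
    stop("axis mismatch: sidecar shape does not match page count",
         call. = FALSE)
  scale <- meta$intensity_scale %||% 1
  data <- array(0, dim = shape)
  i <- 0L
  for (t in seq_len(shape[1])) for (z in seq_len(shape[2]))
    for (c in seq_len(shape[3])) {
      i <- i + 1L
      data[t, z, c, , ] <- pages[[i]] * scale
    }
  image_stack(data, pixel_size = ps, frame_interval = fi,
              z_spacing = zs %||% ps,
              channels = meta$channels %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a track table to CSV with a calibration header
#'
#' Columns `track_id, frame, t_seconds, x_um, y_um, intensity`; calibration
#' is recorded in commented header lines.
#'
#' @param tracks a track or list of tracks (positions in um).
#' @param path output CSV path.
#' @param pixel_size,frame_interval calibration recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, pixel_size = NA, frame_interval = NA) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frame, t_seconds = tr$t,
               x_um = if ("x_um" %in% names(tr)) tr$x_um else tr$x,
               y_um = if ("y_um" %in% names(tr)) tr$y_um else tr$y,
               intensity = tr$intensity)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_um: %s", pixel_size),
               sprintf("# frame_interval_s: %s", frame_interval)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_tracks]
#'
#' @param path CSV path.
#' @return a list of `track` data frames (one per `track_id`).
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, df$track_id), function(d) {
    tr <- data.frame(frame = d$frame, t = d$t_seconds,
                     x = d$x_um, y = d$y_um, intensity = d$intensity)
    class(tr) <- c("track", "data.frame")
    tr
  })
}

#' Run a sequence of pipeline stages
#'
#' Thin driver for the simulate / detect / track / msd stages on one movie,
#' recording the seed and parameters with every output. Stages:
#' `"simulate"` (trajectory ensemble), `"render"`, `"detect"`, `"track"`,
#' `"msd"`. Later stages consume the outputs of earlier ones; `"msd"` falls
#' back to the simulated ground-truth tracks when the imaging stages are
#' skipped.
#'
#' @param config list with entries `model` (a [motion_model]), `acquisition`
#'   (an [acquisition_config]), `n_tracks`, `n_frames`, `seed`, and optional
#'   `detect` (list: sigma, min_size_px) and `tracking` (a
#'   [tracking_params]).
#' @param stages character vector of stage names, in order.
#' @return a report list with one element per executed stage plus `config`
#'   and `seed`; the `"msd"` element is a per-track estimates table with
#'   mean alpha and SEM.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "render", "detect", "track",
                                    "msd")) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(config = config, seed = config$seed)
  known <- c("simulate", "render", "detect", "track", "msd")
  stages <- known[known %in% stages]

  if ("simulate" %in% stages) {
    field <- config$acquisition$field_px * config$acquisition$pixel_size
    report$simulate <- simulate_ensemble(
      config$model, config$n_tracks, config$n_frames,
      config$acquisition$frame_interval, seed = config$seed,
      origin = field / 2, field_um = field)
  }
  if ("render" %in% stages) {
    if (is.null(report$simulate))
      stop("missing upstream artifact: stage 'render' needs 'simulate'",
           call. = FALSE)
    report$render <- lapply(seq_along(report$simulate), function(i)
      render_timelapse(list(report$simulate[[i]]), config$acquisition,
                       seed = config$seed + 1000 + i))
  }
  if ("detect" %in% stages) {
    if (is.null(report$render))
      stop("missing upstream artifact: stage 'detect' needs 'render'",
           call. = FALSE)
    det <- config$detect %||% list(sigma = 1.5, min_size_px = 2)
    report$detect <- lapply(report$render, function(mv)
      detect_movie(mv$stack, sigma = det$sigma,
                   min_size_px = det$min_size_px))
  }
  if ("track" %in% stages) {
    if (is.null(report$detect))
      stop("missing upstream artifact: stage 'track' needs 'detect'",
           call. = FALSE)
    params <- config$tracking %||% tracking_params()
    cal <- list(pixel_size = config$acquisition$pixel_size,
                frame_interval = config$acquisition$frame_interval)
    report$track <- lapply(report$detect, function(cand)
      track_particle(cand, params, calibration = cal))
  }
  if ("msd" %in% stages) {
    tracks <- if (!is.null(report$track)) {
      lapply(report$track, function(tr) {
        data.frame(frame = tr$frame, t = tr$t, x = tr$x_um, y = tr$y_um)
      })
    } else if (!is.null(report$simulate)) report$simulate
    else stop("missing upstream artifact: stage 'msd' needs 'track' or 'simulate'",
              call. = FALSE)
    est <- motion_table(tracks)
    attr(est, "mean_alpha") <- mean(est$alpha)
    attr(est, "sem_alpha") <- stats::sd(est$alpha) / sqrt(nrow(est))
    report$msd <- est
  }
  report
}
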