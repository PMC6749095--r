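# Rendering of synthetic fluorescence images.
#
# Pixel (iy, ix) (0-based) has its center at physical position
# ((ix + 0.5) * pixel_size, (iy + 0.5) * pixel_size); x runs along columns
# and y along rows.

# sample a 2-D Gaussian spot of given amplitude onto an image matrix
add_gaussian_spot <- function(img, x_px, y_px, amplitude, sigma_px) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- (seq_len(nx) - 0.5)
  cy <- (seq_len(ny) - 0.5)
  gx <- exp(-(cx - x_px)^2 / (2 * sigma_px^2))
  gy <- exp(-(cy - y_px)^2 / (2 * sigma_px^2))
  img + amplitude * outer(gy, gx)
}

apply_camera_noise <- function(img, config) {
  if (isTRUE(config$shot_noise)) {
    img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
  }
  if (config$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, config$read_noise_sd)
  }
  img
}

#' Render a time-lapse movie from particle trajectories
#'
#' Each particle is rendered as a 2-D Gaussian of `psf_sigma` on
#' `background_level`. Intensity of frame `t` (0-based) is attenuated by
#' `bleach_retention^t`. If enabled, Poisson shot noise is applied to the
#' signal and then Gaussian read noise, in that order.
#'
#' @param tracks a list of `track` data frames (positions in um; see
#'   [simulate_trajectory]).
#' @param config an [acquisition_config]; `field_px` sets the image size.
#' @param seed integer seed for the noise draws.
#' @param amplitude peak spot amplitude above background, A.U. (recycled per
#'   track and scaled by each track's `intensity` column).
#' @param out_of_field `"error"` to reject tracks leaving the field,
#'   `"clip"` to render only the in-field parts.
#' @return a list with elements `stack` (an [image_stack]) and
#'   `ground_truth` (list of tracks, the config, and the seed).
#' @examples
#' tr <- simulate_trajectory(motion_model("brownian", 0.05), 10, 1/32, seed = 1,
#'                           origin = c(3.2, 3.2))
#' mv <- render_timelapse(list(tr), acquisition_config(1/32), seed = 2)
#' dim(mv$stack)
#' @export
render_timelapse <- function(tracks, config, seed, amplitude = 1000,
                             out_of_field = c("error", "clip")) {
  stopifnot(inherits(config, "acquisition_config"))
  out_of_field <- match.arg(out_of_field)
  if (inherits(tracks, "track")) tracks <- list(tracks)
  ny <- config$field_px[1]; nx <- config$field_px[2]
  ps <- config$pixel_size
  sigma_px <- config$psf_sigma / ps
  n_frames <- max(vapply(tracks, function(tr) max(tr$frame) + 1L, integer(1)))
  amplitude <- rep_len(amplitude, length(tracks))
  retention <- config$bleach_retention[1]

  for (tr in tracks) {
    px <- tr$x / ps; py <- tr$y / ps
    if (any(px < 0 | px > nx | py < 0 | py > ny)) {
      if (out_of_field == "error")
        stop("track leaves the field; use out_of_field = \"clip\" to allow",
             call. = FALSE)
    }
  }

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames) - 1L, function(fr) {
      img <- matrix(config$background_level, ny, nx)
      for (k in seq_along(tracks)) {
        tr <- tracks[[k]]
        row <- which(tr$frame == fr)
        if (!length(row)) next
        px <- tr$x[row] / ps; py <- tr$y[row] / ps
        if (px < 0 || px > nx || py < 0 || py > ny) next
        amp <- amplitude[k] * tr$intensity[row] * retention^fr
        img <- add_gaussian_spot(img, px, py, amp, sigma_px)
      }
      apply_camera_noise(img, config)
    })
  })

  data <- array(0, dim = c(n_frames, 1, 1, ny, nx))
  for (fr in seq_len(n_frames)) data[fr, 1, 1, , ] <- frames[[fr]]
  stack <- image_stack(data, pixel_size = ps,
                       frame_interval = config$frame_interval,
                       z_spacing = config$z_spacing,
                       channels = config$channels[1])
  list(stack = stack,
       ground_truth = list(tracks = tracks, config = config, seed = seed))
}

#' Render a cell z-stack with inclusions
#'
#' Builds a synthetic cell: a circular cytoplasm at a configurable mean
#' intensity, a darker vacuole, and ovoid inclusions rendered as filled
#' ellipsoids, each slice optionally blurred by the Gaussian PSF. A
#' ground-truth label stack marks each inclusion.
#'
#' @param inclusions list of inclusion specs; each a list with `center`
#'   (`c(x, y, z)` um), `radii` (`c(rx, ry, rz)` um) and `intensity`
#'   (mean intensity relative to cytoplasm, e.g. 1.6).
#' @param config an [acquisition_config]; `field_px` sets the slice size.
#' @param seed integer seed for the noise draws.
#' @param n_z number of z planes.
#' @param cytoplasm_level mean cytoplasmic intensity, A.U.
#' @param cell_center,cell_radius cytoplasm disc (um); defaults to a disc
#'   filling most of the field.
#' @param vacuole optional list with `center` (`c(x, y)` um) and `radius`
#'   (um); rendered at 30% of the cytoplasm level.
#' @param blur logical; blur each slice with the PSF.
#' @param allow_merge logical; if `FALSE`, overlapping inclusion specs are an
#'   error.
#' @return list with `stack` (an [image_stack]), `labels` (integer array
#'   Z x Y x X of ground-truth inclusion ids) and `ground_truth` (the specs
#'   with their analytic equatorial areas and the area-rule class of each:
#'   `"small_particle"` below 0.01 um^2, `"IB"` otherwise).
#' @export
render_cell_zstack <- function(inclusions, config, seed, n_z = 11,
                               cytoplasm_level = 100,
                               cell_center = NULL, cell_radius = NULL,
                               vacuole = NULL, blur = TRUE,
                               allow_merge = FALSE) {
  stopifnot(inherits(config, "acquisition_config"))
  ny <- config$field_px[1]; nx <- config$field_px[2]
  ps <- config$pixel_size; zs <- config$z_spacing
  if (is.null(cell_center)) cell_center <- c(nx, ny) * ps / 2
  if (is.null(cell_radius)) cell_radius <- 0.45 * min(nx, ny) * ps
  z_mid <- (n_z - 1) / 2 * zs

  # overlap check on bounding ellipsoids
  if (length(inclusions) > 1 && !allow_merge) {
    for (i in seq_along(inclusions)) for (j in seq_len(i - 1)) {
      a <- inclusions[[i]]; b <- inclusions[[j]]
      d <- sqrt(sum((a$center - b$center)^2))
      if (d < max(a$radii) + max(b$radii))
        stop("inclusion specs overlap; set allow_merge = TRUE to merge",
             call. = FALSE)
    }
  }

  cx <- (seq_len(nx) - 0.5) * ps
  cy <- (seq_len(ny) - 0.5) * ps
  xg <- matrix(cx, ny, nx, byrow = TRUE)
  yg <- matrix(cy, ny, nx)
  cell_mask <- (xg - cell_center[1])^2 + (yg - cell_center[2])^2 <= cell_radius^2

  data <- array(0, dim = c(1, n_z, 1, ny, nx))
  labels <- array(0L, dim = c(n_z, ny, nx))
  sigma_px <- config$psf_sigma / ps

  with_seed(seed, {
    for (z in seq_len(n_z)) {
      zpos <- (z - 1) * zs
      img <- matrix(config$background_level, ny, nx)
      img[cell_mask] <- cytoplasm_level
      if (!is.null(vacuole)) {
        vm <- (xg - vacuole$center[1])^2 + (yg - vacuole$center[2])^2 <=
          vacuole$radius^2
        img[vm & cell_mask] <- 0.3 * cytoplasm_level
      }
      for (k in seq_along(inclusions)) {
        inc <- inclusions[[k]]
        zc <- if (length(inc$center) >= 3) inc$center[3] else z_mid
        rz <- if (length(inc$radii) >= 3) inc$radii[3] else inc$radii[1]
        dz2 <- ((zpos - zc) / rz)^2
        if (dz2 >= 1) next
        inside <- ((xg - inc$center[1]) / inc$radii[1])^2 +
          ((yg - inc$center[2]) / inc$radii[2])^2 <= (1 - dz2)
        img[inside] <- inc$intensity * cytoplasm_level
        labels[z, , ][inside] <- k
      }
      if (blur && sigma_px > 0)
        img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma_px))
      img <- apply_camera_noise(img, config)
      data[1, z, 1, , ] <- img
    }
  })

  eq_area <- vapply(inclusions, function(inc)
    pi * inc$radii[1] * inc$radii[2], numeric(1))
  gt <- data.frame(
    id = seq_along(inclusions),
    equatorial_area_um2 = eq_area,
    class = ifelse(eq_area < 0.01, "small_particle", "IB"))

  stack <- image_stack(data, pixel_size = ps,
                       frame_interval = config$frame_interval,
                       z_spacing = zs, channels = config$channels[1])
  list(stack = stack, labels = labels,
       ground_truth = list(objects = gt, specs = inclusions,
                           cytoplasm_level = cytoplasm_level, seed = seed))
}
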