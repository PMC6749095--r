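#' Multi-dimensional image stack
#'
#' The common currency of all image operations: a 5-D numeric array in TZCYX
#' order (time, z, channel, y, x) carrying physical calibration as attributes.
#' Frame, plane and pixel indices are 0-based in all tabular output; inside R
#' the usual 1-based array indexing applies.
#'
#' @param data numeric array; 2-D (Y, X) arrays are promoted to T = Z = C = 1,
#'   3-D (T, Y, X) to Z = C = 1, and 5-D arrays are taken as TZCYX.
#' @param pixel_size lateral pixel size, um.
#' @param frame_interval time between frames, seconds.
#' @param z_spacing axial spacing, um.
#' @param channels character vector of channel names (length C).
#' @return an `image_stack` object.
#' @examples
#' s <- image_stack(matrix(0, 16, 16), pixel_size = 0.1, frame_interval = 1)
#' dim(s)
#' @export
image_stack <- function(data, pixel_size, frame_interval, z_spacing = pixel_size,
                        channels = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1, 1, 1, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3) {
    d <- dim(data)
    data <- array(data, dim = c(d[1], 1, 1, d[2], d[3]))
  } else if (length(dim(data)) != 5) {
    stop("data must be a 2-D, 3-D (T,Y,X) or 5-D (T,Z,C,Y,X) array",
         call. = FALSE)
  }
  if (missing(pixel_size) || missing(frame_interval))
    stop("pixel_size and frame_interval calibration are required", call. = FALSE)
  if (pixel_size <= 0 || frame_interval <= 0 || z_spacing <= 0)
    stop("calibration values must be > 0", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
  structure(data,
            pixel_size = pixel_size,
            frame_interval = frame_interval,
            z_spacing = z_spacing,
            channels = channels,
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> T=%d Z=%d C=%d %dx%d px | %.3g um/px, %.3g s/frame, %.3g um z\n",
    d[1], d[2], d[3], d[4], d[5],
    attr(x, "pixel_size"), attr(x, "frame_interval"), attr(x, "z_spacing")))
  invisible(x)
}

#' Extract one 2-D frame from a stack
#'
#' @param stack an [image_stack].
#' @param t,z,c 1-based time, z and channel indices.
#' @return a numeric Y-by-X matrix.
#' @export
stack_frame <- function(stack, t = 1, z = 1, c = 1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  if (t > d[1] || z > d[2] || c > d[3]) stop("index out of range", call. = FALSE)
  matrix(stack[t, z, c, , ], d[4], d[5])
}

#' Maximum-intensity projection along z
#'
#' @param stack an [image_stack].
#' @param t,c 1-based time and channel indices.
#' @return a numeric Y-by-X matrix.
#' @export
max_projection <- function(stack, t = 1, c = 1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  out <- matrix(-Inf, d[4], d[5])
  for (z in seq_len(d[2])) out <- pmax(out, stack_frame(stack, t, z, c))
  out
}

#' @export
`[.image_stack` <- function(x, ...) {
  out <- NextMethod()
  out
}
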