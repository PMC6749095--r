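# Spot enhancement (scale-normalised Laplacian of Gaussian) and candidate
# detection for single-particle tracking.

#' Laplacian-of-Gaussian kernel
#'
#' Scale-normalised negative LoG: `sigma^2 * (-Laplacian(Gaussian(sigma)))`,
#' truncated at `radius = ceiling(4 * sigma)` and shifted to exact zero mean
#' so that constant images map to zero. Bright blobs of radius
#' `sigma * sqrt(2)` produce positive maxima at their centers, and responses
#' are comparable across sigma (standard blob-detection normalisation).
#'
#' @param sigma kernel scale, pixels.
#' @return a square numeric matrix of odd size.
#' @export
log_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g <- outer(x, x, function(i, j) {
    r2 <- i^2 + j^2
    # negative LoG times sigma^2
    (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2)) / (pi * sigma^2)
  })
  g - mean(g)
}

#' Spot-enhancing filter (2-D)
#'
#' Convolves a frame with the scale-normalised negative
#' Laplacian-of-Gaussian kernel of [log_kernel], using reflective padding at
#' the borders. The response is zero-mean on constant input and linear in the
#' image, so intensity offsets are annihilated. An optional Gaussian
#' pre-smooth is available as a documented denoising stage.
#'
#' @param image a 2-D numeric matrix (single frame).
#' @param sigma LoG scale in pixels; must be below half the smaller image
#'   dimension.
#' @param presmooth_sigma optional Gaussian pre-smoothing sigma in pixels
#'   (0 disables).
#' @return the filtered frame (same size).
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 1
#' f <- spot_enhancing_filter(img, sigma = 2)
#' which(f == max(f), arr.ind = TRUE)
#' @export
spot_enhancing_filter <- function(image, sigma, presmooth_sigma = 0) {
  stopifnot(is.matrix(image))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (sigma > min(dim(image)) / 2)
    stop("sigma exceeds half the image size", call. = FALSE)
  if (presmooth_sigma > 0)
    image <- as.matrix(EBImage::gblur(EBImage::Image(image),
                                      sigma = presmooth_sigma))
  k <- log_kernel(sigma)
  convolve_reflective(image, k)
}

# 2-D convolution with reflective (mirror) padding; pads by the kernel radius
# and delegates the padded convolution to EBImage::filter2.
convolve_reflective <- function(image, kernel) {
  r <- (nrow(kernel) - 1) / 2
  p <- pad_reflect(image, r)
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(p), kernel,
                                             boundary = "circular"))
  matrix(out[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image))],
         nrow(image), ncol(image))
}

pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci]
}

#' Detect candidate spots in a filtered frame
#'
#' Finds connected supra-threshold regions (8-connected) of the filter
#' response with at least `min_size_px` pixels. Each region yields one
#' candidate at its response-weighted centroid; candidates are sorted by
#' descending peak score. The default threshold is the frame mean plus
#' 3 standard deviations of the response.
#'
#' @param filtered a filtered frame from [spot_enhancing_filter].
#' @param threshold response threshold (A.U.); default `mean + 3 * sd`.
#' @param min_size_px minimum region size in pixels (2 for small particles,
#'   4 for inclusion bodies).
#' @param frame 0-based frame index recorded in the output.
#' @param raw optional raw frame for the `raw_intensity` column.
#' @return a data frame of candidates with columns `frame`, `x`, `y`
#'   (0-based pixel coordinates of the weighted centroid), `score` (peak
#'   response), `raw_intensity` and `size_px`; empty when nothing is found.
#' @export
detect_candidates <- function(filtered, threshold = NULL, min_size_px = 2,
                              frame = 0, raw = NULL) {
  stopifnot(is.matrix(filtered))
  if (min_size_px < 1) stop("min_size_px must be >= 1", call. = FALSE)
  if (is.null(threshold))
    threshold <- mean(filtered) + 3 * stats::sd(filtered)
  mask <- filtered > threshold
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      score = numeric(0), raw_intensity = numeric(0),
                      size_px = integer(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  n <- max(lab)
  rows <- vector("list", n)
  keep <- 0L
  for (id in seq_len(n)) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_size_px) next
    w <- filtered[px]
    w <- w - min(0, min(w))            # guard against negative weights
    if (sum(w) <= 0) w <- rep(1, length(w))
    cx <- sum((px[, 2] - 0.5) * w) / sum(w)
    cy <- sum((px[, 1] - 0.5) * w) / sum(w)
    keep <- keep + 1L
    rows[[keep]] <- data.frame(
      frame = frame, x = cx, y = cy,
      score = max(filtered[px]),
      raw_intensity = if (is.null(raw)) NA_real_ else max(raw[px]),
      size_px = nrow(px))
  }
  if (keep == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(keep)])
  out[order(-out$score), , drop = FALSE]
}

#' Detect candidates across a movie
#'
#' Applies [spot_enhancing_filter] and [detect_candidates] to every frame of
#' a time-lapse stack.
#'
#' @param stack an [image_stack] (single z, single channel).
#' @param sigma LoG scale, pixels.
#' @param min_size_px minimum region size in pixels.
#' @param threshold response threshold; `NULL` for the per-frame default.
#' @param presmooth_sigma optional Gaussian pre-smooth, pixels.
#' @return a data frame of candidates over all frames (0-based `frame`).
#' @export
detect_movie <- function(stack, sigma, min_size_px = 2, threshold = NULL,
                         presmooth_sigma = 0) {
  stopifnot(inherits(stack, "image_stack"))
  n_t <- dim(stack)[1]
  out <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    fr <- stack_frame(stack, t = t)
    f <- spot_enhancing_filter(fr, sigma, presmooth_sigma)
    out[[t]] <- detect_candidates(f, threshold = threshold,
                                  min_size_px = min_size_px,
                                  frame = t - 1L, raw = fr)
  }
  do.call(rbind, out)
}

# 8-connected component labelling: EBImage::bwlabel (4-connected) followed by
# a union-find merge of diagonally adjacent components.
label_components <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union(a[i], b[i])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union(a[i], b[i])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
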