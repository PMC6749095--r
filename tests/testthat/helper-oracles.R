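# Independent oracles and fixture builders shared across the suite.

# Direct O(N^2 k^2) spatial convolution with reflective padding: the
# brute-force oracle for the FFT-based filter path.
conv2_brute <- function(image, kernel) {
  r <- (nrow(kernel) - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  p <- image[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    patch <- p[i:(i + 2 * r), j:(j + 2 * r)]
    out[i, j] <- sum(patch * kernel[(2 * r + 1):1, (2 * r + 1):1])
  }
  out
}

# Exhaustive path enumeration oracle for the DP tracker: scores every
# feasible path through the candidate lists with the documented objective
# and returns the maximum score.
enumerate_best_path <- function(candidates, params, field_px = NULL) {
  frames <- sort(unique(candidates$frame))
  rng <- range(candidates$score)
  r_all <- if (diff(rng) > 0) (candidates$score - rng[1]) / diff(rng)
           else rep(1, nrow(candidates))
  cand <- split(data.frame(x = candidates$x, y = candidates$y, r = r_all),
                factor(candidates$frame, levels = frames))
  center <- if (!is.null(field_px)) c(field_px[2], field_px[1]) / 2 else c(0, 0)
  field_radius <- if (!is.null(field_px)) sqrt(sum((field_px / 2)^2)) else 1
  eps <- 1e-9
  idx <- expand.grid(lapply(cand, function(d) seq_len(nrow(d))))
  best <- -Inf
  for (row in seq_len(nrow(idx))) {
    sc <- 0
    feasible <- TRUE
    prev <- NULL
    for (k in seq_along(frames)) {
      d <- cand[[k]]
      j <- idx[row, k]
      g <- params$w_intensity * d$r[j]
      if (params$w_center > 0) {
        dist_c <- sqrt((d$x[j] - center[1])^2 + (d$y[j] - center[2])^2)
        g <- g - params$w_center * dist_c / field_radius
      }
      if (!is.null(prev)) {
        step <- sqrt((d$x[j] - prev$x)^2 + (d$y[j] - prev$y)^2)
        if (step > params$max_displacement) { feasible <- FALSE; break }
        g <- g + params$w_intensity_variation *
          (1 - abs(d$r[j] - prev$r) / max(prev$r, eps)) -
          params$w_movement * step / params$max_displacement
      }
      sc <- sc + g
      prev <- list(x = d$x[j], y = d$y[j], r = d$r[j])
    }
    if (feasible && sc > best) best <- sc
  }
  best
}

# random tracking fixture: n_frames frames with up to max_cand candidates
random_candidates <- function(n_frames, max_cand, seed, spread = 8) {
  set.seed(seed)
  rows <- lapply(seq_len(n_frames) - 1L, function(fr) {
    n <- sample.int(max_cand, 1)
    data.frame(frame = fr,
               x = runif(n, 0, spread), y = runif(n, 0, spread),
               score = runif(n, 1, 10))
  })
  do.call(rbind, rows)
}

# digital disc mask of radius r px centered in an n x n field
disc_mask <- function(r, n = 2 * ceiling(r) + 9) {
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

# Closed-form solution of the red two-pool system (no divisions):
#   c' = -(k_in + k_deg) c + k_out b ;  b' = k_in c - k_out b
# via eigen decomposition -- the independent oracle for the fixed-step
# integrator and the turnover summary.
red_pools_closed_form <- function(k_in, k_out, k_deg, c0, b0, times) {
  A <- matrix(c(-(k_in + k_deg), k_in, k_out, -k_out), 2, 2)
  ev <- eigen(A)
  coef <- solve(ev$vectors, c(c0, b0))
  t(vapply(times, function(t)
    Re(ev$vectors %*% (coef * exp(ev$values * t))), numeric(2)))
}
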