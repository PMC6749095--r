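#' Motion model for simulated particles
#'
#' Describes how a particle moves in the cytoplasm. Four kinds are supported:
#' `"brownian"` (free diffusion), `"directed"` (diffusion plus a persistent
#' drift whose direction resamples at random), `"ballistic"` (pure drift,
#' fixed direction) and `"stationary"`.
#'
#' The directed kind is a minimal model spanning anomalous-diffusion exponents
#' between 1 (free diffusion) and 2 (ballistic): over lag times shorter than
#' `drift_persistence` the drift contributes a quadratic term to the MSD, so
#' the fitted log-log slope rises above 1 without reaching 2.
#'
#' @param kind one of `"brownian"`, `"directed"`, `"ballistic"`,
#'   `"stationary"`.
#' @param diffusion_coefficient diffusion coefficient D in um^2/s.
#' @param drift_speed drift magnitude in um/s (directed/ballistic kinds).
#' @param drift_persistence mean waiting time, in seconds, between random
#'   re-orientations of the drift direction (directed kind).
#' @return an object of class `motion_model`.
#' @examples
#' motion_model("brownian", diffusion_coefficient = 0.059)
#' motion_model("directed", 0.059, drift_speed = 0.08, drift_persistence = 0.5)
#' @export
motion_model <- function(kind = c("brownian", "directed", "ballistic", "stationary"),
                         diffusion_coefficient = 0,
                         drift_speed = 0,
                         drift_persistence = Inf) {
  kind <- match.arg(kind)
  if (!is.numeric(diffusion_coefficient) || diffusion_coefficient < 0)
    stop("diffusion_coefficient must be >= 0", call. = FALSE)
  if (!is.numeric(drift_speed) || drift_speed < 0)
    stop("drift_speed must be >= 0", call. = FALSE)
  if (kind == "brownian" && drift_speed != 0)
    stop("brownian motion has no drift; use kind = \"directed\"", call. = FALSE)
  if (kind == "stationary" && (diffusion_coefficient != 0 || drift_speed != 0))
    stop("stationary motion requires D = 0 and drift_speed = 0", call. = FALSE)
  if (kind %in% c("directed", "ballistic") && drift_speed == 0)
    stop(kind, " motion requires drift_speed > 0", call. = FALSE)
  structure(
    list(kind = kind,
         diffusion_coefficient = diffusion_coefficient,
         drift_speed = drift_speed,
         drift_persistence = drift_persistence),
    class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> %s: D = %g um^2/s, v = %g um/s, persistence = %g s\n",
              x$kind, x$diffusion_coefficient, x$drift_speed, x$drift_persistence))
  invisible(x)
}

#' Acquisition configuration
#'
#' Physical calibration and camera model for rendered synthetic microscopy.
#' The noise model is Poisson shot noise on the signal followed by additive
#' Gaussian read noise, the standard camera model. Per-exposure photobleaching
#' is geometric: the rendered amplitude of frame `t` (0-based) is multiplied
#' by `bleach_retention^t` for each channel.
#'
#' @param frame_interval time between frames, seconds.
#' @param pixel_size lateral pixel size, um.
#' @param z_spacing axial plane spacing, um.
#' @param exposure exposure time per frame, seconds (metadata only).
#' @param psf_sigma Gaussian point-spread-function sigma, um.
#' @param background_level camera background offset, A.U.
#' @param shot_noise logical; apply Poisson noise to the signal.
#' @param read_noise_sd Gaussian read-noise standard deviation, A.U.
#' @param bleach_retention fraction of intensity retained per exposure,
#'   one value per channel (recycled).
#' @param field_px image size as `c(ny, nx)` pixels.
#' @param channels character vector of channel names.
#' @return an object of class `acquisition_config`.
#' @examples
#' acquisition_config(frame_interval = 1/32)
#' @export
acquisition_config <- function(frame_interval = 1 / 32,
                               pixel_size = 0.1,
                               z_spacing = 0.2,
                               exposure = frame_interval,
                               psf_sigma = 0.12,
                               background_level = 100,
                               shot_noise = FALSE,
                               read_noise_sd = 0,
                               bleach_retention = 1,
                               field_px = c(64, 64),
                               channels = "ch1") {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (z_spacing <= 0) stop("z_spacing must be > 0", call. = FALSE)
  if (any(bleach_retention <= 0) || any(bleach_retention > 1))
    stop("bleach_retention must be in (0, 1]", call. = FALSE)
  structure(
    list(frame_interval = frame_interval, pixel_size = pixel_size,
         z_spacing = z_spacing, exposure = exposure, psf_sigma = psf_sigma,
         background_level = background_level, shot_noise = shot_noise,
         read_noise_sd = read_noise_sd,
         bleach_retention = rep_len(bleach_retention, length(channels)),
         field_px = as.integer(field_px), channels = channels),
    class = "acquisition_config")
}

#' Two-pool photoconversion pulse-chase model
#'
#' Kinetic parameters for the two-pool (cytoplasm, inclusion body) two-colour
#' model used in photoconversion pulse-chase experiments. At time zero a
#' fraction of the green pool is converted irreversibly to red; red protein is
#' never synthesised afterwards. Protein is incorporated into the IB at rate
#' `k_in` (per minute, acting on the cytoplasmic amount), released back at
#' `k_out` (acting on the IB amount) and degraded in the cytoplasm at `k_deg`.
#' Green protein is additionally synthesised at `synthesis_rate`. At each
#' division time the cytoplasmic pool of the mother is divided by
#' `1 + daughter_fraction`; the IB stays with the mother.
#'
#' @param k_in cytoplasm-to-IB incorporation rate, 1/min.
#' @param k_out IB-to-cytoplasm release rate, 1/min.
#' @param k_deg cytoplasmic degradation rate, 1/min.
#' @param synthesis_rate green synthesis rate, A.U./min.
#' @param conversion_fraction fraction of green converted to red at t = 0.
#' @param division_times cell-division times, minutes (may be empty).
#' @param daughter_fraction relative daughter size at division (0, 1).
#' @param init_cyto initial cytoplasmic green amount, A.U.
#' @param init_ib initial IB green amount, A.U.
#' @return an object of class `pulse_chase_model`.
#' @examples
#' pulse_chase_model(k_in = 0.025, k_out = 0.010, k_deg = 0.005)
#' @export
pulse_chase_model <- function(k_in = 0.025, k_out = 0.010, k_deg = 0.005,
                              synthesis_rate = 1,
                              conversion_fraction = 0.5,
                              division_times = c(100, 220),
                              daughter_fraction = 0.7,
                              init_cyto = 100, init_ib = 100) {
  rates <- c(k_in = k_in, k_out = k_out, k_deg = k_deg,
             synthesis_rate = synthesis_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (conversion_fraction < 0 || conversion_fraction > 1)
    stop("conversion_fraction must be in [0, 1]", call. = FALSE)
  if (daughter_fraction <= 0 || daughter_fraction >= 1)
    stop("daughter_fraction must be in (0, 1)", call. = FALSE)
  structure(
    list(k_in = k_in, k_out = k_out, k_deg = k_deg,
         synthesis_rate = synthesis_rate,
         conversion_fraction = conversion_fraction,
         division_times = sort(division_times),
         daughter_fraction = daughter_fraction,
         init_cyto = init_cyto, init_ib = init_ib),
    class = "pulse_chase_model")
}

#' @export
print.pulse_chase_model <- function(x, ...) {
  cat(sprintf(
    "<pulse_chase_model> k_in = %g, k_out = %g, k_deg = %g /min; synthesis = %g A.U./min\n",
    x$k_in, x$k_out, x$k_deg, x$synthesis_rate))
  cat(sprintf("  conversion %.0f%%, divisions at [%s] min, daughter %.0f%%\n",
              100 * x$conversion_fraction,
              paste(x$division_times, collapse = ", "),
              100 * x$daughter_fraction))
  invisible(x)
}

#' Particle-tracking parameters
#'
#' Weights and displacement bound for the dynamic-programming tracker. The
#' defaults are the published tracking settings for mutant-huntingtin
#' particles: maximum displacement 10 px, intensity weight 80%, intensity
#' variation 20%, movement constraint 40% and center constraint 0%.
#'
#' @param max_displacement maximum per-frame displacement, pixels.
#' @param w_intensity weight on the (min-max normalised) filter response.
#' @param w_intensity_variation weight on response stability between frames.
#' @param w_movement penalty weight on step length / `max_displacement`.
#' @param w_center penalty weight on distance from the field center.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(max_displacement = 10,
                            w_intensity = 0.80,
                            w_intensity_variation = 0.20,
                            w_movement = 0.40,
                            w_center = 0.00) {
  if (max_displacement <= 0) stop("max_displacement must be > 0", call. = FALSE)
  w <- c(w_intensity, w_intensity_variation, w_movement, w_center)
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  structure(
    list(max_displacement = max_displacement,
         w_intensity = w_intensity,
         w_intensity_variation = w_intensity_variation,
         w_movement = w_movement,
         w_center = w_center),
    class = "tracking_params")
}

# run stochastic code under a local seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), code)
}
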