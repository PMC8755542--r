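#' Simulation configuration for synthetic kymographs
#'
#' Bundles the acquisition parameters of a confocal line-scanning experiment
#' on a tethered DNA molecule: spatial calibration (nm per pixel), temporal
#' calibration (seconds per scanned line), field size, point-spread-function
#' width, background level and the photon noise model. Defaults follow the
#' acquisition settings typical of C-TRAP kymographs (100 nm per pixel,
#' 0.997 s line time).
#'
#' @param seed Integer seed; identical seed and config give bit-identical
#'   simulated output.
#' @param pixel_size Spatial calibration, nm per pixel. Must be positive.
#' @param line_time Temporal calibration, seconds per frame (scan line).
#' @param n_frames Number of frames (time points).
#' @param n_pixels Number of spatial pixels along the DNA axis.
#' @param psf_sigma Gaussian point-spread-function standard deviation, in
#'   pixels.
#' @param background Mean background level, counts per pixel.
#' @param noise_model One of `"poisson"` (shot noise on photon counts),
#'   `"gaussian"` (additive read noise of standard deviation `noise_sigma`),
#'   `"poisson+gaussian"` (both, emulating an EM-CCD), or `"none"`.
#' @param noise_sigma Read-noise standard deviation in counts, used by the
#'   Gaussian noise models.
#' @param bleach_rate Photobleaching rate in 1/s; each particle's emission is
#'   truncated after an exponentially distributed survival time. Default 0
#'   (off).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_frames = 100, n_pixels = 64)
#' cfg$pixel_size
#' @export
sim_config <- function(seed = NULL,
                       pixel_size = 100,
                       line_time = 0.997,
                       n_frames = 300,
                       n_pixels = 128,
                       psf_sigma = 1.5,
                       background = 10,
                       noise_model = c("poisson", "gaussian", "poisson+gaussian", "none"),
                       noise_sigma = 2,
                       bleach_rate = 0) {
  noise_model <- match.arg(noise_model)
  check_positive(pixel_size, "pixel_size")
  check_positive(line_time, "line_time")
  check_positive(n_frames, "n_frames")
  check_positive(n_pixels, "n_pixels")
  check_positive(psf_sigma, "psf_sigma")
  check_nonneg(background, "background")
  check_nonneg(noise_sigma, "noise_sigma")
  check_nonneg(bleach_rate, "bleach_rate")
  structure(list(
    seed = seed,
    pixel_size = pixel_size,
    line_time = line_time,
    n_frames = as.integer(n_frames),
    n_pixels = as.integer(n_pixels),
    psf_sigma = psf_sigma,
    background = background,
    noise_model = noise_model,
    noise_sigma = noise_sigma,
    bleach_rate = bleach_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field: %d px x %d frames (%.0f nm/px, %.3f s/line)\n",
              x$n_pixels, x$n_frames, x$pixel_size, x$line_time))
  cat(sprintf("  psf sigma %.2f px, background %.1f counts, noise %s\n",
              x$psf_sigma, x$background, x$noise_model))
  invisible(x)
}

#' Particle motion specifications for kymograph simulation
#'
#' Describe a fluorescent particle on the 1D DNA axis. Three motion types are
#' supported: `particle_static()` stays put, `particle_diffusive()` performs
#' 1D Brownian motion with diffusion coefficient `D` (Gaussian increments of
#' variance `2 * D * dt`, reflecting at the DNA ends), and
#' `particle_directed()` translocates unidirectionally at constant velocity
#' `v` and leaves the field of view when it passes an end.
#'
#' @param x0 Start position along the DNA, nm.
#' @param amplitude Peak emission above background, counts.
#' @param start_frame,end_frame First and last frame (1-based, inclusive) in
#'   which the particle is present; `end_frame = Inf` means until the end of
#'   the recording.
#' @param D Diffusion coefficient, nm^2/s.
#' @param v Translocation velocity, nm/s (signed).
#' @return A list of class `particle_spec`.
#' @examples
#' particle_directed(x0 = 1000, v = 14)
#' @name particle_spec
NULL

particle_spec <- function(type, x0, amplitude, start_frame, end_frame, D = NA, v = NA) {
  check_nonneg(x0, "x0")
  check_positive(amplitude, "amplitude")
  structure(list(type = type, x0 = x0, amplitude = amplitude,
                 start_frame = start_frame, end_frame = end_frame,
                 D = D, v = v),
            class = "particle_spec")
}

#' @rdname particle_spec
#' @export
particle_static <- function(x0, amplitude = 200, start_frame = 1, end_frame = Inf) {
  particle_spec("static", x0, amplitude, start_frame, end_frame)
}

#' @rdname particle_spec
#' @export
particle_diffusive <- function(x0, D, amplitude = 200, start_frame = 1, end_frame = Inf) {
  check_nonneg(D, "D")
  particle_spec("diffusive", x0, amplitude, start_frame, end_frame, D = D)
}

#' @rdname particle_spec
#' @export
particle_directed <- function(x0, v, amplitude = 200, start_frame = 1, end_frame = Inf) {
  if (!is.numeric(v) || !is.finite(v)) stop_config("invalid config: 'v' must be finite")
  particle_spec("directed", x0, amplitude, start_frame, end_frame, v = v)
}
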