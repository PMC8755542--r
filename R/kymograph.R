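#' Kymograph container
#'
#' A kymograph is a 2D record of fluorescence intensity along a 1D DNA axis
#' (rows, spatial pixels) versus time (columns, scan lines). The container
#' couples the intensity matrix with its spatial and temporal calibration.
#'
#' Pixel coordinates are 0-based: row `j` of the matrix covers pixel index
#' `j - 1`, whose centre lies at `(j - 1) * pixel_size` nm. Frame `f`
#' (1-based column) was acquired at time `(f - 1) * line_time` s.
#'
#' @param intensity Numeric matrix `[spatial pixel, frame]`, finite and
#'   non-negative.
#' @param pixel_size nm per pixel (> 0).
#' @param line_time Seconds per frame (> 0).
#' @param channel Optional channel label.
#' @return An object of class `kymograph`.
#' @examples
#' k <- kymograph(matrix(0, 32, 10), pixel_size = 100, line_time = 0.997)
#' dim(k$intensity)
#' @export
kymograph <- function(intensity, pixel_size = 100, line_time = 0.997,
                      channel = "ch1") {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop_config("invalid config: 'intensity' must be a numeric matrix")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_config("invalid config: intensity must be finite and non-negative")
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(line_time, "line_time")
  structure(list(intensity = intensity,
                 pixel_size = pixel_size,
                 line_time = line_time,
                 channel = channel),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d frames (%.0f nm/px, %.3f s/line), channel %s\n",
              nrow(x$intensity), ncol(x$intensity),
              x$pixel_size, x$line_time, x$channel))
  invisible(x)
}

#' Simulate a kymograph with known ground truth
#'
#' Renders fluorescent particles moving on a 1D DNA axis into a synthetic
#' kymograph. Each particle contributes a Gaussian line profile
#' `amplitude * exp(-(p - x(t))^2 / (2 * psf_sigma^2))` on top of a constant
#' background; the configured noise model is then applied. Diffusive
#' particles take Gaussian steps of variance `2 * D * line_time` and reflect
#' at the DNA ends (tethered-molecule geometry); directed particles move at
#' constant velocity and stop contributing once they leave the field.
#' Optional photobleaching truncates each particle's emission after an
#' exponential survival time.
#'
#' @param config A [sim_config()].
#' @param particles List of particle specs ([particle_static()],
#'   [particle_diffusive()], [particle_directed()]).
#' @return A list with elements `kymograph` (a [kymograph()]) and `truth`,
#'   where `truth$particles` is a data frame (one row per particle: type,
#'   parameters, start/end frame) and `truth$paths` is a list of per-frame
#'   true positions in nm (`NA` where the particle is absent).
#' @examples
#' cfg <- sim_config(seed = 1, n_frames = 50, n_pixels = 64,
#'                   noise_model = "none")
#' sim <- simulate_kymograph(cfg, list(particle_static(x0 = 1200)))
#' which.max(sim$kymograph$intensity[, 1]) # row 13 = pixel index 12
#' @export
simulate_kymograph <- function(config, particles) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(particles)) stop_config("invalid config: no particles given")
  L <- config$n_pixels * config$pixel_size   # field length, nm
  for (p in particles) {
    if (p$x0 < 0 || p$x0 >= L) {
      stop_config("invalid config: particle start position %.1f nm outside [0, %.1f)",
                  p$x0, L)
    }
  }
  with_seed(config$seed, {
    nf <- config$n_frames
    np <- config$n_pixels
    dt <- config$line_time
    px <- config$pixel_size
    pixel_centers <- (seq_len(np) - 1) * px   # nm

    paths <- vector("list", length(particles))
    clean <- matrix(config$background, nrow = np, ncol = nf)
    truth_rows <- vector("list", length(particles))

    for (i in seq_along(particles)) {
      p <- particles[[i]]
      f0 <- max(1L, as.integer(p$start_frame))
      f1 <- min(nf, as.integer(min(p$end_frame, nf)))
      pos <- rep(NA_real_, nf)
      if (f1 >= f0) {
        nlive <- f1 - f0 + 1L
        x <- switch(p$type,
          static = rep(p$x0, nlive),
          directed = p$x0 + p$v * dt * (seq_len(nlive) - 1),
          diffusive = {
            steps <- stats::rnorm(nlive - 1L, mean = 0,
                                  sd = sqrt(2 * p$D * dt))
            xx <- p$x0 + c(0, cumsum(steps))
            # reflect at DNA ends [0, L)
            period <- 2 * L
            xx <- xx %% period
            ifelse(xx > L, period - xx, xx)
          },
          stop_config("unknown particle type '%s'", p$type))
        if (config$bleach_rate > 0) {
          surv <- stats::rexp(1L, rate = config$bleach_rate)
          nkeep <- min(nlive, max(1L, ceiling(surv / dt)))
          x <- x[seq_len(nkeep)]
          f1 <- f0 + nkeep - 1L
        }
        pos[f0:f1] <- x
        # particles outside the field contribute nothing
        vis <- which(x >= 0 & x < L)
        for (k in vis) {
          f <- f0 + k - 1L
          clean[, f] <- clean[, f] +
            p$amplitude * exp(-(pixel_centers - x[k])^2 /
                                (2 * (config$psf_sigma * px)^2))
        }
      }
      paths[[i]] <- pos
      truth_rows[[i]] <- data.frame(
        particle = i, type = p$type, x0_nm = p$x0,
        D_nm2_s = p$D, v_nm_s = p$v,
        amplitude = p$amplitude, start_frame = f0, end_frame = f1)
    }

    intensity <- switch(config$noise_model,
      none = clean,
      poisson = matrix(stats::rpois(length(clean), lambda = clean),
                       nrow = np),
      gaussian = pmax(0, clean + stats::rnorm(length(clean),
                                              sd = config$noise_sigma)),
      `poisson+gaussian` = pmax(0,
        stats::rpois(length(clean), lambda = clean) +
          stats::rnorm(length(clean), sd = config$noise_sigma)) |>
        matrix(nrow = np))
    if (!is.matrix(intensity)) intensity <- matrix(intensity, nrow = np)

    list(
      kymograph = kymograph(intensity, pixel_size = px, line_time = dt),
      truth = list(particles = do.call(rbind, truth_rows), paths = paths)
    )
  })
}
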