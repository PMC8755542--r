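#' Mean squared displacement of a trajectory
#'
#' Computes, for each lag `n = 1 .. N-1`,
#' `MSD(n, N) = sum_{i=1}^{N-n} (X_{i+n} - X_i)^2 / (N - n)`,
#' where `X_i` is the particle position along the DNA at frame `i` and `N`
#' the number of frames. Requires uniform temporal sampling.
#'
#' @param traj A trajectory: anything with `time_s` and `position_nm`
#'   columns (see [as_trajectory()]), or a numeric position vector together
#'   with `dt`.
#' @param dt Sampling interval, s; required when `traj` is a bare numeric
#'   vector.
#' @return Data frame of class `msd_curve` with columns `lag`,
#'   `lag_time_s`, `msd_nm2`; attributes `N` and `dt`.
#' @examples
#' m <- compute_msd(c(0, 1, 2, 3), dt = 1)
#' m$msd_nm2   # 1 4 9
#' @export
compute_msd <- function(traj, dt = NULL) {
  if (is.numeric(traj) && is.null(dim(traj))) {
    x <- traj
    if (is.null(dt)) stop("dt required for a bare position vector", call. = FALSE)
  } else {
    x <- traj$position_nm
    dt <- check_uniform_dt(traj$time_s)
  }
  N <- length(x)
  if (N < 2L) stop("trajectory must have at least 2 frames", call. = FALSE)
  msd <- vapply(seq_len(N - 1L), function(n) {
    d <- x[(1L + n):N] - x[1:(N - n)]
    sum(d^2) / (N - n)
  }, numeric(1))
  structure(data.frame(lag = seq_len(N - 1L),
                       lag_time_s = seq_len(N - 1L) * dt,
                       msd_nm2 = msd),
            class = c("msd_curve", "data.frame"), N = N, dt = dt)
}

#' Fit a power law to an MSD curve
#'
#' Fits `MSD = D * dt^alpha` over lags `1 .. ceiling(lag_fraction * N)` by
#' linear least squares on the log-log transformed curve. The exponent
#' `alpha` discriminates free or constrained diffusion (`alpha <= 1`) from
#' superdiffusive, directed motion (`alpha > 1`).
#'
#' @param msd An [compute_msd()] result.
#' @param lag_fraction Fraction of `N` setting the largest fitted lag
#'   (default 0.25). At least 4 lags are required.
#' @return List of class `motion_fit`: `D` (nm^2/s^alpha), `alpha`,
#'   `label`, `lag_range`, `static` (TRUE when the MSD is identically zero
#'   and the exponent is undefined).
#' @export
fit_msd <- function(msd, lag_fraction = 0.25) {
  stopifnot(inherits(msd, "msd_curve"))
  N <- attr(msd, "N")
  n_fit <- min(nrow(msd), max(4L, ceiling(lag_fraction * N)))
  if (n_fit < 4L) stop("need at least 4 lags in the fit range", call. = FALSE)
  sub <- msd[seq_len(n_fit), ]
  if (all(sub$msd_nm2 == 0)) {
    return(structure(list(D = 0, alpha = NA_real_, label = "static",
                          lag_range = c(1L, n_fit), static = TRUE),
                     class = "motion_fit"))
  }
  pos <- sub$msd_nm2 > 0
  fit <- stats::lm(log(msd_nm2) ~ log(lag_time_s), data = sub[pos, ])
  alpha <- unname(stats::coef(fit)[2])
  D <- exp(unname(stats::coef(fit)[1]))
  structure(list(D = D, alpha = alpha, label = classify_motion(alpha),
                 lag_range = c(1L, n_fit), static = FALSE),
            class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  if (x$static) {
    cat("<motion_fit> static (MSD identically zero)\n")
  } else {
    cat(sprintf("<motion_fit> alpha = %.3f, D = %.4g nm^2/s^alpha -> %s\n",
                x$alpha, x$D, x$label))
  }
  invisible(x)
}

#' Classify motion from the MSD power-law exponent
#'
#' A particle whose MSD scales with exponent `alpha <= 1` exhibits free or
#' constrained diffusion; `alpha > 1` indicates superdiffusive (directed)
#' motion such as a unidirectional walk.
#'
#' @param alpha Power-law exponent (finite), or a `motion_fit`.
#' @return `"diffusive"` or `"superdiffusive"`.
#' @examples
#' classify_motion(1.5)   # superdiffusive
#' classify_motion(1.0)   # diffusive (boundary)
#' @export
classify_motion <- function(alpha) {
  if (inherits(alpha, "motion_fit")) alpha <- alpha$alpha
  if (!is.numeric(alpha) || !is.finite(alpha)) {
    stop("alpha must be finite", call. = FALSE)
  }
  if (alpha > 1) "superdiffusive" else "diffusive"
}

#' Average translocation velocity of a trajectory
#'
#' The trajectory is first smoothed with a Savitzky-Golay filter (default
#' window 51 frames, polynomial order 3) to suppress tracking inaccuracy
#' and thermal fluctuation; the total route of the molecule -- the sum of
#' absolute smoothed frame-to-frame displacements -- is then divided by the
#' total trajectory time.
#'
#' @param traj Trajectory (see [compute_msd()] for accepted forms).
#' @param dt Sampling interval, s, for bare numeric input.
#' @param window Savitzky-Golay window, odd number of frames (default 51);
#'   clipped to the largest valid odd value on short trajectories.
#' @param polyorder Savitzky-Golay polynomial order (default 3).
#' @return Velocity, nm/s.
#' @examples
#' estimate_velocity(10 * (0:100), dt = 1)   # 10 nm/s
#' @export
estimate_velocity <- function(traj, dt = NULL, window = 51, polyorder = 3) {
  if (is.numeric(traj) && is.null(dim(traj))) {
    x <- traj
    if (is.null(dt)) stop("dt required for a bare position vector", call. = FALSE)
  } else {
    x <- traj$position_nm
    dt <- check_uniform_dt(traj$time_s)
  }
  N <- length(x)
  if (N < 5L) stop("trajectory too short (need >= 5 frames)", call. = FALSE)
  w <- min(window, if (N %% 2L == 1L) N else N - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  w <- max(w, polyorder + 2L + (polyorder %% 2L))  # smallest odd window > polyorder
  sm <- signal::sgolayfilt(x, p = polyorder, n = w)
  sum(abs(diff(sm))) / ((N - 1L) * dt)
}

#' Extract unwinding stroke rates from a bead-distance trace
#'
#' Computes the smoothed first derivative of the bead-centre distance trace
#' (Savitzky-Golay differentiation), segments it into contiguous runs of
#' movement (derivative above `pause_threshold`) and pause (below), and
#' reports a rate per segment. The segment rate is the median of the
#' smoothed derivative within the run, which sits on the rate plateau and
#' is insensitive to the smoothing-blurred transition ramps at the run
#' boundaries. A Gaussian mixture with 1 or 2 components (selected by BIC)
#' is fitted to the segment-rate distribution.
#'
#' @param trace Data frame with columns `time_s` and `distance_nm`
#'   (uniformly sampled), e.g. from [simulate_distance_trace()].
#' @param smooth_window Savitzky-Golay window, odd samples (default 21).
#' @param polyorder Savitzky-Golay polynomial order (default 3).
#' @param pause_threshold Rate below which a sample counts as paused, nm/s
#'   (default 0.5).
#' @param min_segment Minimum run length in samples; shorter runs are
#'   absorbed into the preceding segment (default 5).
#' @return List of class `stroke_fit`: `segments` (data frame `type`,
#'   `start_s`, `end_s`, `rate_nm_s`), `burst_rates`, `mean_burst_rate`,
#'   `mixture` (list: `G`, `means`, `sds`, `weights`, `bic`) or `NULL` when
#'   fewer than 3 segment rates are available.
#' @export
extract_stroke_rates <- function(trace, smooth_window = 21, polyorder = 3,
                                 pause_threshold = 0.5, min_segment = 5) {
  dt <- check_uniform_dt(trace$time_s)
  d <- trace$distance_nm
  if (length(d) < smooth_window) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  v <- signal::sgolayfilt(d, p = polyorder, n = smooth_window, m = 1, ts = dt)
  moving <- v > pause_threshold
  r <- rle(moving)
  # absorb runs shorter than min_segment into the previous run
  if (length(r$lengths) > 1L) {
    repeat {
      short <- which(r$lengths < min_segment)
      short <- short[short > 1L]
      if (!length(short)) break
      j <- short[1]
      r$values[j] <- r$values[j - 1L]
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segments <- data.frame(
    type = ifelse(r$values, "burst", "pause"),
    start_s = trace$time_s[starts],
    end_s = trace$time_s[ends],
    rate_nm_s = vapply(seq_along(starts), function(i) {
      stats::median(v[starts[i]:ends[i]])
    }, numeric(1))
  )
  burst_rates <- segments$rate_nm_s[segments$type == "burst"]
  rates <- segments$rate_nm_s
  mixture <- NULL
  if (length(rates) >= 3L) {
    mc <- tryCatch(mclust_fit(rates, G = 1:2), error = function(e) NULL)
    if (!is.null(mc)) {
      mixture <- list(G = mc$G,
                      means = unname(mc$parameters$mean),
                      sds = sqrt(unname(if (mc$parameters$variance$modelName %in% c("E", "X")) {
                        rep(mc$parameters$variance$sigmasq, mc$G)
                      } else mc$parameters$variance$sigmasq)),
                      weights = unname(mc$parameters$pro),
                      bic = unname(mc$bic))
    }
  } else if (length(rates) >= 1L) {
    mixture <- list(G = 1L, means = mean(rates),
                    sds = if (length(rates) > 1) stats::sd(rates) else 0,
                    weights = 1, bic = NA_real_)
  }
  structure(list(segments = segments,
                 burst_rates = burst_rates,
                 mean_burst_rate = if (length(burst_rates)) mean(burst_rates) else NA_real_,
                 mixture = mixture),
            class = "stroke_fit")
}

#' @export
print.stroke_fit <- function(x, ...) {
  cat(sprintf("<stroke_fit> %d segments (%d bursts), mean burst rate %.2f nm/s\n",
              nrow(x$segments), length(x$burst_rates), x$mean_burst_rate))
  if (!is.null(x$mixture)) {
    cat(sprintf("  mixture: %d component(s), means %s\n", x$mixture$G,
                paste(sprintf("%.2f", x$mixture$means), collapse = ", ")))
  }
  invisible(x)
}
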