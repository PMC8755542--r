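#' Simulate a burst-pause DNA unwinding trace
#'
#' Emulates the bead-centre distance recorded while a helicase unwinds DNA
#' held at constant force: rapid unwinding bursts (distance increases
#' linearly at a per-burst rate drawn from a Gaussian) interspersed by pauses
#' (rate 0), plus additive Gaussian measurement noise. The mean path is
#' piecewise linear and monotone non-decreasing; the drawn per-burst rates
#' are stored as ground truth.
#'
#' @param burst_rate_mean Mean unwinding rate during bursts, nm/s.
#' @param burst_rate_rel_sd Relative standard deviation of per-burst rates
#'   (fraction of the mean); draws are truncated at zero.
#' @param burst_dur,pause_dur Burst and pause durations, s.
#' @param total_dur Total trace duration, s.
#' @param dt Sampling interval, s.
#' @param noise_sigma Additive Gaussian noise standard deviation, nm.
#' @param seed Integer seed.
#' @param start_phase `"burst"` or `"pause"` for the first segment.
#' @return List with `trace` (data frame `time_s`, `distance_nm`) and
#'   `truth` (data frame of segments: `type`, `start_s`, `end_s`,
#'   `rate_nm_s`).
#' @examples
#' sim <- simulate_distance_trace(burst_rate_mean = 3.3, burst_rate_rel_sd = 0.2,
#'                                burst_dur = 60, pause_dur = 30,
#'                                total_dur = 300, dt = 1, noise_sigma = 2,
#'                                seed = 1)
#' head(sim$truth)
#' @export
simulate_distance_trace <- function(burst_rate_mean,
                                    burst_rate_rel_sd = 0.2,
                                    burst_dur = 60,
                                    pause_dur = 30,
                                    total_dur = 450,
                                    dt = 1,
                                    noise_sigma = 2,
                                    seed = NULL,
                                    start_phase = c("burst", "pause")) {
  start_phase <- match.arg(start_phase)
  check_nonneg(burst_rate_mean, "burst_rate_mean")
  check_nonneg(burst_rate_rel_sd, "burst_rate_rel_sd")
  check_positive(burst_dur, "burst_dur")
  check_positive(pause_dur, "pause_dur")
  check_positive(total_dur, "total_dur")
  check_positive(dt, "dt")
  check_nonneg(noise_sigma, "noise_sigma")

  with_seed(seed, {
    # build alternating segments until total_dur is covered
    segs <- list()
    t0 <- 0
    phase <- start_phase
    while (t0 < total_dur) {
      dur <- if (phase == "burst") burst_dur else pause_dur
      dur <- min(dur, total_dur - t0)
      rate <- if (phase == "burst") {
        r <- stats::rnorm(1, burst_rate_mean, burst_rate_rel_sd * burst_rate_mean)
        while (r < 0) {
          r <- stats::rnorm(1, burst_rate_mean, burst_rate_rel_sd * burst_rate_mean)
        }
        r
      } else 0
      segs[[length(segs) + 1L]] <- data.frame(
        type = phase, start_s = t0, end_s = t0 + dur, rate_nm_s = rate)
      t0 <- t0 + dur
      phase <- if (phase == "burst") "pause" else "burst"
    }
    truth <- do.call(rbind, segs)

    time <- seq(0, total_dur, by = dt)
    # integrate the piecewise-constant rate
    mean_path <- numeric(length(time))
    for (i in seq_len(nrow(truth))) {
      s <- truth[i, ]
      overlap <- pmax(0, pmin(time, s$end_s) - s$start_s)
      mean_path <- mean_path + s$rate_nm_s * overlap
    }
    noise <- if (noise_sigma > 0) stats::rnorm(length(time), sd = noise_sigma) else 0
    list(
      trace = data.frame(time_s = time, distance_nm = mean_path + noise),
      truth = truth
    )
  })
}

#' Simulate an exponential fluorescence-loss trace
#'
#' Emulates the integrated fluorescence of a labelled protein being removed
#' from DNA over time: `I(t) = A * exp(-k * t) + C` plus Gaussian noise.
#' Times are in minutes, matching how stripping rates are conventionally
#' reported (k in 1/min).
#'
#' @param k Decay rate, 1/min (>= 0).
#' @param A Decay amplitude, counts.
#' @param C Baseline offset, counts.
#' @param total_dur Duration, min.
#' @param dt Sampling interval, min.
#' @param noise_sigma Additive Gaussian noise sd, counts.
#' @param seed Integer seed.
#' @return Data frame with columns `time_min`, `intensity`.
#' @examples
#' tr <- simulate_decay_trace(k = 0.136, A = 1000, C = 50, total_dur = 30,
#'                            dt = 0.5, noise_sigma = 0, seed = 1)
#' @export
simulate_decay_trace <- function(k, A = 1000, C = 0, total_dur = 30,
                                 dt = 0.25, noise_sigma = 0, seed = NULL) {
  check_nonneg(k, "k")
  check_positive(total_dur, "total_dur")
  check_positive(dt, "dt")
  check_nonneg(noise_sigma, "noise_sigma")
  with_seed(seed, {
    time <- seq(0, total_dur, by = dt)
    clean <- A * exp(-k * time) + C
    noise <- if (noise_sigma > 0) stats::rnorm(length(time), sd = noise_sigma) else 0
    data.frame(time_min = time, intensity = clean + noise)
  })
}

#' Simulate a two-state telegraph smFRET trace
#'
#' Emulates a single-molecule FRET recording of DNA alternating between a
#' protein-free state (high FRET) and a protein-bound state (low FRET). The
#' underlying state path is a two-state continuous-time Markov chain: the
#' free state ends at rate `k_bind` (protein binds), the bound state at rate
#' `k_release`. Holding times are therefore exponential with means
#' `1/k_bind` (t_on) and `1/k_release` (t_off). Donor and acceptor
#' intensities are rendered from the state's FRET efficiency as
#' `I_A = E * total` and `I_D = (1 - E) * total` plus Gaussian noise.
#'
#' @param E_low,E_high FRET efficiencies of the bound (low) and free (high)
#'   states; require `0 <= E_low < E_high <= 1`.
#' @param k_bind Rate of leaving the free state, 1/s.
#' @param k_release Rate of leaving the bound state, 1/s.
#' @param n_frames Number of camera frames.
#' @param exposure Frame exposure time, s (default 0.030).
#' @param noise_sigma Gaussian noise sd on each intensity channel, counts.
#' @param total_counts Total emission per frame, counts.
#' @param init_state `"free"`, `"bound"`, or `"stationary"` (drawn from the
#'   chain's stationary distribution).
#' @param seed Integer seed.
#' @return List with `trace` (data frame `frame`, `time_s`, `I_D`, `I_A`)
#'   and `truth` (list: `states` character vector per frame, `dwells` data
#'   frame of continuous holding times with `state`, `duration_s`,
#'   `censored`).
#' @examples
#' sim <- simulate_fret_trace(E_low = 0.2, E_high = 0.8, k_bind = 0.5,
#'                            k_release = 0.5, n_frames = 200, seed = 1)
#' table(sim$truth$states)
#' @export
simulate_fret_trace <- function(E_low, E_high, k_bind, k_release,
                                n_frames, exposure = 0.030,
                                noise_sigma = 0, total_counts = 1000,
                                init_state = c("stationary", "free", "bound"),
                                seed = NULL) {
  init_state <- match.arg(init_state)
  if (!is.numeric(E_low) || !is.numeric(E_high) ||
      E_low < 0 || E_high > 1 || E_low >= E_high) {
    stop_config("invalid config: require 0 <= E_low < E_high <= 1")
  }
  check_nonneg(k_bind, "k_bind")
  check_nonneg(k_release, "k_release")
  check_positive(n_frames, "n_frames")
  check_positive(exposure, "exposure")
  n_frames <- as.integer(n_frames)

  with_seed(seed, {
    total_time <- n_frames * exposure
    state <- switch(init_state,
      free = "free",
      bound = "bound",
      stationary = {
        # stationary P(free) = k_release / (k_bind + k_release)
        p_free <- if (k_bind + k_release > 0) {
          k_release / (k_bind + k_release)
        } else 0.5
        if (stats::runif(1) < p_free) "free" else "bound"
      })
    t0 <- 0
    dwell_state <- character()
    dwell_dur <- numeric()
    boundaries <- numeric()      # state-change times
    states_seq <- character()    # state in each inter-change interval
    while (t0 < total_time) {
      rate <- if (state == "free") k_bind else k_release
      hold <- if (rate > 0) stats::rexp(1, rate) else Inf
      dwell_state <- c(dwell_state, state)
      dwell_dur <- c(dwell_dur, min(hold, total_time - t0))
      states_seq <- c(states_seq, state)
      t0 <- t0 + hold
      boundaries <- c(boundaries, min(t0, total_time))
      state <- if (state == "free") "bound" else "free"
    }
    censored <- c(rep(FALSE, length(dwell_dur) - 1L), TRUE)
    dwells <- data.frame(state = dwell_state, duration_s = dwell_dur,
                         censored = censored)

    # state at each frame start
    frame_t <- (seq_len(n_frames) - 1L) * exposure
    idx <- findInterval(frame_t, c(0, boundaries), rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > length(states_seq)] <- length(states_seq)
    frame_state <- states_seq[idx]
    E <- ifelse(frame_state == "free", E_high, E_low)

    I_A <- E * total_counts
    I_D <- (1 - E) * total_counts
    if (noise_sigma > 0) {
      I_A <- pmax(0, I_A + stats::rnorm(n_frames, sd = noise_sigma))
      I_D <- pmax(0, I_D + stats::rnorm(n_frames, sd = noise_sigma))
    }
    list(
      trace = data.frame(frame = seq_len(n_frames), time_s = frame_t,
                         I_D = I_D, I_A = I_A),
      truth = list(states = frame_state, dwells = dwells)
    )
  })
}
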