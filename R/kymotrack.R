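#' Detection parameters for kymograph localization
#'
#' @param threshold_k Candidate threshold: pixels brighter than
#'   `median + threshold_k * robust sigma` (MAD) of the averaged profile are
#'   peak candidates (default 3).
#' @param fit_halfwidth Half-width of the fit window around a candidate
#'   maximum, pixels (default 5).
#' @param min_separation Minimum separation between candidate maxima,
#'   pixels (default 3).
#' @param psf_sigma Starting value for the Gaussian width, pixels.
#' @return List of class `detect_params`.
#' @export
detect_params <- function(threshold_k = 3, fit_halfwidth = 5,
                          min_separation = 3, psf_sigma = 1.5) {
  structure(list(threshold_k = threshold_k,
                 fit_halfwidth = as.integer(fit_halfwidth),
                 min_separation = as.integer(min_separation),
                 psf_sigma = psf_sigma),
            class = "detect_params")
}

#' Localize particles in one kymograph frame
#'
#' Sub-pixel localization by the three-frame-window 1D Gaussian fit: the
#' intensity profiles of frames `frame - 1`, `frame`, `frame + 1` are
#' averaged (truncated to two frames at the sequence edges), candidate
#' peaks above a robust threshold are detected, and each candidate is fitted
#' with `offset + amplitude * exp(-(p - mu)^2 / (2 sigma^2))` over a window
#' around the maximum. Only converged fits are returned; a frame with no
#' peak above threshold yields an empty result.
#'
#' @param kymo A [kymograph()].
#' @param frame Frame index (1-based).
#' @param params A [detect_params()].
#' @return Data frame with columns `frame`, `time_s`, `position_nm`,
#'   `amplitude`, `width_nm`, `rss` (zero rows if nothing was found).
#' @export
localize_frame <- function(kymo, frame, params = detect_params()) {
  stopifnot(inherits(kymo, "kymograph"))
  nf <- ncol(kymo$intensity)
  if (frame < 1 || frame > nf) stop("frame index out of range", call. = FALSE)
  win <- intersect((frame - 1L):(frame + 1L), seq_len(nf))
  profile <- rowMeans(kymo$intensity[, win, drop = FALSE])
  loc <- localize_profile(profile, params)
  if (!nrow(loc)) {
    return(data.frame(frame = integer(), time_s = numeric(),
                      position_nm = numeric(), amplitude = numeric(),
                      width_nm = numeric(), rss = numeric()))
  }
  data.frame(frame = frame,
             time_s = (frame - 1) * kymo$line_time,
             position_nm = loc$mu_px * kymo$pixel_size,
             amplitude = loc$amplitude,
             width_nm = loc$sigma_px * kymo$pixel_size,
             rss = loc$rss)
}

# Gaussian-fit localization on a 1D intensity profile.
# Returns mu in 0-based continuous pixel coordinates.
localize_profile <- function(profile, params) {
  np <- length(profile)
  med <- stats::median(profile)
  sig <- stats::mad(profile)
  if (sig == 0) sig <- stats::sd(profile)
  if (!is.finite(sig) || sig == 0) sig <- 1e-9
  thr <- med + params$threshold_k * sig
  above <- which(profile > thr)
  if (!length(above)) {
    return(data.frame(mu_px = numeric(), amplitude = numeric(),
                      sigma_px = numeric(), rss = numeric()))
  }
  # local maxima among above-threshold pixels, enforcing min separation
  is_max <- vapply(above, function(j) {
    lo <- max(1L, j - 1L); hi <- min(np, j + 1L)
    profile[j] == max(profile[lo:hi])
  }, logical(1))
  cand <- above[is_max]
  cand <- cand[order(-profile[cand])]
  keep <- integer()
  for (j in cand) {
    if (!length(keep) || all(abs(keep - j) >= params$min_separation)) {
      keep <- c(keep, j)
    }
  }
  out <- lapply(sort(keep), function(j) {
    lo <- max(1L, j - params$fit_halfwidth)
    hi <- min(np, j + params$fit_halfwidth)
    px <- (lo:hi) - 1           # 0-based pixel coordinate
    y <- profile[lo:hi]
    st <- list(C = med, A = max(profile[j] - med, sig),
               mu = j - 1, s = params$psf_sigma)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ C + A * exp(-(px - mu)^2 / (2 * s^2)),
        start = st,
        lower = c(C = -Inf, A = 0, mu = j - 1 - params$fit_halfwidth,
                  s = 0.3),
        upper = c(C = Inf, A = Inf, mu = j - 1 + params$fit_halfwidth,
                  s = 4 * params$fit_halfwidth),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    if (cf[["A"]] <= 0 || cf[["mu"]] < 0 || cf[["mu"]] > np - 1) return(NULL)
    data.frame(mu_px = cf[["mu"]], amplitude = cf[["A"]],
               sigma_px = cf[["s"]], rss = sum(stats::resid(fit)^2))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(mu_px = numeric(), amplitude = numeric(),
                      sigma_px = numeric(), rss = numeric()))
  }
  fits <- do.call(rbind, out)
  # distinct candidates can converge onto the same emitter; keep the
  # brightest fit within min_separation of each position
  fits <- fits[order(-fits$amplitude), , drop = FALSE]
  kept <- integer()
  for (k in seq_len(nrow(fits))) {
    if (!length(kept) ||
        all(abs(fits$mu_px[kept] - fits$mu_px[k]) >= params$min_separation)) {
      kept <- c(kept, k)
    }
  }
  fits <- fits[kept, , drop = FALSE]
  fits[order(fits$mu_px), , drop = FALSE]
}

#' Localize particles in every frame of a kymograph
#'
#' Applies [localize_frame()] to each frame and binds the results.
#'
#' @inheritParams localize_frame
#' @return Data frame of localizations sorted by frame.
#' @export
localize_kymograph <- function(kymo, params = detect_params()) {
  res <- lapply(seq_len(ncol(kymo$intensity)), function(f) {
    localize_frame(kymo, f, params)
  })
  do.call(rbind, res)
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour linking: frames are processed in order and each
#' localization may extend at most one existing track. A link requires a
#' displacement of at most `max_step` nm and a frame gap of at most
#' `max_gap` frames; among competing candidates the smallest displacement
#' wins and the remaining localization starts a new track. Tracks shorter
#' than `min_length` localizations (unlinked singletons) are dropped from
#' the returned set.
#'
#' @param locs Data frame of localizations (from [localize_kymograph()]),
#'   sorted by frame.
#' @param max_step Maximum frame-to-frame displacement, nm.
#' @param max_gap Maximum allowed gap, frames (default 1 = consecutive
#'   frames only... values > 1 tolerate missed detections).
#' @param min_length Minimum number of localizations per returned track
#'   (default 2).
#' @return List of trajectories; each is a data frame with the localization
#'   columns plus `track_id`. The list carries class `track_set`.
#' @export
link_trajectories <- function(locs, max_step = 300, max_gap = 1,
                              min_length = 2) {
  if (!nrow(locs)) return(structure(list(), class = "track_set"))
  if (is.unsorted(locs$frame)) locs <- locs[order(locs$frame), ]
  tracks <- list()         # each: list(rows = integer indices, last = idx)
  active_last <- integer() # row index of each track's last localization
  for (f in sort(unique(locs$frame))) {
    rows <- which(locs$frame == f)
    if (length(active_last)) {
      gap <- f - locs$frame[active_last]
      ok_tracks <- which(gap >= 1 & gap <= max_gap)
    } else ok_tracks <- integer()
    if (length(ok_tracks) && length(rows)) {
      cand <- expand.grid(tr = ok_tracks, row = rows)
      cand$d <- abs(locs$position_nm[cand$row] -
                      locs$position_nm[active_last[cand$tr]])
      cand <- cand[cand$d <= max_step, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_tr <- logical(length(tracks))
      used_row <- logical(nrow(locs))
      for (k in seq_len(nrow(cand))) {
        tr <- cand$tr[k]; row <- cand$row[k]
        if (!used_tr[tr] && !used_row[row]) {
          tracks[[tr]]$rows <- c(tracks[[tr]]$rows, row)
          active_last[tr] <- row
          used_tr[tr] <- TRUE
          used_row[row] <- TRUE
        }
      }
      rows <- rows[!used_row[rows]]
    }
    for (row in rows) {    # unmatched localizations start new tracks
      tracks[[length(tracks) + 1L]] <- list(rows = row)
      active_last[length(tracks)] <- row
    }
  }
  out <- list()
  for (tr in tracks) {
    if (length(tr$rows) >= min_length) {
      df <- locs[tr$rows, , drop = FALSE]
      df$track_id <- length(out) + 1L
      rownames(df) <- NULL
      out[[length(out) + 1L]] <- df
    }
  }
  structure(out, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d trajectories (lengths %s)\n", length(x),
              paste(vapply(x, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Build a trajectory from time and position vectors
#'
#' @param time_s Times, s, strictly increasing with (near-)constant spacing.
#' @param position_nm Positions along the DNA, nm.
#' @return Data frame of class `trajectory` with columns `time_s`,
#'   `position_nm`.
#' @export
as_trajectory <- function(time_s, position_nm) {
  if (length(time_s) != length(position_nm) || length(time_s) < 2L) {
    stop("trajectory needs >= 2 (time, position) pairs", call. = FALSE)
  }
  check_uniform_dt(time_s)
  structure(data.frame(time_s = time_s, position_nm = position_nm),
            class = c("trajectory", "data.frame"))
}
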