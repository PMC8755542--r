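#' FRET efficiency from donor and acceptor intensities
#'
#' `E_t = I_A / (I_D + I_A)` per frame, from integrated donor and acceptor
#' intensities. Frames with zero total intensity are returned as `NA`
#' (missing), and negative counts are an error.
#'
#' @param I_D,I_A Non-negative count vectors of equal length.
#' @return Numeric vector of efficiencies in `[0, 1]` (with `NA` for
#'   zero-total frames).
#' @examples
#' compute_fret(c(0, 50, 70), c(100, 50, 30))   # 1.0 0.5 0.3
#' @export
compute_fret <- function(I_D, I_A) {
  if (length(I_D) != length(I_A)) {
    stop("I_D and I_A must have equal length", call. = FALSE)
  }
  if (any(I_D < 0, na.rm = TRUE) || any(I_A < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  total <- I_D + I_A
  E <- ifelse(total > 0, I_A / total, NA_real_)
  E
}

#' Population FRET histogram from the start of each trajectory
#'
#' For each trace the first 10 frames are averaged to one FRET value, and
#' the values are histogrammed with bins of width 0.1 on `[0, 1]`. Bins are
#' left-closed (`[0.0, 0.1), ..., [0.9, 1.0]`, the last bin closed on both
#' sides). Traces shorter than 10 frames are excluded with a message.
#'
#' @param traces List of FRET traces: each either a numeric E series or a
#'   data frame with `I_D`, `I_A` columns (E computed via
#'   [compute_fret()]).
#' @param n_first Number of initial frames averaged per trace (default 10).
#' @return List of class `fret_histogram`: `counts` (length 10),
#'   `breaks` (0, 0.1, ..., 1), `values` (one mean E per included trace),
#'   `n_excluded`.
#' @export
fret_histogram <- function(traces, n_first = 10) {
  vals <- numeric()
  n_excluded <- 0L
  for (tr in traces) {
    E <- if (is.numeric(tr)) tr else compute_fret(tr$I_D, tr$I_A)
    if (length(E) < n_first) {
      n_excluded <- n_excluded + 1L
      next
    }
    vals <- c(vals, mean(E[seq_len(n_first)], na.rm = TRUE))
  }
  if (n_excluded > 0L) {
    message(sprintf("%d trace(s) shorter than %d frames excluded",
                    n_excluded, n_first))
  }
  breaks <- seq(0, 1, by = 0.1)
  # left-closed bins; E = 1.0 falls in the last bin
  idx <- pmin(findInterval(vals, breaks, rightmost.closed = TRUE,
                           left.open = FALSE), 10L)
  counts <- tabulate(idx, nbins = 10L)
  structure(list(counts = counts, breaks = breaks, values = vals,
                 n_excluded = n_excluded),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("<fret_histogram>\n")
  lab <- sprintf("[%.1f,%.1f%s", utils::head(x$breaks, -1), x$breaks[-1],
                 c(rep(")", 9), "]"))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-10s %d\n", lab[i], x$counts[i]))
  }
  invisible(x)
}

#' Suggest a two-state threshold from a FRET histogram
#'
#' Uses the midpoint of the two mixture-model modes of the per-trace FRET
#' values (1D Gaussian mixture, 2 components); falls back to 0.5 when a
#' bimodal fit is not supported by the data.
#'
#' @param values Numeric FRET values (e.g. `fret_histogram(...)$values` or
#'   a pooled E series).
#' @return Threshold in (0, 1).
#' @export
fret_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) return(0.5)
  mc <- tryCatch(mclust_fit(values, G = 2), error = function(e) NULL)
  if (is.null(mc)) return(0.5)
  m <- sort(unname(mc$parameters$mean))
  if (diff(m) < 0.1) return(0.5)
  mean(m)
}

#' Segment a FRET trace into free and bound states
#'
#' Thresholds the efficiency series -- frames with `E >= threshold` are the
#' protein-free (high FRET) state, frames below are the bound (low FRET)
#' state -- and merges consecutive same-state frames into intervals whose
#' durations are `frames * exposure`. Runs shorter than `min_dwell` frames
#' are treated as noise crossings and absorbed into the preceding state.
#' The first and last intervals are flagged censored (their true start or
#' end was not observed).
#'
#' @param E Numeric FRET efficiency series (may contain `NA` for missing
#'   frames, but not be entirely missing).
#' @param threshold State threshold in (0, 1); see [fret_threshold()].
#' @param exposure Frame exposure time, s (default 0.030).
#' @param min_dwell Minimum run length in frames (default 2; set 1 to
#'   disable the filter).
#' @return Data frame of class `state_segmentation`: `state` ("free" or
#'   "bound"), `start_frame`, `end_frame`, `n_frames`, `duration_s`,
#'   `censored`; attribute `threshold`.
#' @export
segment_states <- function(E, threshold = 0.5, exposure = 0.030,
                           min_dwell = 2) {
  if (all(is.na(E))) stop("all frames missing", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  # carry the previous state across missing frames
  lab <- ifelse(E >= threshold, "free", "bound")
  for (i in seq_along(lab)) {
    if (is.na(lab[i]) && i > 1L) lab[i] <- lab[i - 1L]
  }
  lab <- rev(lab)
  for (i in seq_along(lab)) {
    if (is.na(lab[i]) && i > 1L) lab[i] <- lab[i - 1L]
  }
  lab <- rev(lab)
  r <- rle(lab)
  if (min_dwell > 1L && length(r$lengths) > 1L) {
    repeat {
      short <- which(r$lengths < min_dwell)
      short <- short[short > 1L]
      if (!length(short)) break
      j <- short[1]
      r$values[j] <- r$values[j - 1L]
      r <- rle(inverse.rle(r))
    }
    # a short leading run joins the following state
    if (length(r$lengths) > 1L && r$lengths[1] < min_dwell) {
      r$values[1] <- r$values[2]
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- data.frame(state = r$values,
                    start_frame = starts,
                    end_frame = ends,
                    n_frames = r$lengths,
                    duration_s = r$lengths * exposure,
                    censored = FALSE)
  seg$censored[1] <- TRUE
  seg$censored[nrow(seg)] <- TRUE
  structure(seg, class = c("state_segmentation", "data.frame"),
            threshold = threshold)
}

#' Dwell times from a state segmentation
#'
#' Extracts the dwell durations of one state, by default excluding the
#' censored first/last intervals so that downstream exponential fits are
#' unbiased.
#'
#' @param seg A [segment_states()] result.
#' @param state `"free"` (t_on) or `"bound"` (t_off).
#' @param drop_censored Exclude censored intervals (default TRUE).
#' @return Data frame `duration_s`, `censored`.
#' @export
state_dwells <- function(seg, state = c("free", "bound"),
                         drop_censored = TRUE) {
  state <- match.arg(state)
  out <- seg[seg$state == state, c("duration_s", "censored")]
  if (drop_censored) out <- out[!out$censored, , drop = FALSE]
  rownames(out) <- NULL
  out
}
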