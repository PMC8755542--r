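#' Fit a single-exponential dwell-time distribution
#'
#' Estimates the mean dwell time `tau` of a single-rate process. Two
#' methods are provided: `"mle"` maximises the censored-exponential
#' likelihood, `tau = (sum of all durations) / (number of uncensored
#' events)`, which for fully uncensored data reduces exactly to the sample
#' mean; `"histogram"` reproduces the figure-style fit of an exponential to
#' binned dwell counts (Freedman-Diaconis bins) by nonlinear least squares.
#'
#' @param dwells Numeric vector of dwell durations, s (> 0), or a data
#'   frame with columns `duration_s` and optionally `censored`.
#' @param censored Logical vector of right-censoring flags (dwell still in
#'   progress when the recording ended); default all `FALSE`.
#' @param method `"mle"` (default) or `"histogram"`.
#' @return List of class `kinetic_fit`: `tau` (s), `se`, `n`,
#'   `n_censored`, `method`.
#' @examples
#' fit_dwell_exponential(c(2, 2, 2))$tau   # 2
#' @export
fit_dwell_exponential <- function(dwells, censored = NULL,
                                  method = c("mle", "histogram")) {
  method <- match.arg(method)
  if (is.data.frame(dwells)) {
    if (is.null(censored) && "censored" %in% names(dwells)) {
      censored <- dwells$censored
    }
    dwells <- dwells$duration_s
  }
  if (is.null(censored)) censored <- rep(FALSE, length(dwells))
  if (any(dwells <= 0)) stop("dwell durations must be positive", call. = FALSE)
  n_unc <- sum(!censored)
  if (n_unc == 0L) stop("all dwells censored: tau not estimable", call. = FALSE)
  if (n_unc < 5L) stop("need at least 5 uncensored dwells", call. = FALSE)

  if (method == "mle") {
    tau <- sum(dwells) / n_unc
    se <- tau / sqrt(n_unc)
  } else {
    obs <- dwells[!censored]
    h <- graphics::hist(obs, breaks = "FD", plot = FALSE)
    mids <- h$mids
    counts <- h$counts
    keep <- counts > 0
    start <- list(N0 = max(counts), tau = mean(obs))
    fit <- minpack.lm::nlsLM(counts ~ N0 * exp(-mids / tau),
                             data = list(counts = counts[keep], mids = mids[keep]),
                             start = start,
                             lower = c(N0 = 0, tau = 1e-9))
    cf <- stats::coef(fit)
    tau <- unname(cf[["tau"]])
    se <- tryCatch(unname(sqrt(diag(stats::vcov(fit)))[["tau"]]),
                   error = function(e) NA_real_)
  }
  structure(list(tau = tau, se = se, n = length(dwells),
                 n_censored = sum(censored), method = method),
            class = "kinetic_fit")
}

#' Fit an exponential fluorescence-loss (stripping) rate
#'
#' Nonlinear least-squares fit of `I(t) = A * exp(-k * t) + C` to an
#' integrated-fluorescence decay trace, returning the stripping rate `k` in
#' 1/min with its standard error. A trace with no net decrease is returned
#' as `k = 0` with `no_decay = TRUE` rather than forcing a fit.
#'
#' @param trace Data frame with columns `time_min` and `intensity`
#'   (>= 10 points), e.g. from [simulate_decay_trace()].
#' @return List of class `kinetic_fit`: `k` (1/min), `se`, `A`, `C`,
#'   `no_decay`, `method = "nls"`.
#' @examples
#' tr <- simulate_decay_trace(k = 0.1, A = 1, C = 0, total_dur = 30, dt = 1)
#' fit_decay_rate(tr)$k
#' @export
fit_decay_rate <- function(trace) {
  t <- trace$time_min
  y <- trace$intensity
  if (length(t) < 10L) stop("need at least 10 time points", call. = FALSE)
  slope <- stats::coef(stats::lm(y ~ t))[2]
  if (slope >= 0) {
    warning("trace shows no net decay; returning k = 0")
    return(structure(list(k = 0, se = NA_real_, A = 0, C = mean(y),
                          no_decay = TRUE, method = "nls"),
                     class = "kinetic_fit"))
  }
  A0 <- max(y) - min(y)
  C0 <- min(y)
  k0 <- max(1 / (max(t) / 3), 1e-6)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-k * t) + C,
                           start = list(A = A0, k = k0, C = C0),
                           lower = c(A = 0, k = 0, C = -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["k"]], error = function(e) NA_real_)
  structure(list(k = unname(cf[["k"]]), se = unname(se),
                 A = unname(cf[["A"]]), C = unname(cf[["C"]]),
                 no_decay = FALSE, method = "nls"),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!is.null(x$tau)) {
    cat(sprintf("<kinetic_fit> tau = %.3g +/- %.2g s (%s, n = %d, %d censored)\n",
                x$tau, x$se, x$method, x$n, x$n_censored))
  } else {
    cat(sprintf("<kinetic_fit> k = %.4g +/- %.2g 1/min%s\n", x$k, x$se,
                if (isTRUE(x$no_decay)) " [no decay]" else ""))
  }
  invisible(x)
}

#' Count binding events and collect dwell times from trajectories
#'
#' Counts tracks lasting at least `min_duration` seconds, grouped by DNA
#' molecule, and collects each qualifying track's duration as a dwell time.
#' Tracks that are still present at the end of the recording are flagged as
#' right-censored.
#'
#' @param tracks A `track_set` (see [link_trajectories()]) or list of
#'   trajectories with `time_s` columns.
#' @param min_duration Minimum track duration to count as an event, s.
#' @param recording_end End time of the recording, s; tracks whose last
#'   frame reaches it (within half a frame) are censored. Default: the
#'   latest time seen across tracks.
#' @param molecule Optional vector assigning each track to a molecule id;
#'   default: all tracks on one molecule.
#' @return List with `frequency` (named vector, events per molecule) and
#'   `dwells` (data frame `duration_s`, `censored`, `molecule`).
#' @export
count_events <- function(tracks, min_duration = 0, recording_end = NULL,
                         molecule = NULL) {
  if (!length(tracks)) {
    return(list(frequency = integer(),
                dwells = data.frame(duration_s = numeric(),
                                    censored = logical(),
                                    molecule = character())))
  }
  if (is.null(molecule)) molecule <- rep("mol1", length(tracks))
  last_t <- vapply(tracks, function(tr) max(tr$time_s), numeric(1))
  first_t <- vapply(tracks, function(tr) min(tr$time_s), numeric(1))
  dts <- vapply(tracks, function(tr) stats::median(diff(tr$time_s)), numeric(1))
  if (is.null(recording_end)) recording_end <- max(last_t)
  duration <- last_t - first_t + dts   # inclusive of the final frame
  censored <- last_t >= recording_end - dts / 2
  keep <- duration >= min_duration
  freq <- table(factor(molecule[keep], levels = unique(molecule)))
  list(frequency = stats::setNames(as.integer(freq), names(freq)),
       dwells = data.frame(duration_s = duration[keep],
                           censored = censored[keep],
                           molecule = molecule[keep]))
}
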