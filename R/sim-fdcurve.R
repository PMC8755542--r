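#' Simulate a force-extension curve with unfolding events
#'
#' Generates a multi-branch worm-like chain force-extension curve: the
#' molecule starts on a branch with the contour length in `polymer`, and at
#' each configured trigger force an unfolding event releases `delta_Lc` nm
#' of contour length (e.g. disruption of a protein-mediated DNA loop),
#' dropping the force onto the next branch. Gaussian noise is added to the
#' force channel. The true contour-length sequence and per-sample branch
#' assignment are stored as ground truth.
#'
#' @param polymer A [polymer_params()] giving the initial branch (its `Lc`
#'   is the first contour length).
#' @param events Data frame with columns `trigger_force` (pN, strictly
#'   increasing) and `delta_Lc` (nm, > 0); zero rows for a single smooth
#'   branch.
#' @param noise_sigma Gaussian noise sd on force, pN.
#' @param n_points Number of extension samples.
#' @param max_rel_ext Largest sampled extension as a fraction of the final
#'   contour length (default 0.95); must remain < 1 on every branch or an
#'   error is raised.
#' @param seed Integer seed.
#' @return List with `curve` (data frame `extension_nm`, `force_pN`) and
#'   `truth` (list: `Lc` true contour length per sample, `Lc_sequence`,
#'   `event_index` first sample of each new branch).
#' @examples
#' p <- polymer_params(Lp = 50, Lc = 15000)
#' sim <- simulate_fd_curve(p, data.frame(trigger_force = 20, delta_Lc = 500),
#'                          noise_sigma = 0, seed = 1)
#' sim$truth$Lc_sequence   # 15000 15500
#' @export
simulate_fd_curve <- function(polymer, events = NULL, noise_sigma = 0.2,
                              n_points = 600, max_rel_ext = 0.95,
                              seed = NULL) {
  stopifnot(inherits(polymer, "polymer_params"))
  if (is.null(events)) {
    events <- data.frame(trigger_force = numeric(), delta_Lc = numeric())
  }
  if (nrow(events)) {
    if (any(events$delta_Lc <= 0)) {
      stop_config("invalid config: delta_Lc must be positive")
    }
    if (is.unsorted(events$trigger_force, strictly = TRUE)) {
      stop_config("invalid config: trigger forces must be strictly increasing")
    }
  }
  check_nonneg(noise_sigma, "noise_sigma")
  check_positive(n_points, "n_points")
  if (max_rel_ext <= 0 || max_rel_ext >= 1) {
    stop_config("invalid config: max_rel_ext must lie in (0, 1)")
  }

  with_seed(seed, {
    Lc_final <- polymer$Lc + sum(events$delta_Lc)
    extension <- seq(0, max_rel_ext * Lc_final, length.out = as.integer(n_points))
    Lc_cur <- polymer$Lc
    ev <- 1L
    Lc_track <- numeric(length(extension))
    force <- numeric(length(extension))
    event_index <- integer()
    for (i in seq_along(extension)) {
      x <- extension[i]
      if (x >= Lc_cur) {
        stop_config(
          "extension %.1f nm >= current contour length %.1f nm: ",
          x, Lc_cur)
      }
      pp <- polymer
      pp$Lc <- Lc_cur
      f <- wlc_force(x, pp)
      while (ev <= nrow(events) && f >= events$trigger_force[ev]) {
        Lc_cur <- Lc_cur + events$delta_Lc[ev]
        ev <- ev + 1L
        event_index <- c(event_index, i)
        pp$Lc <- Lc_cur
        f <- wlc_force(x, pp)
      }
      Lc_track[i] <- Lc_cur
      force[i] <- f
    }
    noise <- if (noise_sigma > 0) stats::rnorm(length(force), sd = noise_sigma) else 0
    list(
      curve = data.frame(extension_nm = extension, force_pN = force + noise),
      truth = list(Lc = Lc_track,
                   Lc_sequence = c(polymer$Lc,
                                   polymer$Lc + cumsum(events$delta_Lc)),
                   event_index = event_index)
    )
  })
}
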