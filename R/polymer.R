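#' Polymer elasticity parameters
#'
#' Parameters of the worm-like chain (WLC) and freely jointed chain (FJC)
#' force-extension models used to fit optical-tweezer data on DNA.
#'
#' @param Lp Persistence length, nm (dsDNA ~ 50 nm).
#' @param Lc Contour length, nm.
#' @param kT Thermal energy, pN nm (4.114 at ~298 K).
#' @param S Stretch modulus, pN, for the extensible WLC variant; `NULL` for
#'   the inextensible Marko-Siggia interpolation.
#' @param kuhn Kuhn length, nm, for the FJC (ssDNA ~ 1.5 nm).
#' @return A list of class `polymer_params`.
#' @examples
#' p <- polymer_params(Lp = 50, Lc = 16000)
#' @export
polymer_params <- function(Lp = 50, Lc = 16000, kT = 4.114, S = NULL,
                           kuhn = 1.5) {
  check_positive(Lp, "Lp")
  check_positive(Lc, "Lc")
  check_positive(kT, "kT")
  if (!is.null(S)) check_positive(S, "S")
  check_positive(kuhn, "kuhn")
  structure(list(Lp = Lp, Lc = Lc, kT = kT, S = S, kuhn = kuhn),
            class = "polymer_params")
}

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation formula
#' `F = (kT/Lp) * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)`. With a finite stretch
#' modulus `S` in `p`, the extensible variant replaces `x/Lc` by
#' `x/Lc - F/S` and the force is solved self-consistently per point.
#'
#' @param extension Extension(s) x, nm. Inextensible variant requires
#'   `0 <= x < Lc`.
#' @param p A [polymer_params()].
#' @return Force(s), pN.
#' @examples
#' wlc_force(0, polymer_params())                  # 0 pN
#' wlc_force(8000, polymer_params(Lc = 16000))     # x/Lc = 0.5
#' @export
wlc_force <- function(extension, p) {
  stopifnot(inherits(p, "polymer_params"))
  if (any(extension < 0)) stop("extension must be non-negative", call. = FALSE)
  if (is.null(p$S)) {
    if (any(extension >= p$Lc)) {
      stop("extension >= contour length: outside inextensible WLC domain",
           call. = FALSE)
    }
    z <- extension / p$Lc
    (p$kT / p$Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
  } else {
    ms <- function(l) (p$kT / p$Lp) * (1 / (4 * (1 - l)^2) - 0.25 + l)
    vapply(extension, function(x) {
      g <- function(f) ms(x / p$Lc - f / p$S) - f
      # effective fractional extension must stay below 1
      fmin <- max(0, (x / p$Lc - 0.999999) * p$S)
      stats::uniroot(g, lower = fmin, upper = fmin + 1e6,
                     extendInt = "downX", tol = 1e-10)$root
    }, numeric(1))
  }
}

#' Freely jointed chain extension at a given force
#'
#' Extensible FJC model used as a single-stranded DNA reference:
#' `x(F) = Lc * (coth(F b / kT) - kT / (F b)) * (1 + F/S)` with Kuhn length
#' `b`. Returns 0 at zero force.
#'
#' @param force Force(s), pN.
#' @param p A [polymer_params()]; uses fields `Lc`, `kT`, `kuhn` and (if
#'   non-`NULL`) `S`.
#' @return Extension(s), nm.
#' @export
fjc_extension <- function(force, p) {
  stopifnot(inherits(p, "polymer_params"))
  b <- p$kuhn
  stretch <- if (is.null(p$S)) rep(1, length(force)) else 1 + force / p$S
  u <- force * b / p$kT
  lang <- ifelse(u == 0, 0, 1 / tanh(u) - 1 / u)   # Langevin function
  p$Lc * lang * stretch
}

#' Fit the contour length of a force-extension branch
#'
#' Least-squares fit of the WLC model to one branch of a force-extension
#' curve with the contour length `Lc` as the only free parameter
#' (persistence length and temperature fixed). The standard error is
#' obtained from the curvature of the residual sum of squares at the
#' optimum, so a branch sampled only at low force (where the model is
#' insensitive to `Lc`) reports a correspondingly wide standard error.
#'
#' @param extension,force Numeric vectors, nm and pN, one branch.
#' @param p A [polymer_params()]; its `Lc` is used only to bound the search.
#' @param n_min Minimum number of points required (default 20).
#' @return List with `Lc` (nm), `se`, `rss`, `n`.
#' @examples
#' p <- polymer_params(Lp = 50, Lc = 16000)
#' x <- seq(1000, 15000, length.out = 100)
#' fit_contour_length(x, wlc_force(x, p), p)$Lc
#' @export
fit_contour_length <- function(extension, force, p, n_min = 20) {
  stopifnot(inherits(p, "polymer_params"))
  if (length(extension) != length(force)) {
    stop("extension and force must have equal length", call. = FALSE)
  }
  if (length(extension) < n_min) {
    stop(sprintf("branch has %d points; need at least %d",
                 length(extension), n_min), call. = FALSE)
  }
  xmax <- max(extension)
  ss <- function(Lc) {
    pp <- p
    pp$Lc <- Lc
    sum((wlc_force(extension, pp) - force)^2)
  }
  lower <- xmax * 1.000001
  upper <- max(xmax * 50, p$Lc * 10)
  opt <- stats::optimize(ss, interval = c(lower, upper), tol = 1e-6)
  Lc_hat <- opt$minimum
  if (!is.finite(opt$objective)) {
    stop(sprintf("contour-length fit failed to converge (rss = %g)",
                 opt$objective), call. = FALSE)
  }
  # se from numeric curvature of the SS surface
  h <- max(Lc_hat * 1e-5, 1e-3)
  d2 <- (ss(Lc_hat + h) - 2 * opt$objective + ss(Lc_hat - h)) / h^2
  sigma2 <- opt$objective / max(1L, length(force) - 1L)
  se <- if (d2 > 0) sqrt(2 * sigma2 / d2) else Inf
  list(Lc = Lc_hat, se = se, rss = opt$objective, n = length(force))
}

#' Detect unfolding events in a force-extension curve
#'
#' Splits a force-extension curve into branches of constant contour length.
#' Points are scanned in order of increasing extension while a running WLC
#' fit (contour length free) tracks the current branch; when the absolute
#' force residual of an incoming point exceeds `residual_threshold` the
#' point starts a new branch. Unfolding events appear as characteristic
#' force drops at these boundaries. Branches that end up shorter than
#' `min_branch` points are merged into their neighbour.
#'
#' @param extension,force Numeric vectors sorted by increasing extension.
#' @param p A [polymer_params()] with the fixed `Lp` and `kT`.
#' @param residual_threshold Force residual, pN, that triggers a new branch
#'   (default 2).
#' @param min_branch Minimum points per branch (default 20).
#' @param refit_every Refit cadence while scanning (default 5 points).
#' @return Integer vector of boundary indices (first point of each new
#'   branch); empty if the curve is a single branch.
#' @export
detect_events <- function(extension, force, p, residual_threshold = 2,
                          min_branch = 20, refit_every = 5) {
  stopifnot(inherits(p, "polymer_params"))
  n <- length(extension)
  if (n != length(force)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(extension)) {
    stop("curve must be sorted by increasing extension", call. = FALSE)
  }
  boundaries <- integer()
  start <- 1L
  i <- start + min_branch
  fit <- NULL
  last_fit_at <- -Inf
  while (i <= n) {
    if (is.null(fit) || (i - last_fit_at) >= refit_every) {
      idx <- start:(i - 1L)
      fit <- tryCatch(
        fit_contour_length(extension[idx], force[idx], p, n_min = 5),
        error = function(e) NULL)
      last_fit_at <- i
    }
    if (!is.null(fit)) {
      pp <- p
      pp$Lc <- fit$Lc
      pred <- if (extension[i] < fit$Lc || !is.null(p$S)) {
        wlc_force(extension[i], pp)
      } else Inf
      if (abs(pred - force[i]) > residual_threshold) {
        boundaries <- c(boundaries, i)
        start <- i
        i <- i + min_branch
        fit <- NULL
        next
      }
    }
    i <- i + 1L
  }
  # merge trailing short branch
  if (length(boundaries) && (n - boundaries[length(boundaries)] + 1L) < min_branch) {
    boundaries <- boundaries[-length(boundaries)]
  }
  boundaries
}

#' Loop sizes from a sequence of fitted contour lengths
#'
#' The contour length released at each unfolding event equals the difference
#' between the contour lengths fitted to neighbouring branches, i.e. the
#' size of the DNA loop disrupted at that event. Negative differences are
#' non-physical and flagged with a warning but retained.
#'
#' @param Lc Numeric vector of per-branch contour lengths, nm, in event
#'   order (>= 2 values for a non-empty result).
#' @return Numeric vector of loop sizes, nm (length `length(Lc) - 1`).
#' @examples
#' loop_sizes(c(15000, 15500))   # 500
#' @export
loop_sizes <- function(Lc) {
  if (length(Lc) < 2L) return(numeric())
  d <- diff(Lc)
  if (any(d < 0)) {
    warning("negative contour-length difference: non-physical loop size retained")
  }
  d
}

#' Analyse a force-extension curve end to end
#'
#' Convenience wrapper: detect unfolding events, fit each branch's contour
#' length and derive loop sizes.
#'
#' @inheritParams detect_events
#' @return List with `boundaries`, `branches` (data frame: `start`, `end`,
#'   `Lc`, `se`, `n`), and `loops` (nm).
#' @export
analyze_fd_curve <- function(extension, force, p, residual_threshold = 2,
                             min_branch = 20) {
  b <- detect_events(extension, force, p, residual_threshold, min_branch)
  starts <- c(1L, b)
  ends <- c(b - 1L, length(extension))
  branches <- do.call(rbind, lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    f <- fit_contour_length(extension[idx], force[idx], p,
                            n_min = min(20, length(idx)))
    data.frame(start = starts[i], end = ends[i], Lc = f$Lc, se = f$se,
               n = f$n)
  }))
  list(boundaries = b, branches = branches,
       loops = loop_sizes(branches$Lc))
}
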