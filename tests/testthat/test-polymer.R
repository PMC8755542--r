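test_that("WLC interpolation formula evaluates as printed", {
  p <- polymer_params(Lp = 50, Lc = 16000, kT = 4.114)
  expect_equal(wlc_force(0, p), 0)
  expect_equal(wlc_force(8000, p), 0.1029, tolerance = 1e-3)
  # strictly increasing across the domain
  x <- seq(0, 0.99 * p$Lc, length.out = 500)
  expect_true(all(diff(wlc_force(x, p)) > 0))
  expect_error(wlc_force(16000, p), "domain|contour")
})

test_that("WLC low-force limit reduces to the Hooke law", {
  p <- polymer_params(Lp = 50, Lc = 16000)
  # the interpolation formula deviates from the Hooke line by ~(x/Lc)/2 to
  # leading order, so the 2% regime extends to x/Lc ~ 0.038
  x <- seq(1, 0.035 * p$Lc, length.out = 50)
  hooke <- 1.5 * p$kT / p$Lp * (x / p$Lc)
  rel <- abs(wlc_force(x, p) - hooke) / hooke
  expect_lt(max(rel), 0.02)
  # and the deviation vanishes towards x = 0
  expect_lt(rel[1], 1e-3)
})

test_that("extensible WLC is self-consistent and softer than inextensible", {
  p0 <- polymer_params(Lp = 50, Lc = 16000)
  pS <- polymer_params(Lp = 50, Lc = 16000, S = 1200)
  x <- c(4000, 8000, 14000)
  F_in <- wlc_force(x, p0)
  F_ex <- wlc_force(x, pS)
  expect_true(all(F_ex <= F_in + 1e-9))
  # self-consistency: plugging F back reproduces the Marko-Siggia branch
  z_eff <- x / pS$Lc - F_ex / pS$S
  ms <- (pS$kT / pS$Lp) * (1 / (4 * (1 - z_eff)^2) - 0.25 + z_eff)
  expect_equal(ms, F_ex, tolerance = 1e-6)
})

test_that("FJC extension has the right limits", {
  p <- polymer_params(Lc = 10000, kuhn = 1.5, S = 800)
  expect_equal(fjc_extension(0, p), 0)
  # high force: Langevin -> 1, extension -> Lc * (1 + F/S)
  expect_equal(fjc_extension(60, p), 10000 * (1 - 4.114 / (60 * 1.5)) * (1 + 60 / 800),
               tolerance = 1e-6)
})

test_that("contour-length fitting inverts the forward model", {
  p <- polymer_params(Lp = 50, Lc = 16000)
  x <- seq(1000, 15500, length.out = 120)
  fit <- fit_contour_length(x, wlc_force(x, p), p)
  expect_lt(abs(fit$Lc - 16000) / 16000, 0.001)
  # noisy branch: within 1% over 20 seeds
  errs <- sapply(1:20, function(s) {
    set.seed(200 + s)
    f <- wlc_force(x, p) + rnorm(length(x), sd = 0.5)
    abs(fit_contour_length(x, f, p)$Lc - 16000) / 16000
  })
  expect_lt(mean(errs), 0.01)
})

test_that("a low-force-only branch reports a wide standard error", {
  p <- polymer_params(Lp = 50, Lc = 16000)
  x_low <- seq(100, 9500, length.out = 60)    # forces stay below ~0.5 pN
  x_hi <- seq(1000, 15500, length.out = 60)
  set.seed(77)
  f_low <- fit_contour_length(x_low, wlc_force(x_low, p) +
                                rnorm(60, sd = 0.05), p)
  f_hi <- fit_contour_length(x_hi, wlc_force(x_hi, p) +
                               rnorm(60, sd = 0.05), p)
  expect_gt(f_low$se, 10 * f_hi$se)
})

test_that("event detection finds unfolding boundaries", {
  p <- polymer_params(Lp = 50, Lc = 15000)
  smooth <- simulate_fd_curve(p, events = NULL, noise_sigma = 0.2,
                              n_points = 800, seed = 81)
  expect_length(detect_events(smooth$curve$extension_nm,
                              smooth$curve$force_pN, p), 0)

  one <- simulate_fd_curve(p, data.frame(trigger_force = 20, delta_Lc = 500),
                           noise_sigma = 0.2, n_points = 1500, seed = 82)
  b <- detect_events(one$curve$extension_nm, one$curve$force_pN, p)
  expect_length(b, 1)
  expect_lte(abs(b - one$truth$event_index), 5)

  two <- simulate_fd_curve(p, data.frame(trigger_force = c(15, 30),
                                         delta_Lc = c(300, 800)),
                           noise_sigma = 0.2, n_points = 2000, seed = 83)
  b2 <- detect_events(two$curve$extension_nm, two$curve$force_pN, p)
  expect_length(b2, 2)
  expect_true(all(diff(b2) > 0))
})

test_that("loop sizes are contour-length differences, translation-invariant", {
  expect_equal(loop_sizes(c(15000, 15500)), 500)
  expect_length(loop_sizes(16000), 0)
  Lc <- c(14000, 14300, 15100)
  expect_equal(loop_sizes(Lc + 1234), loop_sizes(Lc))
  expect_warning(loop_sizes(c(15000, 14000)), "non-physical")
})

test_that("two-event curves recover the true loop sizes within 5%", {
  p <- polymer_params(Lp = 50, Lc = 15000)
  sim <- simulate_fd_curve(p, data.frame(trigger_force = c(15, 30),
                                         delta_Lc = c(300, 800)),
                           noise_sigma = 0.3, n_points = 2000, seed = 84)
  res <- analyze_fd_curve(sim$curve$extension_nm, sim$curve$force_pN, p)
  expect_equal(nrow(res$branches), 3)
  expect_lt(max(abs(res$loops - c(300, 800)) / c(300, 800)), 0.05)
})
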