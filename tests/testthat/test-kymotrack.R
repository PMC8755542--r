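make_peak_kymo <- function(mu_px, amplitude = 300, n_pixels = 32,
                           n_frames = 3, background = 10, psf_sigma = 1.5,
                           pixel_size = 100, noisy = FALSE) {
  px <- 0:(n_pixels - 1)
  profile <- background + amplitude * exp(-(px - mu_px)^2 / (2 * psf_sigma^2))
  m <- matrix(rep(profile, n_frames), ncol = n_frames)
  if (noisy) m <- matrix(rpois(length(m), m), nrow = n_pixels)
  kymograph(m, pixel_size = pixel_size, line_time = 0.997)
}

test_that("noiseless symmetric peak is localized to sub-pixel accuracy", {
  k <- make_peak_kymo(12.0)
  loc <- localize_frame(k, 2)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$position_nm, 1200, tolerance = 0.1 / 1200)
  expect_gt(loc$width_nm, 0)
})

test_that("noisy off-centre peak is recovered without bias", {
  # oracle: the noiseless least-squares fit returns the true centre
  k0 <- make_peak_kymo(12.37)
  expect_equal(localize_frame(k0, 2)$position_nm, 1237, tolerance = 1e-3)
  set.seed(11)
  pos <- replicate(200, {
    k <- make_peak_kymo(12.37, noisy = TRUE)
    loc <- localize_frame(k, 2)
    if (nrow(loc) == 1) loc$position_nm else NA_real_
  })
  pos <- pos[!is.na(pos)]
  expect_gt(length(pos), 180)
  expect_lt(abs(mean(pos) - 1237), 5)
})

test_that("a uniform background frame yields no localizations", {
  set.seed(5)
  m <- matrix(rpois(32 * 3, 10), nrow = 32)
  k <- kymograph(m, 100, 0.997)
  loc <- localize_frame(k, 2)
  expect_equal(nrow(loc), 0)
})

test_that("noiseless single-particle track matches the true path to 0.01 px", {
  cfg <- sim_config(seed = 4, n_frames = 60, n_pixels = 64,
                    noise_model = "none")
  sim <- simulate_kymograph(cfg, list(particle_directed(x0 = 1500, v = 14)))
  locs <- localize_kymograph(sim$kymograph)
  expect_equal(nrow(locs), 60)
  # three-frame averaging of a moving emitter displaces the centroid by
  # < v * line_time; compare the central frame positions to the truth
  truth <- sim$truth$paths[[1]]
  err_px <- abs(locs$position_nm - truth[locs$frame]) / cfg$pixel_size
  # interior frames: the symmetric 3-frame window cancels the motion shift
  expect_lt(max(err_px[2:59]), 0.01)
})

test_that("well-separated static particles stay on separate tracks", {
  cfg <- sim_config(seed = 6, n_frames = 40, n_pixels = 64,
                    noise_model = "poisson")
  sim <- simulate_kymograph(cfg, list(particle_static(x0 = 1000),
                                      particle_static(x0 = 3000)))
  locs <- localize_kymograph(sim$kymograph)
  tracks <- link_trajectories(locs, max_step = 300, max_gap = 2)
  long <- Filter(function(t) nrow(t) >= 20, tracks)
  expect_length(long, 2)
  means <- sort(vapply(long, function(t) mean(t$position_nm), numeric(1)))
  expect_lt(abs(means[1] - 1000), 100)
  expect_lt(abs(means[2] - 3000), 100)
  # no track mixes the two positions
  for (t in long) expect_lt(diff(range(t$position_nm)), 500)
})

test_that("directed particle displacement is recovered within 5%", {
  cfg <- sim_config(seed = 2, n_frames = 300, n_pixels = 128,
                    noise_model = "poisson")
  sim <- simulate_kymograph(cfg, list(particle_directed(x0 = 1000, v = 14,
                                                        amplitude = 300)))
  locs <- localize_kymograph(sim$kymograph)
  tracks <- link_trajectories(locs, max_step = 300, max_gap = 3)
  main <- tracks[[which.max(vapply(tracks, nrow, integer(1)))]]
  truth <- sim$truth$paths[[1]]
  true_disp <- truth[max(main$frame)] - truth[min(main$frame)]
  got_disp <- main$position_nm[nrow(main)] - main$position_nm[1]
  expect_lt(abs(got_disp - true_disp) / abs(true_disp), 0.05)
})

test_that("localization precision improves with amplitude", {
  sd_at <- function(amplitude) {
    set.seed(21)
    pos <- replicate(60, {
      k <- make_peak_kymo(12.3, amplitude = amplitude, noisy = TRUE)
      loc <- localize_frame(k, 2)
      if (nrow(loc) == 1) loc$position_nm else NA_real_
    })
    sd(pos, na.rm = TRUE)
  }
  expect_lt(sd_at(400), sd_at(100))
})

test_that("linking is invariant to localization order within a frame", {
  locs <- data.frame(frame = rep(1:5, each = 2),
                     time_s = rep(0:4, each = 2) * 0.997,
                     position_nm = c(rbind(1000 + 14 * (0:4),
                                           3000 - 10 * (0:4))),
                     amplitude = 300, width_nm = 150, rss = 0)
  shuffled <- locs[c(2, 1, 3, 4, 6, 5, 7, 8, 10, 9), ]
  t1 <- link_trajectories(locs, max_step = 300)
  t2 <- link_trajectories(shuffled, max_step = 300)
  key <- function(ts) {
    sets <- lapply(ts, function(t) sort(t$position_nm))
    sets[order(vapply(sets, min, numeric(1)))]
  }
  expect_equal(key(t1), key(t2))
})
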