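test_that("site positions respect the accessible annulus exactly", {
  set.seed(1)
  mix <- kinetic_mixture(1, k_d = 5, k_a = 0.1)
  for (f in c(0.2, 0.37, 0.64, 1.0)) {
    spec <- particle_spec(a = 2000, b = 1500, tilt = 0.4,
                          accessible_fraction = f, site_density = 100)
    sites <- generate_site_map(spec, mix)
    dx <- sites$x_nm - spec$center[1]; dy <- sites$y_nm - spec$center[2]
    xp <- cos(spec$tilt) * dx + sin(spec$tilt) * dy
    yp <- -sin(spec$tilt) * dx + cos(spec$tilt) * dy
    rho <- sqrt((xp / spec$a)^2 + (yp / spec$b)^2)
    expect_true(all(rho >= 1 - f - 1e-12))
    expect_true(all(rho <= 1 + 1e-12))
  }
})

test_that("a dense full disc is probed down to the center", {
  set.seed(2)
  spec <- particle_spec(a = 1000, b = 1000, site_density = 3000)
  sites <- generate_site_map(spec, kinetic_mixture(1, 1, 0.1))
  rho <- sqrt((sites$x_nm / 1000)^2 + (sites$y_nm / 1000)^2)
  expect_lt(min(rho), 0.05)
})

test_that("a thin-shell SPP geometry keeps all sites within the shell", {
  # 1.35-um particle with a 0.5-um accessible porous layer
  set.seed(3)
  spec <- particle_spec(a = 1350, b = 1350,
                        accessible_fraction = 0.5 / 1.35,
                        site_density = 200)
  sites <- generate_site_map(spec, kinetic_mixture(1, 1, 0.1))
  edge_dist <- 1350 - sqrt(sites$x_nm^2 + sites$y_nm^2)
  expect_true(all(edge_dist <= 500 + 1e-9))
  expect_true(all(edge_dist >= -1e-9))
})

test_that("site counts are Poisson with mean density x accessible area", {
  # disc with accessible area exactly 20 um^2 at 10 sites/um^2
  r <- sqrt(20 / pi) * 1000
  spec <- particle_spec(a = r, b = r, site_density = 10)
  expect_equal(accessible_shell_area(spec), 20, tolerance = 1e-12)
  set.seed(4)
  counts <- replicate(500, nrow(generate_site_map(
    spec, kinetic_mixture(1, 1, 0.1))))
  se <- sqrt(200 / 500)
  expect_lt(abs(mean(counts) - 200), 3 * se)
})

test_that("zero accessible area or invalid specs are rejected", {
  expect_error(particle_spec(a = 1000, b = 1000, accessible_fraction = 0))
  expect_error(particle_spec(a = 500, b = 1000))
  spec <- particle_spec(a = 1000, b = 1000, site_density = 0)
  set.seed(5)
  sites <- generate_site_map(spec, kinetic_mixture(1, 1, 0.1))
  expect_equal(nrow(sites), 0L)
})

test_that("no arrivals means an empty event table", {
  set.seed(6)
  spec <- particle_spec(a = 1000, b = 1000, site_density = 50)
  sites <- generate_site_map(spec, kinetic_mixture(1, k_d = 5, k_a = 0))
  ev <- simulate_events(sites, duration = 100)
  expect_equal(nrow(ev), 0L)
})

test_that("single-site dwells are exponential with mean 1/k_d", {
  sites <- data.frame(site = 1L, x_nm = 0, y_nm = 0, k_d = 2, k_a = 100,
                      component = 1L)
  ev <- simulate_events(sites, duration = 100, seed = 7)
  expect_gt(nrow(ev), 9000)
  se <- 0.5 / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$dwell_s) - 0.5), 3 * se)
  expect_true(all(ev$dwell_s > 0))
  expect_true(all(ev$t_start_s >= 0))
})

test_that("pooled dwells follow the two-component mixture law", {
  set.seed(8)
  spec <- particle_spec(a = 2000, b = 2000, site_density = 100)
  mix <- kinetic_mixture(c(0.5, 0.5), k_d = c(10, 0.5), k_a = c(0.1, 0.1))
  sites <- generate_site_map(spec, mix)
  ev <- simulate_events(sites, duration = 10000 / (sum(sites$k_a)))
  expect_gt(nrow(ev), 8000)
  d <- sort(ev$dwell_s)
  n <- length(d)
  Fd <- 1 - 0.5 * exp(-10 * d) - 0.5 * exp(-0.5 * d)
  ks <- max(pmax(abs(seq_len(n) / n - Fd), abs((seq_len(n) - 1) / n - Fd)))
  expect_lt(ks, 0.02)
  # mixture-mean invariant at 3 Monte-Carlo SEs
  mu <- 0.5 / 10 + 0.5 / 0.5
  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - mu), 3 * se)
})

test_that("bleaching truncates dwell times", {
  sites <- data.frame(site = 1L, x_nm = 0, y_nm = 0, k_d = 1, k_a = 50,
                      component = 1L)
  ev <- simulate_events(sites, duration = 100, seed = 9, bleach_rate = 4)
  # truncated mean is 1/(k_d + bleach) = 0.2
  se <- 0.2 / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$dwell_s) - 0.2), 4 * se)
})

test_that("an empty field renders as pure background", {
  im <- imaging_spec(n_frames = 20, width_px = 64, height_px = 64,
                     background = 10)
  ev <- data.frame(event = integer(0), site = integer(0),
                   x_nm = numeric(0), y_nm = numeric(0),
                   t_start_s = numeric(0), dwell_s = numeric(0))
  mov <- render_movie(ev, im, seed = 10)
  n <- length(mov)
  se <- sqrt((10 + im$read_noise^2) / n)
  expect_lt(abs(mean(mov) - 10), 3 * se)
  expect_true(is.integer(mov))
})

test_that("a noiseless rendered spot is centered on the truth", {
  im <- imaging_spec(n_frames = 1, width_px = 32, height_px = 32,
                     background = 0, photons_per_frame = 1e5)
  ev <- data.frame(event = 1L, site = 1L, x_nm = 1650, y_nm = 1550,
                   t_start_s = 0, dwell_s = 1)
  sig <- render_movie(ev, im, noise = FALSE)[, , 1]
  xc <- (col(sig) - 0.5) * 100
  yc <- (row(sig) - 0.5) * 100
  expect_lt(abs(sum(sig * xc) / sum(sig) - 1650), 1)
  expect_lt(abs(sum(sig * yc) / sum(sig) - 1550), 1)
})

test_that("expected signal is linear in photons per frame", {
  ev <- data.frame(event = 1L, site = 1L, x_nm = 1600, y_nm = 1600,
                   t_start_s = 0, dwell_s = 1)
  im1 <- imaging_spec(n_frames = 1, width_px = 32, height_px = 32,
                      background = 5, photons_per_frame = 1000)
  im2 <- imaging_spec(n_frames = 1, width_px = 32, height_px = 32,
                      background = 5, photons_per_frame = 2000)
  s1 <- render_movie(ev, im1, noise = FALSE) - 5
  s2 <- render_movie(ev, im2, noise = FALSE) - 5
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("temporal overlap and the axial sheet scale the signal", {
  im <- imaging_spec(n_frames = 2, width_px = 32, height_px = 32,
                     background = 0, photons_per_frame = 1000,
                     frame_interval_s = 0.032, sheet_fwhm_nm = 2300)
  # half of frame 1 only
  ev <- data.frame(event = 1L, site = 1L, x_nm = 1600, y_nm = 1600,
                   t_start_s = 0.016, dwell_s = 0.016)
  s <- render_movie(ev, im, noise = FALSE)
  expect_equal(sum(s[, , 1]), 500, tolerance = 0.01)
  expect_equal(sum(s[, , 2]), 0, tolerance = 1e-9)
  # one sheet-sigma off focus attenuates by exp(-1/2)
  ev$z_nm <- 2300 / (2 * sqrt(2 * log(2)))
  ev$t_start_s <- 0; ev$dwell_s <- 0.032
  s2 <- render_movie(ev, im, noise = FALSE)
  expect_equal(sum(s2[, , 1]), 1000 * exp(-0.5), tolerance = 0.01)
})

test_that("rendering is bit-exact for a fixed seed", {
  sites <- data.frame(site = 1:3, x_nm = c(800, 1600, 2400),
                      y_nm = c(800, 1600, 2400), k_d = 3, k_a = 2,
                      component = 1L)
  ev <- simulate_events(sites, duration = 0.5, seed = 11)
  im <- imaging_spec(n_frames = 15, width_px = 32, height_px = 32)
  m1 <- render_movie(ev, im, seed = 12)
  m2 <- render_movie(ev, im, seed = 12)
  expect_identical(m1, m2)
})

test_that("events outside the field of view are rejected", {
  im <- imaging_spec(n_frames = 1, width_px = 32, height_px = 32)
  ev <- data.frame(event = 1L, site = 1L, x_nm = 5000, y_nm = 100,
                   t_start_s = 0, dwell_s = 1)
  expect_error(render_movie(ev, im), "field of view")
})
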