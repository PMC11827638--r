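# closed-form exponentially-modified-Gaussian density, for moment oracles
demg <- function(t, mu, sigma, tau) {
  arg <- sigma^2 / (2 * tau^2) - (t - mu) / tau
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  (1 / (2 * tau)) * exp(arg) *
    erfc((sigma / tau - (t - mu) / sigma) / sqrt(2))
}

test_that("the empirical CF obeys its defining identities", {
  set.seed(51)
  d <- rexp(200, 5)
  om <- seq(-50, 50, length.out = 101)
  cf <- empirical_cf(d, om)
  expect_equal(cf$phi[om == 0], 1 + 0i)
  expect_true(all(Mod(cf$phi) <= 1 + 1e-12))
  # Hermitian symmetry
  expect_equal(cf$phi[om == -10], Conj(cf$phi[om == 10]))
  # single dwell: phi(w) = exp(i w t1)
  cf1 <- empirical_cf(0.25, om)
  expect_equal(cf1$phi, exp(1i * om * 0.25), tolerance = 1e-12)
  expect_error(empirical_cf(numeric(0), om), "empty")
})

test_that("the empirical CF converges to the exponential closed form", {
  set.seed(52)
  tau <- 0.1
  d <- rexp(1e5, 1 / tau)
  om <- seq(-100, 100, length.out = 201)
  cf <- empirical_cf(d, om)
  expect_lt(max(Mod(cf$phi - 1 / (1 - 1i * om * tau))), 0.02)
})

.trapz_mass <- function(prof, lo, hi) {
  sel <- prof$time_s >= lo & prof$time_s <= hi
  sum(prof$density[sel]) * prof$dt
}

test_that("n_bar = 0 gives a delta peak at the transit time", {
  prof <- elution_profile(0.1, n_bar = 0, t_M = 10, dt = 0.01,
                          n_grid = 4096)
  i_peak <- which.max(prof$density)
  expect_equal(prof$time_s[i_peak], 10, tolerance = 0.011)
  # all mass within one grid step of t_M
  mass_near <- .trapz_mass(prof, 10 - 0.011, 10 + 0.011)
  expect_gt(mass_near, 1 - 1e-6)
})

test_that("profile cumulants match the compound-Poisson closed form", {
  set.seed(53)
  d <- rexp(2e4, 10)  # tau = 0.1 s
  prof <- elution_profile(d, n_bar = 50, t_M = 10)
  mom <- peak_moments(prof)
  expect_equal(mom$area, 1, tolerance = 1e-6)
  expect_lt(abs(mom$center_s - (10 + 50 * mean(d))) /
              (10 + 50 * mean(d)), 0.01)
  expect_lt(abs(mom$variance_s2 - 50 * mean(d^2)) / (50 * mean(d^2)), 0.01)
  # sample moments sit near the population values (15 s, 1.0 s^2)
  expect_equal(mom$center_s, 15, tolerance = 0.1)
  expect_equal(mom$variance_s2, 1.0, tolerance = 0.05)
  expect_gt(mom$skew, 0)  # tailing
})

test_that("cumulant discretization error vanishes with grid refinement", {
  set.seed(54)
  d <- rexp(5000, 8)
  target <- 5 + 30 * mean(d)
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    prof <- elution_profile(d, n_bar = 30, t_M = 5, dt = dt)
    abs(peak_moments(prof)$center_s - target)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 1e-9)
  expect_lt(errs[3] / target, 1e-3)
})

test_that("the FFT profile matches direct Monte-Carlo sampling", {
  set.seed(55)
  d <- rexp(5000, 10)
  n_bar <- 50; t_M <- 10
  prof <- elution_profile(d, n_bar = n_bar, t_M = t_M)
  n_mc <- 1e5
  K <- rpois(n_mc, n_bar)
  draws <- sample(d, sum(K), replace = TRUE)
  grp <- rep.int(seq_len(n_mc), K)
  tot <- numeric(n_mc)
  sums <- tapply(draws, grp, sum)
  tot[as.integer(names(sums))] <- sums
  t_mc <- t_M + tot
  # KS distance between MC ECDF and the FFT profile CDF
  cdf_fft <- cumsum(prof$density) * prof$dt
  ecdf_at <- stats::ecdf(t_mc)(prof$time_s)
  expect_lt(max(abs(cdf_fft - ecdf_at)), 0.01)
})

test_that("profiles are nonnegative, unit-area, and alias-guarded", {
  set.seed(56)
  d <- rexp(2000, 5)
  prof <- elution_profile(d, n_bar = 20, t_M = 1)
  expect_true(all(prof$density >= 0))
  expect_equal(sum(prof$density) * prof$dt, 1, tolerance = 1e-3)
  expect_error(elution_profile(d, n_bar = 20, t_M = 1, n_grid = 1024,
                               dt = 0.008),
               "aliasing|grid")
})

test_that("the modeled centroid increases strictly with n_bar", {
  set.seed(57)
  d <- rexp(2000, 10)
  centers <- vapply(c(30, 60, 120), function(nb)
    peak_moments(elution_profile(d, n_bar = nb, t_M = 2))$center_s,
    numeric(1))
  expect_true(all(diff(centers) > 0))
})

test_that("peak moments reproduce Gaussian and EMG closed forms", {
  tt <- seq(0, 40, by = 0.005)
  g <- dnorm(tt, 20, 1.5)
  mg <- peak_moments(tt, g)
  expect_equal(mg$center_s, 20, tolerance = 1e-6)
  expect_equal(mg$variance_s2, 1.5^2, tolerance = 1e-4)
  expect_lt(abs(mg$skew), 1e-3)

  mu <- 10; sigma <- 0.8; tau <- 1.2
  y <- demg(tt, mu, sigma, tau)
  m <- peak_moments(tt, y)
  expect_lt(abs(m$center_s - (mu + tau)) / (mu + tau), 0.005)
  expect_lt(abs(m$variance_s2 - (sigma^2 + tau^2)) / (sigma^2 + tau^2),
            0.005)
  skew_true <- 2 * tau^3 / (sigma^2 + tau^2)^1.5
  expect_lt(abs(m$skew - skew_true) / skew_true, 0.005)
})

test_that("baseline subtraction and degenerate traces are handled", {
  tt <- seq(0, 10, by = 0.01)
  y <- dnorm(tt, 5, 0.5) + 0.2
  m <- peak_moments(tt, y, baseline = "linear")
  expect_equal(m$center_s, 5, tolerance = 1e-3)
  expect_error(peak_moments(tt, numeric(length(tt))), "area")
})

test_that("identical dwell sets give zero centroid shift", {
  set.seed(58)
  d <- rexp(2000, 5)
  cmp <- compare_conditions(d, d, n_bar = 50, t_M = 1)
  expect_equal(cmp$centroid_shift_s, 0, tolerance = 1e-9)
})

test_that("removing the long-dwell tail shifts elution earlier", {
  set.seed(59)
  d <- rexp(5000, 5)
  d_trim <- d[d <= quantile(d, 0.95)]
  cmp <- compare_conditions(d, d_trim, n_bar = 100, t_M = 0)
  expect_lt(cmp$centroid_shift_s, 0)
  expect_gt(cmp$moments_A$skew, 0)
  expect_gt(cmp$moments_B$skew, 0)
  # cumulant linearity: shift = n_bar * (mean(B) - mean(A))
  pred <- 100 * (mean(d_trim) - mean(d))
  expect_lt(abs(cmp$centroid_shift_s - pred) / abs(pred), 0.01)
})
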