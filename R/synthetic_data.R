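#' Particle geometry specification
#'
#' Describes the cross-section of a porous stationary-phase particle as an
#' ellipse with an accessible shell. The accessible region is the elliptical
#' annulus with normalized radius \eqn{\rho \in [1-f, 1]}: \code{f = 1} is a
#' fully porous particle (FPP), small \code{f} a superficially porous
#' particle (SPP) whose solid core excludes analytes.
#'
#' @param a,b Semi-axes of the particle cross-section in nm (\code{a >= b}).
#' @param center Numeric length-2, ellipse center (x, y) in nm.
#' @param tilt Rotation of the major axis, radians.
#' @param accessible_fraction Depth of the accessible shell as a fraction of
#'   the radius, in (0, 1].
#' @param site_density Adsorption sites per square micron of accessible area.
#' @return A \code{particle_spec} object (list).
#' @examples
#' # SPP-like geometry: 1.7-um solid core + 0.5-um porous shell
#' particle_spec(a = 1350, b = 1350, accessible_fraction = 0.5 / 1.35,
#'               site_density = 30)
#' @export
particle_spec <- function(a, b, center = c(0, 0), tilt = 0,
                          accessible_fraction = 1, site_density = 200) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!(a >= b && b > 0))
    stop("semi-axes must satisfy a >= b > 0")
  f <- accessible_fraction
  if (!(is.numeric(f) && length(f) == 1L && f > 0 && f <= 1))
    stop("accessible_fraction must lie in (0, 1]")
  if (site_density < 0) stop("site_density must be >= 0")
  structure(list(center = as.numeric(center), a = a, b = b, tilt = tilt,
                 accessible_fraction = f, site_density = site_density),
            class = "particle_spec")
}

#' Heterogeneous n-site kinetic mixture
#'
#' Individual adsorption sites have first-order kinetics; heterogeneity
#' between sites is modelled as a finite mixture of site classes, each with
#' its own desorption rate \code{k_d} (1/s) and per-site arrival rate
#' \code{k_a} (events/s).
#'
#' @param weights Mixture weights (normalized internally; must be positive).
#' @param k_d Desorption rates, 1/s, one per component.
#' @param k_a Arrival rates per site, 1/s, one per component.
#' @return A \code{kinetic_mixture} object.
#' @export
kinetic_mixture <- function(weights, k_d, k_a) {
  stopifnot(length(weights) == length(k_d), length(k_d) == length(k_a))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid mixture weights")
  if (any(k_d <= 0)) stop("all k_d must be > 0")
  if (any(k_a < 0)) stop("all k_a must be >= 0")
  structure(list(weights = weights / sum(weights),
                 k_d = as.numeric(k_d), k_a = as.numeric(k_a)),
            class = "kinetic_mixture")
}

#' Accessible cross-sectional area of a particle spec
#'
#' Area of the elliptical annulus \eqn{\rho \in [1-f, 1]}:
#' \eqn{\pi a b (1 - (1-f)^2)}.
#'
#' @param spec A \code{\link{particle_spec}}.
#' @return Area in square microns.
#' @export
accessible_shell_area <- function(spec) {
  f <- spec$accessible_fraction
  pi * spec$a * spec$b * (1 - (1 - f)^2) / 1e6
}

#' Generate a spatial map of adsorption sites
#'
#' Site count is Poisson with mean \code{site_density} times the accessible
#' area; positions are uniform over the accessible elliptical annulus; each
#' site's kinetic parameters are drawn i.i.d. from the mixture.
#'
#' @param spec A \code{\link{particle_spec}}.
#' @param mix A \code{\link{kinetic_mixture}}.
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{site, x_nm, y_nm, k_d, k_a,
#'   component} and attributes \code{spec} and \code{mix}.
#' @export
generate_site_map <- function(spec, mix, seed = NULL) {
  stopifnot(inherits(spec, "particle_spec"), inherits(mix, "kinetic_mixture"))
  area <- accessible_shell_area(spec)
  if (area <= 0) stop("zero accessible area")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, spec$site_density * area)
  f <- spec$accessible_fraction
  # uniform over the elliptical annulus: rho^2 ~ U((1-f)^2, 1)
  rho <- sqrt(stats::runif(n, (1 - f)^2, 1))
  theta <- stats::runif(n, 0, 2 * pi)
  xl <- spec$a * rho * cos(theta)
  yl <- spec$b * rho * sin(theta)
  ct <- cos(spec$tilt); st <- sin(spec$tilt)
  comp <- if (n > 0)
    sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  else integer(0)
  out <- data.frame(
    site = seq_len(n),
    x_nm = spec$center[1] + ct * xl - st * yl,
    y_nm = spec$center[2] + st * xl + ct * yl,
    k_d = mix$k_d[comp],
    k_a = mix$k_a[comp],
    component = comp)
  attr(out, "spec") <- spec
  attr(out, "mix") <- mix
  out
}

#' Deterministic calibration layout of adsorption sites
#'
#' A square grid of identical sites with guaranteed separation, for
#' calibration runs that isolate temporal kinetics from spot-overlap
#' effects: with spacing well beyond the PSF width, co-active neighbors
#' never merge optically, so recovered dwell statistics reflect the
#' linker and estimator alone.
#'
#' @param spacing_nm Grid spacing (use several PSF widths).
#' @param k_d,k_a First-order desorption and arrival rates shared by all
#'   sites.
#' @param field_nm Length-2 field of view (x, y), nm.
#' @param margin_nm Margin kept free at the field edges.
#' @return Site map data frame as from \code{\link{generate_site_map}}.
#' @export
grid_site_map <- function(spacing_nm = 800, k_d = 2, k_a = 0.04,
                          field_nm = c(12800, 12800), margin_nm = 1000) {
  xs <- seq(margin_nm, field_nm[1] - margin_nm, by = spacing_nm)
  ys <- seq(margin_nm, field_nm[2] - margin_nm, by = spacing_nm)
  g <- expand.grid(x_nm = xs, y_nm = ys)
  data.frame(site = seq_len(nrow(g)), x_nm = g$x_nm, y_nm = g$y_nm,
             k_d = k_d, k_a = k_a, component = 1L)
}

#' Simulate adsorption events at mapped sites
#'
#' Each site receives a homogeneous Poisson arrival process at its own rate
#' \code{k_a}; arrivals are non-blocking (overlapping events at one site are
#' allowed, appropriate for low nanomolar occupancy). Each event's dwell time
#' is exponential with mean \code{1/k_d}. An optional photobleaching rate
#' truncates dwells at an independent exponential bleaching time (default
#' off).
#'
#' @param sites Site map from \code{\link{generate_site_map}}.
#' @param duration Acquisition length in seconds.
#' @param seed Optional integer seed.
#' @param bleach_rate Bleaching rate in 1/s; 0 disables truncation.
#' @return Event table: \code{event, site, x_nm, y_nm, t_start_s, dwell_s}.
#' @export
simulate_events <- function(sites, duration, seed = NULL, bleach_rate = 0) {
  stopifnot(is.data.frame(sites), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n_ev <- stats::rpois(nrow(sites), sites$k_a * duration)
  idx <- rep.int(seq_len(nrow(sites)), n_ev)
  n <- length(idx)
  dwell <- if (n > 0) stats::rexp(n, rate = sites$k_d[idx]) else numeric(0)
  if (bleach_rate > 0 && n > 0)
    dwell <- pmin(dwell, stats::rexp(n, rate = bleach_rate))
  out <- data.frame(
    event = seq_len(n),
    site = sites$site[idx],
    x_nm = sites$x_nm[idx],
    y_nm = sites$y_nm[idx],
    t_start_s = if (n > 0) stats::runif(n, 0, duration) else numeric(0),
    dwell_s = dwell)
  out <- out[order(out$t_start_s), , drop = FALSE]
  out$event <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "duration") <- duration
  out
}

#' Camera and illumination specification
#'
#' Defaults follow a HILO light-sheet single-molecule setup: 32-ms frames,
#' 100-nm pixels, 130-nm PSF sigma, and a Gaussian axial sheet profile of
#' 2.3-um FWHM.
#'
#' @param n_frames Number of frames.
#' @param width_px,height_px Field of view in pixels.
#' @param pixel_size_nm Camera pixel size in sample space, nm.
#' @param frame_interval_s Frame interval, s.
#' @param psf_sigma_nm Gaussian PSF standard deviation, nm.
#' @param photons_per_frame Expected photons from one molecule fully active
#'   during a frame at the sheet center.
#' @param background Background level, photons/pixel/frame.
#' @param read_noise Camera read noise, electrons rms.
#' @param sheet_fwhm_nm Axial FWHM of the light sheet, nm.
#' @param sheet_center_z_nm Axial position of the sheet center, nm.
#' @return An \code{imaging_spec} object.
#' @export
imaging_spec <- function(n_frames, width_px = 128, height_px = 128,
                         pixel_size_nm = 100, frame_interval_s = 0.032,
                         psf_sigma_nm = 130, photons_per_frame = 2000,
                         background = 10, read_noise = 2,
                         sheet_fwhm_nm = 2300, sheet_center_z_nm = 0) {
  vals <- c(n_frames, width_px, height_px, pixel_size_nm, frame_interval_s,
            psf_sigma_nm, photons_per_frame, sheet_fwhm_nm)
  if (any(vals <= 0)) stop("imaging parameters must be positive")
  if (background < 0 || read_noise < 0)
    stop("background and read_noise must be >= 0")
  structure(list(n_frames = as.integer(n_frames),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 psf_sigma_nm = psf_sigma_nm,
                 photons_per_frame = photons_per_frame,
                 background = background, read_noise = read_noise,
                 sheet_fwhm_nm = sheet_fwhm_nm,
                 sheet_center_z_nm = sheet_center_z_nm),
            class = "imaging_spec")
}

# pixel-integrated Gaussian weights along one axis; edges in nm at
# 0, p, 2p, ... length n+1; returns per-pixel integral of N(mu, sigma)
.pixel_gauss <- function(n, p, mu, sigma, lo, hi) {
  j <- lo:hi
  stats::pnorm(j * p, mu, sigma) - stats::pnorm((j - 1) * p, mu, sigma)
}

#' Render a synthetic single-molecule movie
#'
#' Each adsorption event active during a frame contributes a pixel-integrated
#' symmetric 2D Gaussian spot. Expected photons are
#' \code{photons_per_frame * (fractional temporal overlap with the frame) *
#' (axial sheet weight)}, where the sheet weight is a Gaussian in z with the
#' spec's FWHM (events carry an optional \code{z_nm} column; absent, they sit
#' at the sheet center). Pixel values are Poisson(signal + background) plus
#' Gaussian read noise, rounded and clamped to a 16-bit range.
#'
#' The image x axis maps to columns and y to rows; pixel (row i, col j)
#' covers x in [(j-1)p, jp], y in [(i-1)p, ip] with p the pixel size.
#'
#' @param events Event table from \code{\link{simulate_events}}.
#' @param imaging An \code{\link{imaging_spec}}.
#' @param seed Optional integer seed.
#' @param noise If \code{FALSE}, return the noiseless expected signal
#'   (including background) as a double array.
#' @return Integer (or double, if \code{noise = FALSE}) array
#'   \code{[height_px, width_px, n_frames]}.
#' @export
render_movie <- function(events, imaging, seed = NULL, noise = TRUE) {
  stopifnot(inherits(imaging, "imaging_spec"))
  im <- imaging
  p <- im$pixel_size_nm
  if (nrow(events) > 0) {
    fov_x <- im$width_px * p; fov_y <- im$height_px * p
    if (any(events$x_nm < 0 | events$x_nm > fov_x |
            events$y_nm < 0 | events$y_nm > fov_y))
      stop("events outside the field of view")
  }
  if (!is.null(seed)) set.seed(seed)
  sig <- array(0, dim = c(im$height_px, im$width_px, im$n_frames))
  dt <- im$frame_interval_s
  sig_sd <- im$psf_sigma_nm
  half <- ceiling(4 * sig_sd / p) + 1L
  sheet_sd <- im$sheet_fwhm_nm / (2 * sqrt(2 * log(2)))
  z <- if ("z_nm" %in% names(events)) events$z_nm
       else rep(im$sheet_center_z_nm, nrow(events))
  wz <- exp(-(z - im$sheet_center_z_nm)^2 / (2 * sheet_sd^2))
  for (e in seq_len(nrow(events))) {
    t0 <- events$t_start_s[e]
    t1 <- t0 + events$dwell_s[e]
    f0 <- max(1L, floor(t0 / dt) + 1L)
    f1 <- min(im$n_frames, ceiling(t1 / dt))
    if (f1 < f0) next
    cx <- events$x_nm[e]; cy <- events$y_nm[e]
    jc <- ceiling(cx / p); ic <- ceiling(cy / p)
    jlo <- max(1L, jc - half); jhi <- min(im$width_px, jc + half)
    ilo <- max(1L, ic - half); ihi <- min(im$height_px, ic + half)
    if (jlo > jhi || ilo > ihi) next
    gx <- .pixel_gauss(im$width_px, p, cx, sig_sd, jlo, jhi)
    gy <- .pixel_gauss(im$height_px, p, cy, sig_sd, ilo, ihi)
    spot <- outer(gy, gx)
    for (fr in f0:f1) {
      overlap <- (min(t1, fr * dt) - max(t0, (fr - 1) * dt)) / dt
      if (overlap <= 0) next
      nph <- im$photons_per_frame * overlap * wz[e]
      sig[ilo:ihi, jlo:jhi, fr] <- sig[ilo:ihi, jlo:jhi, fr] + nph * spot
    }
  }
  sig <- sig + im$background
  if (!noise) return(sig)
  n <- length(sig)
  counts <- stats::rpois(n, sig)
  if (im$read_noise > 0)
    counts <- counts + round(stats::rnorm(n, 0, im$read_noise))
  counts <- pmax(0L, pmin(65535L, as.integer(counts)))
  array(counts, dim = dim(sig))
}
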