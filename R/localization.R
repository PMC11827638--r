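#' Detect candidate single-molecule spots in one frame
#'
#' Difference-of-Gaussians bandpass (sigmas matched to the PSF), then local
#' maxima above \code{median + k * robust noise SD}, with a minimum
#' separation between accepted maxima. The noise scale is the robust SD of
#' the fine residual level (frame minus its PSF-scale blur), the convention
#' of wavelet-style single-molecule detectors, which is insensitive to the
#' spots themselves.
#'
#' @param frame Numeric matrix (one movie frame, rows = y, cols = x).
#' @param psf_sigma_px PSF sigma in pixels (sets the bandpass scales).
#' @param k Threshold in robust noise SDs above the filtered-frame median.
#' @param min_sep Minimum separation between maxima, pixels.
#' @return Data frame \code{row, col, response} (possibly empty), pixel
#'   indices of candidate centers.
#' @export
detect_spots <- function(frame, psf_sigma_px = 1.3, k = 4, min_sep = 4) {
  stopifnot(is.matrix(frame))
  lo <- EBImage::gblur(frame, sigma = psf_sigma_px)
  f <- lo - EBImage::gblur(frame, sigma = 2 * psf_sigma_px)
  noise_sd <- stats::mad(frame - lo)
  thr <- stats::median(f) + k * noise_sd
  cand <- which(f > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      response = numeric(0)))
  # keep only local maxima over a (2*min_sep+1)^2 neighborhood, greedily
  v <- f[cand]
  ord <- order(v, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  v <- v[ord]
  keep <- logical(nrow(cand))
  kr <- integer(0); kc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (length(kr) == 0L || all((kr - r)^2 + (kc - c)^2 >= min_sep^2)) {
      keep[i] <- TRUE
      kr <- c(kr, r); kc <- c(kc, c)
    }
  }
  data.frame(row = as.integer(cand[keep, 1]),
             col = as.integer(cand[keep, 2]),
             response = v[keep])
}

#' Fit a symmetric 2D Gaussian to a spot ROI
#'
#' Least-squares fit of amplitude, center, sigma and constant offset on a
#' square ROI around a candidate pixel. Localization precision follows the
#' Thompson-style formula
#' \deqn{\sigma_{loc}^2 = (s^2 + p^2/12)/N + 8\pi s^4 b^2 / (p^2 N^2)}
#' with PSF sigma \eqn{s}, pixel size \eqn{p}, photons \eqn{N} and local
#' background \eqn{b} (photons/pixel). Fits are rejected when sigma falls
#' outside \code{sigma_window * psf_sigma} or photons drop below
#' \code{n_min}.
#'
#' @param frame Numeric matrix.
#' @param row,col Candidate center pixel (1-based).
#' @param pixel_size_nm Pixel size, nm.
#' @param psf_sigma_nm Nominal PSF sigma, nm (initial value and window
#'   anchor).
#' @param roi Half ROI edge is \code{(roi-1)/2}; default 7x7.
#' @param sigma_window Acceptance window on fitted sigma as multiples of
#'   \code{psf_sigma_nm}.
#' @param n_min Minimum accepted photon count.
#' @return One-row data frame \code{x_nm, y_nm, photons, sigma_nm,
#'   background, precision_nm, ok, reason}; \code{ok} is FALSE with a reason
#'   code (\code{"border"}, \code{"nonconvergence"}, \code{"sigma"},
#'   \code{"photons"}) for rejected fits.
#' @export
fit_spot <- function(frame, row, col, pixel_size_nm = 100,
                     psf_sigma_nm = 130, roi = 7,
                     sigma_window = c(0.5, 2), n_min = 100) {
  h <- (roi - 1L) %/% 2L
  rej <- function(reason) data.frame(
    x_nm = NA_real_, y_nm = NA_real_, photons = NA_real_,
    sigma_nm = NA_real_, background = NA_real_, precision_nm = NA_real_,
    ok = FALSE, reason = reason)
  if (row - h < 1L || row + h > nrow(frame) ||
      col - h < 1L || col + h > ncol(frame)) return(rej("border"))
  z <- frame[(row - h):(row + h), (col - h):(col + h)]
  p <- pixel_size_nm
  # pixel-center coordinates in nm, global frame
  xs <- ((col - h):(col + h) - 0.5) * p
  ys <- ((row - h):(row + h) - 0.5) * p
  X <- matrix(xs, roi, roi, byrow = TRUE)
  Y <- matrix(ys, roi, roi)
  b0 <- min(z); a0 <- max(z) - b0
  start <- c(A = max(a0, 1), x0 = (col - 0.5) * p, y0 = (row - 0.5) * p,
             s = psf_sigma_nm, b = b0)
  res_fun <- function(par) {
    m <- par["A"] * exp(-((X - par["x0"])^2 + (Y - par["y0"])^2) /
                          (2 * par["s"]^2)) + par["b"]
    as.numeric(m - z)
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = res_fun,
                         lower = c(0, xs[1] - p, ys[1] - p, 0.1 * p, -Inf),
                         upper = c(Inf, xs[roi] + p, ys[roi] + p, 5 * p, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(rej("nonconvergence"))
  par <- fit$par
  s <- par[["s"]]
  N <- 2 * pi * par[["A"]] * (s / p)^2  # photons: integral of the Gaussian
  if (s < sigma_window[1] * psf_sigma_nm || s > sigma_window[2] * psf_sigma_nm)
    return(rej("sigma"))
  if (!is.finite(N) || N < n_min) return(rej("photons"))
  b <- max(par[["b"]], 0)
  prec <- sqrt((s^2 + p^2 / 12) / N + 8 * pi * s^4 * b^2 / (p^2 * N^2))
  data.frame(x_nm = par[["x0"]], y_nm = par[["y0"]], photons = N,
             sigma_nm = s, background = b, precision_nm = prec,
             ok = TRUE, reason = "ok")
}

#' Localize all spots in a movie
#'
#' Runs \code{\link{detect_spots}} and \code{\link{fit_spot}} on every frame
#' and collects accepted localizations.
#'
#' @param movie Array \code{[rows, cols, frames]}.
#' @param imaging An \code{\link{imaging_spec}} (pixel size, PSF sigma).
#' @param k Detection threshold in robust SDs.
#' @param min_sep Minimum spot separation, pixels.
#' @param roi ROI edge for fitting, pixels.
#' @param sigma_window,n_min Fit acceptance windows (see
#'   \code{\link{fit_spot}}).
#' @return Localization table: \code{frame, x_nm, y_nm, photons, sigma_nm,
#'   background, precision_nm} (ThunderSTORM-style column ordering).
#' @export
localize_movie <- function(movie, imaging, k = 4, min_sep = 4, roi = 7,
                           sigma_window = c(0.5, 2), n_min = 100) {
  stopifnot(length(dim(movie)) == 3L, inherits(imaging, "imaging_spec"))
  p <- imaging$pixel_size_nm
  spx <- imaging$psf_sigma_nm / p
  out <- vector("list", dim(movie)[3])
  for (fr in seq_len(dim(movie)[3])) {
    frame <- movie[, , fr]
    storage.mode(frame) <- "double"
    cand <- detect_spots(frame, psf_sigma_px = spx, k = k, min_sep = min_sep)
    if (nrow(cand) == 0L) next
    fits <- lapply(seq_len(nrow(cand)), function(i)
      fit_spot(frame, cand$row[i], cand$col[i], pixel_size_nm = p,
               psf_sigma_nm = imaging$psf_sigma_nm, roi = roi,
               sigma_window = sigma_window, n_min = n_min))
    fits <- do.call(rbind, fits)
    fits <- fits[fits$ok, , drop = FALSE]
    if (nrow(fits) > 0L) {
      fits$frame <- fr
      out[[fr]] <- fits
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), photons = numeric(0),
                      sigma_nm = numeric(0), background = numeric(0),
                      precision_nm = numeric(0))
  rownames(out) <- NULL
  out[, c("frame", "x_nm", "y_nm", "photons", "sigma_nm", "background",
          "precision_nm")]
}

#' Reconstruct a super-resolution map from localizations
#'
#' 2D histogram of localization positions at a map pixel much smaller than
#' the camera pixel (default 30 nm, the lateral resolution scale).
#'
#' @param locs Localization table with \code{x_nm, y_nm}.
#' @param map_pixel_nm Map pixel size, nm.
#' @param origin_nm Length-2 lower-left corner of the map, nm; defaults to
#'   the floor of the data range.
#' @param width_nm,height_nm Optional map extent, nm.
#' @return An \code{srmap}: list with \code{counts} (integer matrix, rows =
#'   y), \code{pixel_nm}, \code{origin_nm}.
#' @export
reconstruct_map <- function(locs, map_pixel_nm = 30, origin_nm = NULL,
                            width_nm = NULL, height_nm = NULL) {
  if (nrow(locs) == 0L) stop("no localizations to reconstruct")
  if (is.null(origin_nm))
    origin_nm <- c(floor(min(locs$x_nm) / map_pixel_nm),
                   floor(min(locs$y_nm) / map_pixel_nm)) * map_pixel_nm
  if (is.null(width_nm)) width_nm <- max(locs$x_nm) - origin_nm[1] + map_pixel_nm
  if (is.null(height_nm)) height_nm <- max(locs$y_nm) - origin_nm[2] + map_pixel_nm
  nx <- ceiling(width_nm / map_pixel_nm)
  ny <- ceiling(height_nm / map_pixel_nm)
  jx <- floor((locs$x_nm - origin_nm[1]) / map_pixel_nm) + 1
  jy <- floor((locs$y_nm - origin_nm[2]) / map_pixel_nm) + 1
  ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
  counts <- matrix(0L, ny, nx)
  tab <- table(factor(jy[ok], levels = 1:ny), factor(jx[ok], levels = 1:nx))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, pixel_nm = map_pixel_nm,
                 origin_nm = as.numeric(origin_nm)),
            class = "srmap")
}
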