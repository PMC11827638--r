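#' Fit an elliptical particle outline to a super-resolution map
#'
#' Binarizes the map (any localization marks a pixel), applies morphological
#' closing with a disc, keeps the largest connected component, fills holes,
#' and fits an ellipse through second-order image moments of the filled
#' component. The closing bridges gaps between discrete adsorption sites so
#' the outline tracks the outer particle boundary even when the interior is
#' inaccessible.
#'
#' @param srmap An \code{srmap} from \code{\link{reconstruct_map}}.
#' @param min_localizations Minimum localizations required in the map.
#' @param closing_radius Disc radius for morphological closing, map pixels.
#' @return A \code{particle_outline}: list with \code{center_nm},
#'   \code{a_nm}, \code{b_nm} (semi-axes, \code{a >= b}), \code{tilt_rad},
#'   \code{Ai_um2} (\eqn{\pi a b}), \code{r_nm} (\eqn{(a+b)/2}).
#' @export
fit_outline <- function(srmap, min_localizations = 500, closing_radius = 5) {
  stopifnot(inherits(srmap, "srmap"))
  if (sum(srmap$counts) < min_localizations)
    stop("too few localizations to fit an outline (need ",
         min_localizations, ")")
  mask <- .closed_mask(srmap, closing_radius)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) < 1) stop("no connected component found")
  sizes <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(sizes))
  comp <- EBImage::fillHull(comp)
  m <- as.matrix(comp) > 0
  idx <- which(m, arr.ind = TRUE)
  py <- idx[, 1] - 0.5
  px <- idx[, 2] - 0.5
  # moments of the component's convex hull: a particle cross-section is
  # convex, and the hull (unlike hole filling) also recovers the outer
  # boundary when the accessible shell is a broken ring around a solid core
  hull <- grDevices::chull(px, py)
  pm <- .polygon_moments(px[hull], py[hull])
  cx <- pm$cx; cy <- pm$cy
  eg <- eigen(pm$cov, symmetric = TRUE)
  a_px <- 2 * sqrt(max(eg$values[1], 0))
  b_px <- 2 * sqrt(max(eg$values[2], 0))
  tilt <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  if (tilt < -pi / 2) tilt <- tilt + pi
  if (tilt > pi / 2) tilt <- tilt - pi
  s <- srmap$pixel_nm
  a <- a_px * s; b <- b_px * s
  if (b <= 0) stop("degenerate outline (zero minor axis)")
  structure(list(
    center_nm = c(srmap$origin_nm[1] + cx * s, srmap$origin_nm[2] + cy * s),
    a_nm = a, b_nm = b, tilt_rad = tilt,
    Ai_um2 = pi * a * b / 1e6, r_nm = (a + b) / 2),
    class = "particle_outline")
}

# area, centroid and covariance of a simple polygon (Green's theorem)
.polygon_moments <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Exx <- sum((x^2 + x * x2 + x2^2) * cr) / (12 * A)
  Eyy <- sum((y^2 + y * y2 + y2^2) * cr) / (12 * A)
  Exy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / (24 * A)
  list(area = abs(A), cx = cx, cy = cy,
       cov = matrix(c(Exx - cx^2, Exy - cx * cy,
                      Exy - cx * cy, Eyy - cy^2), 2, 2))
}

.closed_mask <- function(srmap, closing_radius) {
  mask <- EBImage::Image(srmap$counts >= 1)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  mask
}

# normalized elliptical radius of points w.r.t. an outline
.ellipse_rho <- function(x, y, outline) {
  dx <- x - outline$center_nm[1]
  dy <- y - outline$center_nm[2]
  ct <- cos(outline$tilt_rad); st <- sin(outline$tilt_rad)
  xp <- ct * dx + st * dy
  yp <- -st * dx + ct * dy
  sqrt((xp / outline$a_nm)^2 + (yp / outline$b_nm)^2)
}

#' Depth-from-edge distribution of localizations
#'
#' For each localization, the normalized elliptical radius \eqn{\rho} is
#' computed in the outline's rotated frame and the depth from the outer edge
#' is \eqn{(1 - \min(\rho, 1)) \times 100} in \%r. Localizations with
#' \eqn{\rho > 1 + tol} (localization noise outside the contour) are
#' excluded and counted. \code{d99}, the accessible-depth limit, is the 99th
#' percentile of the depth distribution with linear interpolation — the
#' depth beyond which 99\% of analytes do not reach.
#'
#' @param locs Localization table with \code{x_nm, y_nm}.
#' @param outline A \code{particle_outline}.
#' @param tol Exclusion tolerance on \eqn{\rho} beyond 1 (default 5\%).
#' @param cdf_grid Depth grid (\%r) on which the binned CDF is evaluated.
#' @return A \code{depth_distribution}: list with \code{depths_percent_r},
#'   \code{d99_percent_r}, \code{n}, \code{n_excluded}, \code{cdf_grid},
#'   \code{cdf} (empirical CDF on the grid).
#' @export
compute_depths <- function(locs, outline, tol = 0.05,
                           cdf_grid = seq(0, 100, by = 0.5)) {
  stopifnot(inherits(outline, "particle_outline"))
  if (nrow(locs) == 0L) stop("no localizations")
  rho <- .ellipse_rho(locs$x_nm, locs$y_nm, outline)
  excl <- rho > 1 + tol
  rho <- rho[!excl]
  if (length(rho) == 0L) stop("all localizations outside the outline")
  depth <- (1 - pmin(rho, 1)) * 100
  d99 <- unname(stats::quantile(depth, 0.99, type = 7))
  ec <- stats::ecdf(depth)
  structure(list(depths_percent_r = depth, d99_percent_r = d99,
                 n = length(depth), n_excluded = sum(excl),
                 cdf_grid = cdf_grid, cdf = ec(cdf_grid)),
            class = "depth_distribution")
}

#' Accessible area and accessible-area ratio
#'
#' \eqn{A_p} is the area of map pixels covered by localizations (after the
#' same morphological closing used for the outline) whose centers lie inside
#' the fitted ellipse; the ratio \eqn{A_p/A_i} compares the area probed by
#' analytes with the imaged cross-sectional area.
#'
#' @param srmap An \code{srmap}.
#' @param outline A \code{particle_outline}.
#' @param closing_radius Disc radius for closing, map pixels (match
#'   \code{\link{fit_outline}}).
#' @return List with \code{Ap_um2}, \code{Ai_um2}, \code{ratio}.
#' @export
accessible_area <- function(srmap, outline, closing_radius = 5) {
  stopifnot(inherits(srmap, "srmap"), inherits(outline, "particle_outline"))
  mask <- as.matrix(.closed_mask(srmap, closing_radius)) > 0
  s <- srmap$pixel_nm
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(Ap_um2 = 0, Ai_um2 = outline$Ai_um2, ratio = 0))
  x <- srmap$origin_nm[1] + (idx[, 2] - 0.5) * s
  y <- srmap$origin_nm[2] + (idx[, 1] - 0.5) * s
  inside <- .ellipse_rho(x, y, outline) <= 1
  Ap <- min(sum(inside) * s^2 / 1e6, outline$Ai_um2)
  list(Ap_um2 = Ap, Ai_um2 = outline$Ai_um2, ratio = Ap / outline$Ai_um2)
}

#' Aggregate accessibility metrics over particles
#'
#' Per-depth-bin mean and SD of the cumulative distributions, and mean and
#' sample SD of \code{d99} and \code{A_p/A_i}, across two or more particles.
#'
#' @param depth_dists List of \code{depth_distribution} objects on a common
#'   grid.
#' @param ratios Optional numeric vector of accessible-area ratios, one per
#'   particle.
#' @return List with \code{cdf_grid}, \code{cdf_mean}, \code{cdf_sd},
#'   \code{d99_mean}, \code{d99_sd}, and (when ratios are given)
#'   \code{ratio_mean}, \code{ratio_sd}.
#' @export
aggregate_particles <- function(depth_dists, ratios = NULL) {
  if (length(depth_dists) < 2L) stop("need at least two particles")
  grids <- lapply(depth_dists, `[[`, "cdf_grid")
  if (!all(vapply(grids[-1], function(g) identical(g, grids[[1]]), logical(1))))
    stop("mismatched CDF bin grids across particles")
  cdfs <- do.call(rbind, lapply(depth_dists, `[[`, "cdf"))
  d99 <- vapply(depth_dists, `[[`, numeric(1), "d99_percent_r")
  out <- list(cdf_grid = grids[[1]],
              cdf_mean = colMeans(cdfs),
              cdf_sd = apply(cdfs, 2, stats::sd),
              d99_mean = mean(d99), d99_sd = stats::sd(d99))
  if (!is.null(ratios)) {
    out$ratio_mean <- mean(ratios)
    out$ratio_sd <- stats::sd(ratios)
  }
  out
}

#' Closed-form accessible-depth limits for idealized geometries
#'
#' For analytes uniform over a full disc, the depth CDF is
#' \eqn{F(u) = 1 - (1-u)^2} (depth \eqn{u} as a fraction of \eqn{r}), so the
#' 99th-percentile depth is \eqn{100(1 - \sqrt{0.01}) = 90} \%r. For a
#' uniform annulus of shell fraction \eqn{f},
#' \eqn{F(u) = [1-(1-u)^2] / [1-(1-f)^2]} on \eqn{[0, f]}, giving
#' \eqn{d_{99} = 100 (1 - \sqrt{1 - 0.99\,(1-(1-f)^2)})}.
#'
#' @param f Shell depth as a fraction of the radius, in (0, 1].
#' @param q Quantile (default 0.99).
#' @return Depth limit in \%r.
#' @export
d99_annulus <- function(f, q = 0.99) {
  stopifnot(all(f > 0 & f <= 1))
  100 * (1 - sqrt(1 - q * (1 - (1 - f)^2)))
}

#' @rdname d99_annulus
#' @export
d99_disc <- function(q = 0.99) d99_annulus(1, q)

#' Expected accessible-area ratio of a uniform annulus
#'
#' At dense uniform sampling of a shell of fractional depth \eqn{f},
#' \eqn{A_p/A_i \to 1 - (1-f)^2}.
#'
#' @param f Shell depth fraction in (0, 1].
#' @return Expected \eqn{A_p/A_i}.
#' @export
annulus_area_ratio <- function(f) {
  stopifnot(all(f > 0 & f <= 1))
  1 - (1 - f)^2
}
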