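#' Link localizations across frames into adsorption events
#'
#' Greedy nearest-neighbor linking: a localization continues an active track
#' when it lies within \code{r_link} of the track's last position and at
#' most \code{max_gap} frames have been missed (single-frame blinks are
#' tolerated by the default gap of 1). The dwell time of an n-frame event is
#' \code{n * frame_interval}; events touching the first or last movie frame
#' are flagged censored, since their true start or end was not observed.
#'
#' @param locs Localization table sorted by frame (\code{frame, x_nm,
#'   y_nm}).
#' @param r_link Linking radius, nm.
#' @param max_gap Maximum missed frames inside one event.
#' @param frame_interval_s Frame interval, s.
#' @param n_frames Total frames in the movie (for end-censoring); defaults
#'   to \code{max(locs$frame)}.
#' @return Event table: \code{start_frame, n_frames, dwell_s, x_nm, y_nm,
#'   censored, n_loc, n_gap}. \code{n_frames} spans first to last linked
#'   frame inclusive (\code{n_loc} localizations plus \code{n_gap} gap
#'   fills).
#' @export
link_events <- function(locs, r_link = 100, max_gap = 1,
                        frame_interval_s = 0.032, n_frames = NULL) {
  if (nrow(locs) == 0L)
    return(data.frame(start_frame = integer(0), n_frames = integer(0),
                      dwell_s = numeric(0), x_nm = numeric(0),
                      y_nm = numeric(0), censored = logical(0),
                      n_loc = integer(0), n_gap = integer(0)))
  if (is.unsorted(locs$frame)) locs <- locs[order(locs$frame), ]
  if (is.null(n_frames)) n_frames <- max(locs$frame)
  n <- nrow(locs)
  track <- integer(n)        # track id per localization
  # active tracks: id, last index, last frame
  act_id <- integer(0); act_last <- integer(0); act_frame <- integer(0)
  next_id <- 1L
  frames <- unique(locs$frame)
  by_frame <- split(seq_len(n), locs$frame)
  for (fr in frames) {
    alive <- act_frame >= fr - max_gap - 1L
    act_id <- act_id[alive]; act_last <- act_last[alive]
    act_frame <- act_frame[alive]
    idx <- by_frame[[as.character(fr)]]
    taken <- logical(length(idx))
    # tracks claim their nearest unassigned localization, closest pairs first
    if (length(act_id) > 0L && length(idx) > 0L) {
      dx <- outer(locs$x_nm[act_last], locs$x_nm[idx], "-")
      dy <- outer(locs$y_nm[act_last], locs$y_nm[idx], "-")
      d <- sqrt(dx^2 + dy^2)
      d[d > r_link] <- NA
      repeat {
        if (all(is.na(d))) break
        best <- arrayInd(which.min(d), dim(d))
        ti <- best[1]; li <- best[2]
        track[idx[li]] <- act_id[ti]
        act_last[ti] <- idx[li]; act_frame[ti] <- fr
        taken[li] <- TRUE
        d[ti, ] <- NA; d[, li] <- NA
      }
    }
    for (li in which(!taken)) {
      track[idx[li]] <- next_id
      act_id <- c(act_id, next_id)
      act_last <- c(act_last, idx[li]); act_frame <- c(act_frame, fr)
      next_id <- next_id + 1L
    }
  }
  sp <- split(seq_len(n), track)
  ev <- lapply(sp, function(ii) {
    fr <- locs$frame[ii]
    f0 <- min(fr); f1 <- max(fr)
    nf <- f1 - f0 + 1L
    data.frame(start_frame = f0, n_frames = nf,
               dwell_s = nf * frame_interval_s,
               x_nm = mean(locs$x_nm[ii]), y_nm = mean(locs$y_nm[ii]),
               censored = (f0 == 1L) || (f1 == n_frames),
               n_loc = length(ii), n_gap = nf - length(ii))
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$start_frame), ]
  rownames(ev) <- NULL
  ev
}

#' Cumulative dwell-time distribution
#'
#' Empirical CDF over event dwell times; censored events (whose dwell is a
#' lower bound, not a measurement) are excluded by default.
#'
#' @param events Event table from \code{\link{link_events}}.
#' @param exclude_censored Drop censored events (default TRUE).
#' @return List with \code{dwells_s} (sorted), \code{cdf} (an
#'   \code{\link[stats]{ecdf}}), \code{n}, \code{n_censored}.
#' @export
dwell_distribution <- function(events, exclude_censored = TRUE) {
  d <- events$dwell_s
  nc <- sum(events$censored)
  if (exclude_censored) d <- d[!events$censored]
  if (length(d) == 0L) stop("no uncensored dwell times")
  list(dwells_s = sort(d), cdf = stats::ecdf(d), n = length(d),
       n_censored = nc)
}

#' Desorption rate from observed dwell times
#'
#' The inverse mean dwell, \code{k_d = 1/mean(t_D)}. Frame-quantized dwells
#' (\code{n} frames recorded as \code{n * dt}) overestimate the true
#' sojourn by one frame interval on average, since an event touching
#' \code{n} frames lasted between \code{(n-2) dt} and \code{n dt};
#' supplying \code{frame_interval} subtracts that offset so the rate is
#' unbiased for dwells down to a few frames. With the default
#' \code{frame_interval = 0} this is the plain reciprocal-mean-dwell
#' convention.
#'
#' @param dwells Observed dwell times, s.
#' @param frame_interval Frame interval used to quantize the dwells, s; 0
#'   disables the offset correction.
#' @return Desorption rate, 1/s.
#' @export
estimate_kd <- function(dwells, frame_interval = 0) {
  if (length(dwells) == 0L) stop("no dwell times")
  m <- mean(dwells) - frame_interval
  if (m <= 0) stop("mean dwell does not exceed the discretization offset")
  1 / m
}

#' Cluster adsorption events into sites
#'
#' Single-linkage clustering of event positions with a distance threshold:
#' events within \code{site_radius} of any event in a cluster share a site.
#' Per site, the desorption rate is \code{k_d = 1/(mean uncensored dwell)}
#' (optionally discretization-corrected, see \code{\link{estimate_kd}}) and
#' the arrival rate \code{k_a = events / duration}.
#'
#' @param events Event table.
#' @param site_radius Clustering distance threshold, nm (default 60, about
#'   twice the super-resolution map pixel).
#' @param duration Acquisition length, s.
#' @param frame_interval_s Discretization offset passed to
#'   \code{\link{estimate_kd}} (default 0: plain reciprocal mean dwell).
#' @return Site table: \code{site, x_nm, y_nm, n_events, mean_dwell_s,
#'   kd_per_s, ka_per_s} plus a \code{site} column added to a copy of the
#'   events, returned as attribute \code{"events"}.
#' @export
cluster_sites <- function(events, site_radius = 60, duration,
                          frame_interval_s = 0) {
  if (nrow(events) == 0L) stop("no events to cluster")
  stopifnot(duration > 0)
  if (nrow(events) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(events[, c("x_nm", "y_nm")]),
                        method = "single")
    cl <- stats::cutree(hc, h = site_radius)
  }
  ev <- events
  ev$site <- cl
  agg <- lapply(split(seq_len(nrow(ev)), cl), function(ii) {
    unc <- ii[!ev$censored[ii]]
    md <- if (length(unc) > 0) mean(ev$dwell_s[unc]) else NA_real_
    kd <- if (is.na(md) || md - frame_interval_s <= 0) NA_real_
          else 1 / (md - frame_interval_s)
    data.frame(x_nm = mean(ev$x_nm[ii]), y_nm = mean(ev$y_nm[ii]),
               n_events = length(ii), mean_dwell_s = md,
               kd_per_s = kd, ka_per_s = length(ii) / duration)
  })
  sites <- do.call(rbind, agg)
  sites <- cbind(site = as.integer(names(agg)), sites)
  rownames(sites) <- NULL
  attr(sites, "events") <- ev
  sites
}

#' Per-site adsorption free energy
#'
#' Pseudo-first-order equilibrium constant
#' \eqn{K_{eq} = k_a / (k_d \cdot C/C^\circ)} with reference concentration
#' \eqn{C^\circ = 1} M, giving \eqn{\Delta G = -RT \ln K_{eq}} in kJ/mol.
#' This convention treats the observed arrival rate as proportional to the
#' analyte concentration; it is reported alongside results since free-energy
#' scales depend on the chosen reference state.
#'
#' @param sites Site table from \code{\link{cluster_sites}} (or any frame
#'   with \code{kd_per_s, ka_per_s}).
#' @param concentration Analyte concentration, mol/L (default 1 nM).
#' @param temperature Kelvin (default 298.15).
#' @return The site table with a \code{dG_kJ_mol} column appended.
#' @export
site_energetics <- function(sites, concentration = 1e-9,
                            temperature = 298.15) {
  stopifnot(concentration > 0, temperature > 0)
  R <- 8.314462618e-3  # kJ/(mol K)
  Keq <- sites$ka_per_s / (sites$kd_per_s * concentration / 1)
  sites$dG_kJ_mol <- -R * temperature * log(Keq)
  sites
}
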