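# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# Full imaging pipeline on a shell particle with accessible fraction f.
pipeline_fixture <- function(f) {
  fixture(paste0("pipeline_f", f), function() {
    run_pipeline(
      list(seed = 101L, particle = list(accessible_fraction = f)),
      outdir = file.path(tempdir(), paste0("pipe_f", f)))
  })
}

# Single-exponential calibration movie for kinetics recovery: k_d = 2/s
# (mean dwell 0.5 s, about 16 frames) on a grid of well-separated sites,
# so co-active spots never merge optically and the per-site arrival rate
# keeps same-site temporal overlap rare.
kinetics_fixture <- function(seed = 202L) {
  fixture(paste0("kinetics_movie_", seed), function() {
    sites <- grid_site_map(spacing_nm = 800, k_d = 2, k_a = 0.04)
    im <- imaging_spec(n_frames = 2400)
    set.seed(seed)
    events_truth <- simulate_events(sites, duration = 2400 * 0.032)
    movie <- render_movie(events_truth, im, seed = seed + 1L)
    locs <- localize_movie(movie, im)
    events <- link_events(locs, frame_interval_s = 0.032, n_frames = 2400)
    list(sites = sites, events_truth = events_truth,
         localizations = locs, events = events, imaging = im)
  })
}

# Uniform points over an elliptical annulus (rho in [1-f, 1]), in nm.
sample_annulus <- function(n, f = 1, a = 2500, b = a,
                           center = c(6400, 6400), tilt = 0) {
  rho <- sqrt(stats::runif(n, (1 - f)^2, 1))
  th <- stats::runif(n, 0, 2 * pi)
  xl <- a * rho * cos(th); yl <- b * rho * sin(th)
  data.frame(x_nm = center[1] + cos(tilt) * xl - sin(tilt) * yl,
             y_nm = center[2] + sin(tilt) * xl + cos(tilt) * yl)
}

# An exact outline object (bypasses fitting) for closed-form depth oracles.
exact_outline <- function(a = 2500, b = a, center = c(6400, 6400),
                          tilt = 0) {
  structure(list(center_nm = center, a_nm = a, b_nm = b, tilt_rad = tilt,
                 Ai_um2 = pi * a * b / 1e6, r_nm = (a + b) / 2),
            class = "particle_outline")
}

# CDF of frame-quantized dwells: an event with true dwell t starting at a
# uniform phase touches N = 1 + floor((u + t)/dt) frames, so
# P(N*dt <= m*dt) = 1 - sum_i w_i exp(-k_i m dt) (exp(k_i dt) - 1)/(k_i dt).
discretized_mixture_cdf <- function(m_dt, weights, k_d, dt) {
  sapply(m_dt, function(x) {
    m <- round(x / dt)
    1 - sum(weights * exp(-k_d * m * dt) * (exp(k_d * dt) - 1) / (k_d * dt))
  })
}

# Greedy matching of localizations to ground-truth event positions active
# in the same frame; returns recall and precision at the given radius.
match_to_truth <- function(locs, events_truth, imaging, radius = 150,
                           min_overlap = 0.5) {
  dt <- imaging$frame_interval_s
  tp <- 0
  truth_frames <- 0
  n_loc_true <- 0
  for (fr in seq_len(imaging$n_frames)) {
    t0 <- (fr - 1) * dt; t1 <- fr * dt
    ov <- (pmin(events_truth$t_start_s + events_truth$dwell_s, t1) -
             pmax(events_truth$t_start_s, t0)) / dt
    act <- which(ov >= min_overlap)
    truth_frames <- truth_frames + length(act)
    li <- which(locs$frame == fr)
    # recall: majority-overlap truth spots claimed by a localization
    if (length(act) > 0L && length(li) > 0L) {
      d <- sqrt(outer(events_truth$x_nm[act], locs$x_nm[li], "-")^2 +
                  outer(events_truth$y_nm[act], locs$y_nm[li], "-")^2)
      d[d > radius] <- NA
      while (!all(is.na(d))) {
        best <- arrayInd(which.min(d), dim(d))
        tp <- tp + 1
        d[best[1], ] <- NA; d[, best[2]] <- NA
      }
    }
    # precision: localizations near any truth spot active at all
    any_act <- which(ov > 0.02)
    if (length(li) > 0L && length(any_act) > 0L) {
      d2 <- sqrt(outer(locs$x_nm[li], events_truth$x_nm[any_act], "-")^2 +
                   outer(locs$y_nm[li], events_truth$y_nm[any_act], "-")^2)
      n_loc_true <- n_loc_true + sum(apply(d2, 1, min) <= radius)
    }
  }
  list(recall = tp / truth_frames,
       precision = n_loc_true / nrow(locs))
}
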