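# Synthetic axonal-transport time-lapse movies: stationary puncta persisting
# for the whole recording (a stated fraction on synapse-marker puncta,
# rendered in separate pre/post marker frames) plus run-and-pause moving
# particles entering as a Poisson process.

#' Generate a synthetic axonal time-lapse movie with ground truth
#'
#' The axon is a straight horizontal line imaged over
#' `duration / frame_interval` frames. Moving particles enter from either
#' axon end as a Poisson process at `entry_rate` (per 100 um per min) and
#' alternate constant-speed runs (exponential run lengths at `pause_rate`)
#' with exponential pauses; stationary puncta are fixed for the whole movie.
#' Synapse-marker (SV2A-like) still frames are rendered before and after the
#' movie with independent noise, including transient distractor puncta
#' present in only one of the two frames.
#'
#' @param params a [motility_params()] object.
#' @return list with `movie` (class `timelapse`: `frames` list of matrices,
#'   `frame_interval` s, `pixel_size` nm, `sv2a_pre`/`sv2a_post` matrices,
#'   `path` 2-column matrix of 0-based pixel coordinates along the axon,
#'   `axon_length` um) and `truth` (class `ground_truth`: `events` list of
#'   [track_event()]s, `stationary` data.frame, realized counts).
#' @export
gen_timelapse <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  withr::with_seed(params$seed, .gen_timelapse_impl(params))
}

.gen_timelapse_impl <- function(p) {
  dt <- p$frame_interval
  n_frames <- as.integer(round(p$duration / dt))
  times <- (seq_len(n_frames) - 1L) * dt
  L <- p$axon_length
  ps_um <- p$pixel_size / 1000
  width_px <- as.integer(round(L / ps_um))
  height_px <- 9L
  y0 <- 4L                               # 0-based axon row
  sig_px <- p$psf_sigma / p$pixel_size

  # stationary puncta, mutually separated so they are resolvable
  stat_x <- numeric(0)
  if (p$n_stationary > 0) {
    while (length(stat_x) < p$n_stationary) {
      cand <- stats::runif(1, 1, L - 1)
      if (!length(stat_x) || min(abs(stat_x - cand)) > 1.5) {
        stat_x <- c(stat_x, cand)
      }
    }
  }
  n_syn_stat <- round(p$stationary_synaptic_fraction * p$n_stationary)
  stat_synaptic <- rep(FALSE, p$n_stationary)
  if (n_syn_stat > 0) stat_synaptic[seq_len(n_syn_stat)] <- TRUE

  # synapse-marker puncta: those under synaptic stationary cargo plus
  # independent synapses without cargo
  syn_x <- stat_x[stat_synaptic]
  n_extra <- stats::rpois(1, L / 10)
  if (n_extra > 0) {
    for (i in seq_len(n_extra)) {
      cand <- stats::runif(1, 1, L - 1)
      if (!length(stat_x) || min(abs(stat_x - cand)) > 1.5) {
        syn_x <- c(syn_x, cand)
      }
    }
  }

  # moving particles
  lambda <- p$entry_rate * (L / 100) * (p$duration / 60)
  n_enter <- stats::rpois(1, lambda)
  events <- list()
  if (n_enter > 0) {
    t_entry <- sort(stats::runif(n_enter, 0, p$duration - 2 * dt))
    for (i in seq_len(n_enter)) {
      from_left <- stats::runif(1) < 0.5
      ev <- .simulate_run_pause(t_entry[i], if (from_left) 0 else L,
                                if (from_left) 1 else -1, p, L)
      events[[length(events) + 1L]] <- ev
    }
  }

  # render movie frames
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- matrix(0, height_px, width_px)
    for (x in stat_x) img <- .add_punctum(img, x / ps_um, y0, sig_px, 1)
    for (ev in events) {
      xk <- .event_position(ev, times[k])
      if (!is.na(xk) && xk >= 0 && xk <= L) {
        img <- .add_punctum(img, xk / ps_um, y0, sig_px, 1)
      }
    }
    frames[[k]] <- .add_noise(img, p$snr)
  }

  render_sv2a <- function() {
    img <- matrix(0, height_px, width_px)
    for (x in syn_x) img <- .add_punctum(img, x / ps_um, y0, sig_px, 1)
    n_tr <- stats::rpois(1, 2)           # transient distractors
    if (n_tr > 0) {
      for (x in stats::runif(n_tr, 1, L - 1)) {
        img <- .add_punctum(img, x / ps_um, y0, sig_px, 0.8)
      }
    }
    .add_noise(img, p$snr)
  }
  sv2a_pre <- render_sv2a()
  sv2a_post <- render_sv2a()

  path <- cbind(seq(0, width_px - 1), rep(y0, width_px))

  movie <- structure(list(frames = frames, frame_interval = dt,
                          pixel_size = p$pixel_size, sv2a_pre = sv2a_pre,
                          sv2a_post = sv2a_post, path = path,
                          axon_length = L), class = "timelapse")
  truth <- structure(list(
    params = unclass(p), events = events, n_events = length(events),
    stationary = data.frame(x_um = stat_x,
                            synaptic = stat_synaptic),
    synapse_x_um = syn_x), class = "ground_truth")
  list(movie = movie, truth = truth)
}

# Simulate one run-and-pause trajectory; returns a track_event whose
# vertices are the segment change points clipped to the movie and axon.
.simulate_run_pause <- function(t0, x0, dir, p, L) {
  t <- t0; x <- x0
  ts <- t; xs <- x; labs <- character(0)
  running <- TRUE
  while (t < p$duration && x >= 0 && x <= L) {
    if (running) {
      dur <- if (p$pause_rate > 0) stats::rexp(1, p$pause_rate) else Inf
      # clip the run at the axon end or movie end
      t_exit <- if (dir > 0) (L - x) / p$run_speed else x / p$run_speed
      dur <- min(dur, t_exit, p$duration - t)
      t <- t + dur; x <- x + dir * p$run_speed * dur
      labs <- c(labs, "run")
    } else {
      dur <- min(stats::rexp(1, 1 / p$pause_duration_mean), p$duration - t)
      t <- t + dur
      labs <- c(labs, "pause")
    }
    ts <- c(ts, t); xs <- c(xs, x)
    running <- !running
    if (x <= 0 || x >= L) break
  }
  track_event(ts, xs, labs)
}

# Piecewise-linear position at time t; NA outside [appearance, disappearance]
.event_position <- function(ev, t) {
  if (t < ev$t[1] || t > ev$t[length(ev$t)]) return(NA_real_)
  stats::approx(ev$t, ev$x, xout = t, ties = "ordered")$y
}

# Add a Gaussian punctum at 0-based pixel position (x_px on the axon row)
.add_punctum <- function(img, x_px, y_px, sig_px, amp) {
  x_lo <- max(0, floor(x_px - 4 * sig_px))
  x_hi <- min(ncol(img) - 1, ceiling(x_px + 4 * sig_px))
  if (x_lo > x_hi) return(img)
  xs <- x_lo:x_hi
  ys <- 0:(nrow(img) - 1)
  patch <- amp * outer(exp(-(ys - y_px)^2 / (2 * sig_px^2)),
                       exp(-(xs - x_px)^2 / (2 * sig_px^2)))
  img[, xs + 1] <- img[, xs + 1] + patch
  img
}
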