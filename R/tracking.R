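# Moving-path events: automated ridge tracing on kymographs (a convenience
# for synthetic/high-SNR data; hand-annotated vertex lists are accepted
# verbatim via track_event/read_events) and the transport statistics defined
# on events: flux, instant speed, net speed.

#' Construct a movement event from its path vertices
#'
#' An event is one outlined path on the kymograph from appearance to
#' disappearance, including pauses; vertices are (time, position) pairs and
#' each inter-vertex interval is labeled `"run"` or `"pause"`.
#'
#' @param t strictly increasing times, s.
#' @param x positions, um.
#' @param labels interval labels, length `length(t) - 1`, values `"run"` or
#'   `"pause"`; if NULL, intervals are labeled from their speeds with the
#'   default pause criterion.
#' @param flags optional character flags (e.g. `"ambiguous"`, `"censored"`).
#' @return object of class `track_event`.
#' @export
track_event <- function(t, x, labels = NULL, flags = character()) {
  stopifnot(length(t) == length(x), length(t) >= 2, all(diff(t) > 0))
  if (is.null(labels)) {
    v <- abs(diff(x) / diff(t))
    labels <- ifelse(v < 0.05, "pause", "run")
  }
  stopifnot(length(labels) == length(t) - 1L,
            all(labels %in% c("run", "pause")))
  structure(list(t = as.numeric(t), x = as.numeric(x),
                 labels = as.character(labels), flags = flags),
            class = "track_event")
}

#' Instant and net speed of a movement event
#'
#' Instant speed pools the event's moving segments, time-weighted:
#' sum of absolute segment displacements over total moving time. Net speed
#' is appearance-to-disappearance displacement over total event time,
#' pauses included. Net speed can never exceed instant speed.
#'
#' @param event a [track_event()].
#' @return named list: `instant_speed`, `net_speed` (um/s), `n_moving_segments`,
#'   `pause_time` (s). `instant_speed` is NA when the event has no moving
#'   segment.
#' @export
event_speeds <- function(event) {
  stopifnot(inherits(event, "track_event"))
  segs <- .merge_segments(event)
  mov <- segs[segs$label == "run", , drop = FALSE]
  n <- length(event$t)
  net <- abs(event$x[n] - event$x[1]) / (event$t[n] - event$t[1])
  if (!nrow(mov) || sum(mov$dt) == 0) {
    return(list(instant_speed = NA_real_, net_speed = net,
                n_moving_segments = 0L,
                pause_time = sum(segs$dt[segs$label == "pause"])))
  }
  inst <- sum(abs(mov$dx)) / sum(mov$dt)
  list(instant_speed = inst, net_speed = net,
       n_moving_segments = nrow(mov),
       pause_time = sum(segs$dt[segs$label == "pause"]))
}

# collapse consecutive intervals with equal labels into segments
.merge_segments <- function(event) {
  lab <- event$labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(label = r$values,
             dt = event$t[ends + 1L] - event$t[starts],
             dx = event$x[ends + 1L] - event$x[starts])
}

#' Transport flux
#'
#' @param events list of [track_event()]s (only the count is used).
#' @param axon_length axon length, um.
#' @param duration imaging time, min.
#' @return events per 100 um of axon per minute.
#' @export
compute_flux <- function(events, axon_length, duration) {
  if (axon_length <= 0 || duration <= 0) {
    stop("axon_length and duration must be positive", call. = FALSE)
  }
  length(events) * 100 / (axon_length * duration)
}

#' Trace moving-particle paths on a kymograph
#'
#' Removes the stationary component (per-position temporal median), detects
#' per-frame intensity peaks with subpixel centroids, and links detections
#' frame to frame with velocity-predictive nearest-neighbor gating. A track
#' continues across pauses and short detection gaps when the continuation
#' is unambiguous (a single gated candidate); competing candidates inside
#' the gate flag the event `"ambiguous"`. Intervals slower than
#' `pause_speed` for at least `pause_min_frames` consecutive frames are
#' labeled pauses.
#'
#' @param kymo a [build_kymograph()] result.
#' @param min_frames minimal detections for a track to become an event.
#' @param max_step_um linking gate: maximal deviation from the predicted
#'   position per frame, um.
#' @param pause_speed pause threshold, um/s.
#' @param pause_min_frames minimal pause length, frames.
#' @param detect_nsd detection threshold in robust noise SDs of the
#'   stationary-subtracted kymograph (noise is estimated per position).
#' @param max_gap maximal number of consecutive missed frames bridged
#'   within one track.
#' @param min_range_um minimal positional range for a track to count as a
#'   movement event rather than a wobbling stationary object, um.
#' @return list of [track_event()]s.
#' @export
trace_moving_paths <- function(kymo, min_frames = 5, max_step_um = 1.2,
                               pause_speed = 0.05, pause_min_frames = 3,
                               detect_nsd = 5, max_gap = 3,
                               min_range_um = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  g <- kymo$grid
  step_um <- kymo$position_step / 1000
  dt <- kymo$time_step
  med <- apply(g, 2, stats::median)
  resid <- sweep(g, 2, med)
  resid[resid < 0] <- 0
  # per-position noise from temporal differences (robust to passing ridges,
  # and captures the larger shot noise on bright stationary columns)
  sd_col <- apply(g, 2, function(col) {
    stats::mad(diff(col), center = 0) / sqrt(2)
  })
  sd_col <- pmax(sd_col, stats::median(sd_col))
  thr <- pmax(detect_nsd * sd_col, 1e-9)

  detections <- lapply(seq_len(nrow(g)), function(k) {
    .detect_peaks_thr(resid[k, ], thr) * step_um
  })

  tracks <- list()     # each: list(t_idx, x, last_seen, vel)
  done <- list()
  for (k in seq_len(nrow(g))) {
    det <- detections[[k]]
    claimed <- rep(FALSE, length(det))
    if (length(tracks)) {
      pred <- vapply(tracks, function(tr) {
        gap <- k - tr$last_seen
        tr$x[length(tr$x)] + tr$vel * gap * dt
      }, numeric(1))
      ord <- order(vapply(tracks, function(tr) -tr$last_seen, numeric(1)))
      for (ti in ord) {
        if (!length(det)) break
        d <- abs(det - pred[ti])
        gate <- max_step_um * (k - tracks[[ti]]$last_seen)
        cand <- which(d <= gate & !claimed)
        if (!length(cand)) next
        best <- cand[which.min(d[cand])]
        if (length(cand) > 1L &&
            sort(d[cand])[2] <= gate) {
          tracks[[ti]]$flags <- union(tracks[[ti]]$flags, "ambiguous")
        }
        claimed[best] <- TRUE
        tr <- tracks[[ti]]
        dt_gap <- (k - tr$last_seen) * dt
        vel_new <- (det[best] - tr$x[length(tr$x)]) / dt_gap
        tr$vel <- if (abs(vel_new) < pause_speed) tr$vel * 0.5 else
          0.5 * tr$vel + 0.5 * vel_new
        tr$t_idx <- c(tr$t_idx, k)
        tr$x <- c(tr$x, det[best])
        tr$last_seen <- k
        tracks[[ti]] <- tr
      }
    }
    # retire stale tracks
    if (length(tracks)) {
      stale <- vapply(tracks, function(tr) k - tr$last_seen > max_gap,
                      logical(1))
      done <- c(done, tracks[stale])
      tracks <- tracks[!stale]
    }
    # unclaimed detections start new tracks
    for (x in det[!claimed]) {
      tracks[[length(tracks) + 1L]] <- list(t_idx = k, x = x, last_seen = k,
                                            vel = 0, flags = character())
    }
  }
  done <- c(done, tracks)

  # segments between pauses are not independent events: fragments whose
  # endpoints are each other's unique gated continuation are rejoined
  done <- done[vapply(done, function(tr) length(tr$t_idx) >= 3L,
                      logical(1))]
  done <- .merge_unambiguous(done, dt, max_step_um,
                             gap_t = (max_gap + 8) * dt,
                             x_bounds = c(0, (ncol(g) - 1) * step_um))

  events <- list()
  for (tr in done) {
    if (length(tr$t_idx) < min_frames) next
    t <- (tr$t_idx - 1L) * dt
    # a track that never leaves one spot is stationary, not a movement event
    if (max(tr$x) - min(tr$x) < min_range_um) next
    labels <- .label_intervals(t, tr$x, pause_speed, pause_min_frames)
    flags <- tr$flags
    if (tr$t_idx[1] == 1L || tr$last_seen == nrow(g)) {
      flags <- union(flags, "censored")
    }
    events[[length(events) + 1L]] <- track_event(t, tr$x, labels, flags)
  }
  events
}

# Join track fragments A -> B when B starts after A ends within gap_t, the
# positional jump is within the per-frame gate, and neither has a competing
# candidate; competing fragments stay separate and are flagged ambiguous.
# Fragments ending (starting) at the axon boundary are exits (entries), not
# pause interruptions, and are never merged across.
.merge_unambiguous <- function(tracks, dt, max_step_um, gap_t, x_bounds) {
  near_edge <- function(x) {
    x < x_bounds[1] + 1.5 || x > x_bounds[2] - 1.5
  }
  repeat {
    n <- length(tracks)
    if (n < 2) return(tracks)
    starts_t <- vapply(tracks, function(tr) tr$t_idx[1] * dt, numeric(1))
    ends_t <- vapply(tracks, function(tr) tr$last_seen * dt, numeric(1))
    starts_x <- vapply(tracks, function(tr) tr$x[1], numeric(1))
    ends_x <- vapply(tracks, function(tr) tr$x[length(tr$x)], numeric(1))
    edge_start <- vapply(starts_x, near_edge, logical(1))
    edge_end <- vapply(ends_x, near_edge, logical(1))
    merged <- FALSE
    for (a in seq_len(n)) {
      if (edge_end[a]) next
      gap <- starts_t - ends_t[a]
      ok <- which(gap > 0 & gap <= gap_t & !edge_start &
                    abs(starts_x - ends_x[a]) <= max_step_um * gap / dt)
      if (length(ok) != 1L) {
        if (length(ok) > 1L) {
          tracks[[a]]$flags <- union(tracks[[a]]$flags, "ambiguous")
        }
        next
      }
      b <- ok
      # b must also have no competing predecessor
      gap_b <- starts_t[b] - ends_t
      pred <- which(gap_b > 0 & gap_b <= gap_t &
                      abs(starts_x[b] - ends_x) <=
                        max_step_um * gap_b / dt)
      if (length(pred) != 1L || pred != a) {
        tracks[[b]]$flags <- union(tracks[[b]]$flags, "ambiguous")
        next
      }
      tr <- tracks[[a]]
      tb <- tracks[[b]]
      tr$t_idx <- c(tr$t_idx, tb$t_idx)
      tr$x <- c(tr$x, tb$x)
      tr$last_seen <- tb$last_seen
      tr$vel <- tb$vel
      tr$flags <- union(tr$flags, tb$flags)
      tracks[[a]] <- tr
      tracks[[b]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) return(tracks)
  }
}

# local maxima above a (possibly per-position) threshold with 5-point
# centroid refinement; returns 0-based positions in steps
.detect_peaks_thr <- function(row, thr) {
  n <- length(row)
  if (n < 3) return(numeric(0))
  is_peak <- row > thr &
    row >= c(-Inf, row[-n]) & row > c(row[-1], -Inf)
  idx <- which(is_peak)
  if (!length(idx)) return(numeric(0))
  # merge peaks closer than 3 steps, keeping the brighter
  if (length(idx) > 1) {
    keep <- rep(TRUE, length(idx))
    for (i in 2:length(idx)) {
      if (idx[i] - idx[i - 1] < 3) {
        if (row[idx[i]] >= row[idx[i - 1]]) keep[i - 1] <- FALSE else
          keep[i] <- FALSE
      }
    }
    idx <- idx[keep]
  }
  vapply(idx, function(j) {
    lo <- max(1, j - 2); hi <- min(n, j + 2)
    w <- row[lo:hi]
    sum((lo:hi - 1) * w) / sum(w)
  }, numeric(1))
}

# pause = run of >= pause_min_frames consecutive intervals slower than
# pause_speed; everything else is moving
.label_intervals <- function(t, x, pause_speed, pause_min_frames) {
  v <- abs(diff(x) / diff(t))
  slow <- v < pause_speed
  labels <- rep("run", length(v))
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= pause_min_frames) {
      labels[starts[i]:ends[i]] <- "pause"
    }
  }
  labels
}
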