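# Side-view line-profile analysis: bar placement perpendicular to the AZ/PSD
# marker, 0.2 x 1.0 um intensity extraction with a rolling average of three,
# and alignment of target profiles to the reference marker peak.

#' Place the profile bar across a side-view synapse
#'
#' Positions a rectangular profile bar through the intensity-weighted
#' centroid of the AZ/PSD marker object, oriented perpendicular to the
#' marker bar (i.e. along the marker's minor principal axis). The axis sign
#' is chosen so that negative positions point toward the presynaptic side,
#' identified by the vesicle-channel centroid. Marker objects whose principal
#' axis ratio is below `anisotropy_min` are rejected as not side-view.
#'
#' @param marker_channel STED [image_channel()] of the AZ/PSD marker.
#' @param vesicle_channel confocal [image_channel()] of the vesicle cloud.
#' @param bar_length,bar_width profile bar extent, nm (1.0 x 0.2 um).
#' @param anisotropy_min minimal sqrt-eigenvalue ratio of the marker's
#'   second moments for the synapse to count as side-view.
#' @return object of class `profile_bar`: `center` (nm), `axis` (unit
#'   vector, negative direction presynaptic), `length`, `width`,
#'   `anisotropy`.
#' @export
place_profile_bar <- function(marker_channel, vesicle_channel,
                              bar_length = 1000, bar_width = 200,
                              anisotropy_min = 2) {
  stopifnot(inherits(marker_channel, "image_channel"))
  .check_registered(marker_channel, vesicle_channel)
  ps <- marker_channel$pixel_size
  objs <- threshold_objects(marker_channel)
  if (!length(objs)) stop("no marker object found", call. = FALSE)
  main <- objs[[which.max(vapply(objs, `[[`, numeric(1), "n_pixels"))]]
  g <- marker_channel$grid
  rc <- arrayInd(main$idx, dim(g))
  w <- g[main$idx]
  # pixel centers in nm (0-based index + 0.5)
  xs <- (rc[, 2] - 0.5) * ps
  ys <- (rc[, 1] - 0.5) * ps
  cx <- sum(w * xs) / sum(w)
  cy <- sum(w * ys) / sum(w)
  cxx <- sum(w * (xs - cx)^2) / sum(w)
  cyy <- sum(w * (ys - cy)^2) / sum(w)
  cxy <- sum(w * (xs - cx) * (ys - cy)) / sum(w)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  anis <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
  if (anis < anisotropy_min) {
    stop(sprintf(paste0("not a side-view synapse: marker anisotropy %.2f ",
                        "below %.2f"), anis, anisotropy_min), call. = FALSE)
  }
  axis <- ev$vectors[, 2]                 # minor principal axis
  axis <- axis / sqrt(sum(axis^2))
  gv <- .as_grid(vesicle_channel)
  tot <- sum(gv)
  vx <- sum(gv * matrix((seq_len(ncol(gv)) - 0.5) * ps, nrow(gv), ncol(gv),
                        byrow = TRUE)) / tot
  vy <- sum(gv * matrix((seq_len(nrow(gv)) - 0.5) * ps, nrow(gv),
                        ncol(gv))) / tot
  if ((vx - cx) * axis[1] + (vy - cy) * axis[2] > 0) axis <- -axis
  structure(list(center = c(cx, cy), axis = axis, length = bar_length,
                 width = bar_width, anisotropy = anis),
            class = "profile_bar")
}

#' Extract a smoothed line profile along a bar
#'
#' Samples the channel along the bar axis at one-pixel steps; at each step
#' the intensity is the mean across the bar width (bilinear interpolation on
#' the rotated grid), then a rolling average of three consecutive values is
#' applied, dropping the two edge samples.
#'
#' @param bar a [place_profile_bar()] result (or a manually built
#'   `profile_bar`).
#' @param channel registered [image_channel()].
#' @return object of class `line_profile`: `positions` (nm, 0 at the bar
#'   center, negative = presynaptic), `intensities` (smoothed),
#'   `peak_position`, `peak_intensity`, `peak_tie` flag.
#' @export
extract_profile <- function(bar, channel) {
  stopifnot(inherits(bar, "profile_bar"), inherits(channel, "image_channel"))
  ps <- channel$pixel_size
  pos <- seq(-bar$length / 2, bar$length / 2, by = ps)
  wid <- seq(-bar$width / 2, bar$width / 2, by = ps)
  perp <- c(-bar$axis[2], bar$axis[1])
  g <- channel$grid
  raw <- vapply(pos, function(p) {
    px <- bar$center[1] + p * bar$axis[1] + wid * perp[1]
    py <- bar$center[2] + p * bar$axis[2] + wid * perp[2]
    v <- bilinear(g, px / ps - 0.5, py / ps - 0.5)
    if (anyNA(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
  if (anyNA(raw)) stop("profile bar exceeds image bounds", call. = FALSE)
  sm <- rolling3(raw)
  spos <- pos[2:(length(pos) - 1L)]
  .line_profile(spos, sm)
}

.line_profile <- function(positions, intensities) {
  mx <- max(intensities)
  peaks <- which(intensities == mx)
  structure(list(positions = positions, intensities = intensities,
                 peak_position = positions[peaks[1L]],  # most presynaptic tie
                 peak_intensity = mx,
                 peak_tie = length(peaks) > 1L), class = "line_profile")
}

#' Align target profiles to the reference marker peak
#'
#' Shifts each synapse's positions so the reference (AZ/PSD marker) profile
#' peak sits at 0, keeping the sign convention (negative = presynaptic).
#' Reports the per-synapse target peak position/intensity and the aggregate
#' mean and SEM profile over synapses; aligned positions present in fewer
#' than half the synapses are dropped from the mean profile.
#'
#' @param profiles list with one element per synapse, each a list with
#'   `reference` and `target` [extract_profile()] results.
#' @param normalize divide each target profile by its own maximum before
#'   averaging (default TRUE).
#' @return list with `per_synapse` (data.frame `synapse`,
#'   `peak_position_nm`, `peak_intensity`, `peak_tie`) and `mean_profile`
#'   (data.frame `position_nm`, `mean`, `sem`, `n`).
#' @export
align_profiles <- function(profiles, normalize = TRUE) {
  stopifnot(length(profiles) >= 1)
  n_syn <- length(profiles)
  per <- vector("list", n_syn)
  long <- vector("list", n_syn)
  for (s in seq_len(n_syn)) {
    ref <- profiles[[s]]$reference
    tgt <- profiles[[s]]$target
    stopifnot(inherits(ref, "line_profile"), inherits(tgt, "line_profile"))
    shift <- ref$peak_position
    tpos <- tgt$positions - shift
    tint <- tgt$intensities
    if (normalize) tint <- tint / max(tint)
    aligned <- .line_profile(tpos, tint)
    per[[s]] <- data.frame(synapse = s,
                           peak_position_nm = aligned$peak_position,
                           peak_intensity = aligned$peak_intensity,
                           peak_tie = aligned$peak_tie | ref$peak_tie)
    long[[s]] <- data.frame(synapse = s, position_nm = round(tpos, 6),
                            intensity = tint)
  }
  long <- do.call(rbind, long)
  agg_n <- stats::aggregate(intensity ~ position_nm, long, length)
  agg_m <- stats::aggregate(intensity ~ position_nm, long, mean)
  agg_s <- stats::aggregate(intensity ~ position_nm, long, stats::sd)
  mp <- data.frame(position_nm = agg_m$position_nm, mean = agg_m$intensity,
                   sem = agg_s$intensity / sqrt(agg_n$intensity),
                   n = agg_n$intensity)
  mp <- mp[mp$n >= ceiling(n_syn / 2), , drop = FALSE]
  mp <- mp[order(mp$position_nm), , drop = FALSE]
  rownames(mp) <- NULL
  list(per_synapse = do.call(rbind, per), mean_profile = mp)
}

#' Run the full side-view profile analysis on a synapse stack
#'
#' For each synapse: places the profile bar from the marker and vesicle
#' channels, extracts reference (marker) and target profiles, and aligns all
#' target profiles to the marker peaks. Synapses failing the side-view
#' anisotropy test are skipped with a warning.
#'
#' @param synapses list of `sideview_synapse` objects (see
#'   [gen_sideview_stack()]), each with `vesicle`, `marker` and `target`
#'   channels.
#' @param normalize passed to [align_profiles()].
#' @inheritParams place_profile_bar
#' @return as [align_profiles()], plus `bars` (the per-synapse
#'   `profile_bar`s) and `used` (indices of analyzed synapses).
#' @export
analyze_sideview_stack <- function(synapses, normalize = TRUE,
                                   bar_length = 1000, bar_width = 200,
                                   anisotropy_min = 2) {
  profiles <- list(); bars <- list(); used <- integer()
  for (s in seq_along(synapses)) {
    ch <- synapses[[s]]$channels
    bar <- tryCatch(
      place_profile_bar(ch$marker, ch$vesicle, bar_length, bar_width,
                        anisotropy_min),
      error = function(e) NULL)
    if (is.null(bar)) {
      warning(sprintf("synapse %d skipped: %s", s, "not side-view"))
      next
    }
    profiles[[length(profiles) + 1L]] <- list(
      reference = extract_profile(bar, ch$marker),
      target = extract_profile(bar, ch$target))
    bars[[length(bars) + 1L]] <- bar
    used <- c(used, s)
  }
  if (!length(profiles)) stop("no analyzable side-view synapses",
                              call. = FALSE)
  out <- align_profiles(profiles, normalize = normalize)
  out$bars <- bars
  out$used <- used
  out
}
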