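# Kymograph construction and the stationary-cargo statistics: full-duration
# stationary objects, their density per 10 um of axon, and the fraction
# overlapping confirmed synapse-marker puncta.

#' Build a kymograph from a time-lapse movie
#'
#' Samples each frame along the axon path at one-pixel steps; the intensity
#' at each path position is the mean across a `line_width`-pixel-wide line
#' normal to the path (3 pixels by default). Rows are frames in time order,
#' columns are path positions, so moving particles appear as diagonal ridges
#' and stationary objects as vertical bars.
#'
#' @param movie a `timelapse` (see [gen_timelapse()]) or a list with
#'   `frames`, `frame_interval` (s) and `pixel_size` (nm).
#' @param path 2-column matrix of 0-based pixel coordinates of the axon
#'   polyline; defaults to `movie$path`.
#' @param line_width width of the normal line-scan, pixels (odd).
#' @return object of class `kymograph`: `grid` (time x position),
#'   `position_step` nm, `time_step` s.
#' @export
build_kymograph <- function(movie, path = movie$path, line_width = 3) {
  stopifnot(length(movie$frames) >= 2, line_width >= 1,
            line_width %% 2 == 1)
  path <- as.matrix(path)
  # resample the polyline at 1-px arc-length steps
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  arc <- c(0, cumsum(seg))
  n_pos <- max(2L, floor(arc[length(arc)]) + 1L)
  s <- seq(0, arc[length(arc)], length.out = n_pos)
  px <- stats::approx(arc, path[, 1], xout = s, ties = "ordered")$y
  py <- stats::approx(arc, path[, 2], xout = s, ties = "ordered")$y
  # unit tangents -> normals
  tx <- c(diff(px), diff(px)[n_pos - 1L])
  ty <- c(diff(py), diff(py)[n_pos - 1L])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- seq(-(line_width - 1) / 2, (line_width - 1) / 2)

  grid <- matrix(NA_real_, length(movie$frames), n_pos)
  for (k in seq_along(movie$frames)) {
    f <- movie$frames[[k]]
    acc <- 0
    for (o in offs) {
      v <- bilinear(f, px + o * nx, py + o * ny)
      acc <- acc + v
    }
    grid[k, ] <- acc / line_width
  }
  if (anyNA(grid)) stop("path (with its line width) leaves the frame bounds",
                        call. = FALSE)
  structure(list(grid = grid, position_step = movie$pixel_size,
                 time_step = movie$frame_interval), class = "kymograph")
}

#' Confirm synapse objects from pre/post marker frames
#'
#' Thresholds both still frames at the first frame's Otsu threshold and
#' keeps only objects present (overlapping above threshold) in both
#' binaries, rejecting transient puncta.
#'
#' @param pre,post registered intensity matrices (marker frames captured
#'   before and after the time lapse).
#' @return list with `mask` (logical matrix of confirmed object pixels),
#'   `labels` (integer label matrix), `n_objects`.
#' @export
confirm_synapse_objects <- function(pre, post) {
  pre <- .as_grid(pre); post <- .as_grid(post)
  .check_registered(pre, post)
  rng <- range(pre)
  if (rng[1] == rng[2]) stop("constant marker frame: no threshold exists",
                             call. = FALSE)
  thr <- rng[1] +
    EBImage::otsu((pre - rng[1]) / (rng[2] - rng[1])) * (rng[2] - rng[1])
  b_pre <- pre > thr
  b_post <- post > thr
  lab <- EBImage::bwlabel(b_pre)
  keep <- integer(0)
  for (k in seq_len(max(lab))) {
    if (any(b_post[lab == k])) keep <- c(keep, k)
  }
  mask <- lab %in% keep
  dim(mask) <- dim(lab)
  lab[!mask] <- 0L
  list(mask = mask, labels = lab, n_objects = length(keep))
}

#' Detect stationary objects on a kymograph
#'
#' A position is stationary when its (thresholded) signal is present in
#' every frame within `position_tol` position steps; contiguous stationary
#' positions are grouped into objects. Objects must therefore persist for
#' the entire movie -- one missing frame disqualifies them.
#'
#' @param kymo a [build_kymograph()] result.
#' @param position_tol positional tolerance, steps.
#' @return list with `objects` (data.frame `position_um`, `col_lo`,
#'   `col_hi`), `count` and `density_per_10um` (count x 10 /
#'   axon-length-um).
#' @export
detect_stationary <- function(kymo, position_tol = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  g <- kymo$grid
  rng <- range(g)
  if (rng[1] == rng[2]) stop("constant kymograph", call. = FALSE)
  thr <- rng[1] +
    EBImage::otsu((g - rng[1]) / (rng[2] - rng[1])) * (rng[2] - rng[1])
  b <- g > thr
  n_pos <- ncol(g)
  present <- matrix(FALSE, nrow(g), n_pos)
  for (j in seq_len(n_pos)) {
    lo <- max(1, j - position_tol); hi <- min(n_pos, j + position_tol)
    present[, j] <- rowSums(b[, lo:hi, drop = FALSE]) > 0
  }
  stat_col <- colSums(present) == nrow(g)
  runs <- rle(stat_col)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  step_um <- kymo$position_step / 1000
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    cols <- starts[i]:ends[i]
    w <- colSums(g[, cols, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      position_um = sum((cols - 1) * w) / sum(w) * step_um,
      col_lo = starts[i], col_hi = ends[i])
  }
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position_um = numeric(), col_lo = integer(),
               col_hi = integer())
  axon_um <- (n_pos - 1) * step_um
  list(objects = objects, count = nrow(objects),
       density_per_10um = nrow(objects) * 10 / axon_um)
}

#' Sample a synapse mask along the kymograph path
#'
#' @param mask logical matrix (e.g. from [confirm_synapse_objects()]).
#' @param path 2-column matrix of 0-based pixel coordinates.
#' @param line_width normal line width, pixels.
#' @return logical vector: TRUE at path positions covered by a synapse
#'   object.
#' @keywords internal
path_mask_profile <- function(mask, path, line_width = 3) {
  k <- build_kymograph(list(frames = list(mask * 1, mask * 1),
                            frame_interval = 1, pixel_size = 1),
                       path = path, line_width = line_width)
  k$grid[1, ] > 0
}

#' Fraction of stationary objects that are synaptic
#'
#' A stationary object is synaptic when its positional footprint overlaps a
#' confirmed synapse object by more than zero positions.
#'
#' @param stationary result of [detect_stationary()].
#' @param synapse_profile logical vector along the same path (see
#'   [path_mask_profile()]).
#' @return list with `fraction` (NA when there are no stationary objects),
#'   `synaptic` logical vector per object.
#' @export
synaptic_fraction <- function(stationary, synapse_profile) {
  objs <- stationary$objects
  if (!nrow(objs)) return(list(fraction = NA_real_, synaptic = logical()))
  syn <- vapply(seq_len(nrow(objs)), function(i) {
    any(synapse_profile[objs$col_lo[i]:objs$col_hi[i]])
  }, logical(1))
  list(fraction = mean(syn), synaptic = syn)
}
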