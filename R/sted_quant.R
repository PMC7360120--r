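# Confocal/STED ROI quantification: Otsu-thresholded binary objects,
# per-object intensity statistics, non-active-zone fractions, per-synapse
# crop correlations and Bassoon/mito-Rab6 overlap fractions.

#' Image channel container
#'
#' @param grid 2-D non-negative intensity matrix (rows = y, columns = x).
#' @param pixel_size pixel size, nm.
#' @param channel_name label for outputs.
#' @param modality `"confocal"` or `"sted"`.
#' @return object of class `image_channel`.
#' @export
image_channel <- function(grid, pixel_size, channel_name = "channel",
                          modality = c("confocal", "sted")) {
  modality <- match.arg(modality)
  grid <- as.matrix(grid)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (any(grid < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(grid = grid, pixel_size = pixel_size,
                 channel_name = channel_name, modality = modality),
            class = "image_channel")
}

.as_grid <- function(x) {
  if (inherits(x, "image_channel")) x$grid else as.matrix(x)
}

.check_registered <- function(a, b) {
  if (!identical(dim(.as_grid(a)), dim(.as_grid(b)))) {
    stop("channels are not registered on the same pixel grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Threshold a channel into binary ROI objects
#'
#' Binarizes the channel (Otsu's method by default, or a fixed manual value)
#' and labels connected components, discarding objects smaller than
#' `min_area`. Deterministic: the same image always yields the same objects.
#'
#' @param channel an [image_channel()].
#' @param method `"otsu"` or `"manual"`.
#' @param min_area minimal object area, um^2.
#' @param value threshold intensity when `method = "manual"`.
#' @return list of `roi_object`s, each with `label`, `idx` (linear pixel
#'   indices into the grid), `n_pixels`, `area` (um^2). The threshold used is
#'   attached as attribute `threshold`.
#' @export
threshold_objects <- function(channel, method = c("otsu", "manual"),
                              min_area = 0, value = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(channel, "image_channel"))
  g <- channel$grid
  rng <- range(g)
  if (rng[1] == rng[2]) stop("constant image: no threshold exists",
                             call. = FALSE)
  thr <- if (method == "otsu") {
    norm <- (g - rng[1]) / (rng[2] - rng[1])
    rng[1] + EBImage::otsu(norm, range = c(0, 1)) * (rng[2] - rng[1])
  } else {
    if (is.null(value)) stop("manual thresholding needs `value`",
                             call. = FALSE)
    value
  }
  mask <- g > thr
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  px_area <- channel$pixel_size^2 / 1e6
  out <- list()
  for (k in seq_len(nlab)) {
    idx <- which(lab == k)
    area <- length(idx) * px_area
    if (area < min_area) next
    out[[length(out) + 1L]] <- structure(
      list(label = k, idx = idx, n_pixels = length(idx), area = area,
           dim = dim(g), pixel_size = channel$pixel_size),
      class = "roi_object")
  }
  attr(out, "threshold") <- thr
  attr(out, "method") <- method
  out
}

#' Measure per-object intensity in a target channel
#'
#' @param objects list of `roi_object`s from [threshold_objects()].
#' @param target_channel registered [image_channel()] to quantify.
#' @param normalize_to optional control mean; when given, an additional
#'   `norm_mean` column divides each object mean by it.
#' @return data.frame with one row per object: `label`, `n_pixels`,
#'   `area_um2`, `sum`, `mean` (and `norm_mean`).
#' @export
measure_roi_intensity <- function(objects, target_channel,
                                  normalize_to = NULL) {
  g <- .as_grid(target_channel)
  rows <- lapply(objects, function(o) {
    if (!identical(o$dim, dim(g))) {
      stop("object grid and target channel are not registered",
           call. = FALSE)
    }
    s <- sum(g[o$idx])
    data.frame(label = o$label, n_pixels = o$n_pixels, area_um2 = o$area,
               sum = s, mean = s / o$n_pixels)
  })
  out <- do.call(rbind, rows)
  if (!is.null(normalize_to)) {
    if (normalize_to <= 0) stop("normalize_to must be > 0", call. = FALSE)
    out$norm_mean <- out$mean / normalize_to
  }
  out
}

#' Fraction of target signal outside the active zone
#'
#' Computes `1 - I(target within synapsin-and-bassoon pixels) / I(target
#' within synapsin pixels)` for one image: the fraction of a synaptic
#' protein's signal that does not colocalize with the active-zone marker.
#'
#' @param target_channel [image_channel()] or matrix.
#' @param synapsin_mask,bassoon_mask logical matrices registered with the
#'   target channel.
#' @return fraction in `[0, 1]`, or `NA` when the synapsin ROI holds no
#'   target intensity.
#' @export
non_az_fraction <- function(target_channel, synapsin_mask, bassoon_mask) {
  g <- .as_grid(target_channel)
  .check_registered(g, synapsin_mask)
  .check_registered(g, bassoon_mask)
  i_syn <- sum(g[synapsin_mask])
  if (i_syn == 0) return(NA_real_)
  i_both <- sum(g[synapsin_mask & bassoon_mask])
  1 - i_both / i_syn
}

#' Per-synapse crop intensities for correlation analysis
#'
#' Sums each channel's intensity in a square crop (default 1.5 x 1.5 um^2)
#' centered on every synapse, without background subtraction. Crops falling
#' outside the image are skipped with a warning.
#'
#' @param channel_a,channel_b registered [image_channel()]s.
#' @param synapse_centers data.frame with `x_nm`, `y_nm` columns.
#' @param crop crop side length, nm.
#' @return data.frame with `synapse`, `I_a`, `I_b`; pass the two columns to
#'   [pearson()].
#' @export
synapse_crop_correlation <- function(channel_a, channel_b, synapse_centers,
                                     crop = 1500) {
  .check_registered(channel_a, channel_b)
  ga <- .as_grid(channel_a); gb <- .as_grid(channel_b)
  ps <- channel_a$pixel_size
  half_px <- floor(crop / ps / 2)
  rows <- list()
  for (i in seq_len(nrow(synapse_centers))) {
    cxp <- round(synapse_centers$x_nm[i] / ps + 0.5)
    cyp <- round(synapse_centers$y_nm[i] / ps + 0.5)
    xs <- (cxp - half_px):(cxp + half_px)
    ys <- (cyp - half_px):(cyp + half_px)
    if (min(xs) < 1 || min(ys) < 1 || max(xs) > ncol(ga) ||
        max(ys) > nrow(ga)) {
      warning(sprintf("synapse %d crop out of bounds; skipped", i))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      synapse = i, I_a = sum(ga[ys, xs]), I_b = sum(gb[ys, xs]))
  }
  if (!length(rows)) {
    return(data.frame(synapse = integer(), I_a = numeric(),
                      I_b = numeric()))
  }
  do.call(rbind, rows)
}

#' Fraction of synapses positive for a mitochondrially mistargeted marker
#'
#' A Bassoon object is counted positive when at least `cutoff` of its area
#' overlaps the marker mask (50% by default).
#'
#' @param bassoon_objects `roi_object` list from [threshold_objects()].
#' @param marker_mask logical matrix registered with the Bassoon channel.
#' @param cutoff minimal overlapping area fraction.
#' @return list with `fraction` (NA when there are no objects), `overlaps`
#'   (per-object overlap fractions) and `n_objects`.
#' @export
mito_positive_synapse_fraction <- function(bassoon_objects, marker_mask,
                                           cutoff = 0.5) {
  if (!length(bassoon_objects)) {
    return(list(fraction = NA_real_, overlaps = numeric(), n_objects = 0L))
  }
  overlaps <- vapply(bassoon_objects, function(o) {
    if (!identical(o$dim, dim(marker_mask))) {
      stop("marker mask not registered with Bassoon objects", call. = FALSE)
    }
    sum(marker_mask[o$idx]) / o$n_pixels
  }, numeric(1))
  list(fraction = mean(overlaps >= cutoff), overlaps = overlaps,
       n_objects = length(overlaps))
}
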