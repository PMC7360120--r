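# Planar geometry helpers. All coordinates are in nm, x rightward, y downward
# (raster convention); polylines/polygons are n x 2 matrices of vertices.

#' Distance from points to a polyline
#'
#' Minimal Euclidean distance from each query point to a polyline, taken over
#' all its segments (feet of perpendiculars are clamped to segment ends).
#'
#' @param pts numeric matrix (n x 2) of query points, nm.
#' @param poly numeric matrix (m x 2) of polyline vertices, nm.
#' @return numeric vector of length n.
#' @keywords internal
dist_to_polyline <- function(pts, poly) {
  pts <- rbind(pts)
  if (nrow(poly) < 2L) {
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  }
  best <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(poly) - 1L)) {
    d <- .dist_point_segment(pts, poly[k, ], poly[k + 1L, ])$dist
    best <- pmin(best, d)
  }
  best
}

# Distance and projection parameter from points to one segment a--b.
# Returns list(dist, t) with t clamped to [0, 1].
.dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    return(list(dist = d, t = rep(0, nrow(pts))))
  }
  t_raw <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t_raw))
  fx <- a[1] + t * ab[1]
  fy <- a[2] + t * ab[2]
  list(dist = sqrt((pts[, 1] - fx)^2 + (pts[, 2] - fy)^2), t = t_raw)
}

#' Distance from points to a polyline with interior-projection requirement
#'
#' Like [dist_to_polyline()] but only counts segments onto which the point's
#' perpendicular foot falls strictly inside the segment (projection parameter
#' in [0, 1]); points whose nearest approach is past both ends of the whole
#' polyline get `Inf`.
#'
#' @inheritParams dist_to_polyline
#' @keywords internal
dist_to_polyline_interior <- function(pts, poly) {
  pts <- rbind(pts)
  best <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(poly) - 1L)) {
    ds <- .dist_point_segment(pts, poly[k, ], poly[k + 1L, ])
    hit <- ds$t >= 0 & ds$t <= 1
    best[hit] <- pmin(best[hit], ds$dist[hit])
  }
  best
}

#' Perimeter of a closed polygon
#'
#' @param poly numeric matrix (m x 2), vertices in order; closure edge from the
#'   last vertex back to the first is implied.
#' @return perimeter in the same unit as the coordinates.
#' @keywords internal
polygon_perimeter <- function(poly) {
  closed <- rbind(poly, poly[1L, ])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param pts n x 2 matrix of query points.
#' @param poly m x 2 matrix of polygon vertices.
#' @return logical vector, TRUE for points inside.
#' @keywords internal
point_in_polygon <- function(pts, poly) {
  pts <- rbind(pts)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a closed polygon boundary
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of unsigned distances to the boundary.
#' @keywords internal
dist_to_polygon <- function(pts, poly) {
  dist_to_polyline(pts, rbind(poly, poly[1L, ]))
}

#' Bilinear interpolation into an image matrix
#'
#' Image is indexed as `img[row, col]` = `img[y + 1, x + 1]` for 0-based pixel
#' coordinates; a pixel's center is at integer (x, y). Queries outside the
#' image return NA.
#'
#' @param img numeric matrix.
#' @param x,y 0-based pixel coordinates (numeric vectors, recycled together).
#' @return interpolated intensities.
#' @keywords internal
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the upper neighbor on the last row/col so edge queries stay valid
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  out <- rep(NA_real_, length(x))
  i <- which(ok)
  if (length(i)) {
    v00 <- img[cbind(y0[i] + 1, x0[i] + 1)]
    v10 <- img[cbind(y0[i] + 1, x1[i] + 1)]
    v01 <- img[cbind(y1[i] + 1, x0[i] + 1)]
    v11 <- img[cbind(y1[i] + 1, x1[i] + 1)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v10 * fx[i] * (1 - fy[i]) +
      v01 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

#' Centered rolling mean of three consecutive values
#'
#' Only positions with a full window are returned, so the result is two
#' samples shorter than the input.
#'
#' @param x numeric vector of length >= 3.
#' @return numeric vector of length `length(x) - 2`.
#' @keywords internal
rolling3 <- function(x) {
  stopifnot(length(x) >= 3L)
  as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))[2:(length(x) - 1L)]
}

# Truncated-normal draw (lower truncation at `lower`), by rejection; the
# default vesicle diameter regime (mean 40, sd 5, lower 10) almost never
# rejects so this stays cheap.
rtruncnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

# Shared parameter validation helpers --------------------------------------

.check_num <- function(x, name, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric of length %d", name, len),
         call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x[1])), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, lower = 0L) {
  .check_num(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("`%s` must be an integer count", name),
                          call. = FALSE)
  invisible(as.integer(x))
}
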