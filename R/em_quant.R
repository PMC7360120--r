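# Operational EM classification rules: boutons (vesicle clusters), axonal
# vesicles, docked vesicles, endosomes, and mitochondrion-tethered vesicles.
# Vesicle tables are data.frames with columns id, x_nm, y_nm, diameter_nm.

#' Axon segment annotation
#'
#' @param centerline 2-column matrix of polyline vertices, nm.
#' @param width shaft width, um.
#' @param length segment length, um; defaults to the centerline length.
#' @return object of class `axon_segment` with a `valid` flag: a segment is
#'   analyzable when it is at least 1 um long and its width lies within
#'   0.2--0.75 um.
#' @export
axon_segment <- function(centerline, width, length = NULL) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 2, nrow(centerline) >= 2)
  if (is.null(length)) {
    length <- sum(sqrt(diff(centerline[, 1])^2 +
                         diff(centerline[, 2])^2)) / 1000
  }
  structure(list(centerline = centerline, width = width, length = length,
                 valid = length >= 1 && width >= 0.2 && width <= 0.75),
            class = "axon_segment")
}

#' Mitochondrion annotation
#'
#' @param boundary closed polygon, 2-column matrix of vertices in nm (closure
#'   edge implied).
#' @return object of class `mitochondrion` carrying the polygon and its
#'   perimeter in um.
#' @export
mitochondrion <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3) stop("degenerate polygon: need >= 3 vertices",
                               call. = FALSE)
  per <- polygon_perimeter(boundary) / 1000
  if (per <= 0) stop("degenerate polygon: zero perimeter", call. = FALSE)
  structure(list(boundary = boundary, perimeter = per),
            class = "mitochondrion")
}

.check_vesicles <- function(vesicles) {
  need <- c("id", "x_nm", "y_nm", "diameter_nm")
  if (!all(need %in% names(vesicles))) {
    stop("vesicle table must have columns id, x_nm, y_nm, diameter_nm",
         call. = FALSE)
  }
  if (anyDuplicated(vesicles$id)) stop("duplicate vesicle ids", call. = FALSE)
  if (any(vesicles$diameter_nm <= 0)) stop("vesicle diameters must be > 0",
                                           call. = FALSE)
  invisible(vesicles)
}

#' Cluster vesicles into boutons
#'
#' A bouton is a group of at least `min_size` vesicles in which every
#' vesicle's center is at most `nn_max` from the center of its nearest
#' neighbor within the group. This is formalized as the connected components
#' of the graph joining vesicle pairs with center distance <= `nn_max`
#' (inclusive at equality), keeping components of size >= `min_size`.
#'
#' @param vesicles vesicle table (`id`, `x_nm`, `y_nm`, `diameter_nm`).
#' @param nn_max maximal nearest-neighbor center distance, nm.
#' @param min_size minimal number of member vesicles.
#' @return list of boutons, each a list with `member_ids`, `n_vesicles`,
#'   `n_docked` (NA until [count_docked()] is run) and `area` (NA unless an
#'   annotation polygon supplies it). Boutons are ordered by their smallest
#'   member id, so the output is independent of input row order.
#' @export
cluster_boutons <- function(vesicles, nn_max = 100, min_size = 20) {
  .check_vesicles(vesicles)
  n <- nrow(vesicles)
  if (n == 0) return(list())
  xy <- as.matrix(vesicles[, c("x_nm", "y_nm")])
  d <- as.matrix(stats::dist(xy))
  g <- igraph::graph_from_adjacency_matrix(d <= nn_max, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  out <- lapply(keep, function(k) {
    ids <- sort(vesicles$id[comp$membership == k])
    list(member_ids = ids, n_vesicles = length(ids), n_docked = NA_integer_,
         area = NA_real_)
  })
  out[order(vapply(out, function(b) min(b$member_ids), numeric(1)))]
}

#' Classify axonal transport vesicles
#'
#' Axonal vesicles are vesicles of diameter <= `max_diam` nm whose center lies
#' within the axon-segment footprint and at least `min_dist` nm
#' (center-to-center, inclusive: exactly `min_dist` qualifies) from the center
#' of every bouton-member vesicle.
#'
#' @param vesicles vesicle table for the scene.
#' @param boutons bouton list from [cluster_boutons()].
#' @param segment a valid [axon_segment()].
#' @param min_dist exclusion distance from bouton vesicle centers, nm.
#' @param max_diam maximal qualifying diameter, nm.
#' @return subset of `vesicles` that qualify as axonal.
#' @export
classify_axonal_vesicles <- function(vesicles, boutons, segment,
                                     min_dist = 150, max_diam = 50) {
  .check_vesicles(vesicles)
  stopifnot(inherits(segment, "axon_segment"))
  if (!segment$valid) {
    stop("axon segment fails validity criteria (length >= 1 um and width ",
         "within 0.2-0.75 um)", call. = FALSE)
  }
  if (nrow(vesicles) == 0) return(vesicles)
  ok_diam <- vesicles$diameter_nm <= max_diam
  half_w_nm <- segment$width * 1000 / 2
  d_axis <- dist_to_polyline(as.matrix(vesicles[, c("x_nm", "y_nm")]),
                             segment$centerline)
  in_shaft <- d_axis <= half_w_nm
  member_ids <- unlist(lapply(boutons, `[[`, "member_ids"))
  far <- rep(TRUE, nrow(vesicles))
  if (length(member_ids)) {
    bx <- vesicles[match(member_ids, vesicles$id), c("x_nm", "y_nm")]
    for (i in seq_len(nrow(vesicles))) {
      far[i] <- all((bx$x_nm - vesicles$x_nm[i])^2 +
                      (bx$y_nm - vesicles$y_nm[i])^2 >= min_dist^2)
    }
  }
  not_member <- !(vesicles$id %in% member_ids)
  vesicles[ok_diam & in_shaft & far & not_member, , drop = FALSE]
}

#' Axonal vesicle density
#'
#' @param axonal_vesicles table from [classify_axonal_vesicles()].
#' @param segment the [axon_segment()] they were measured on.
#' @return vesicles per um of axon.
#' @export
axonal_vesicle_density <- function(axonal_vesicles, segment) {
  stopifnot(inherits(segment, "axon_segment"))
  if (!segment$valid) stop("axon segment fails validity criteria",
                           call. = FALSE)
  if (segment$length <= 0) stop("zero-length segment", call. = FALSE)
  nrow(axonal_vesicles) / segment$length
}

#' Count docked vesicles in a bouton
#'
#' A vesicle is docked when there is no visible gap between its membrane and
#' the presynaptic plasma membrane opposed to the PSD; operationally, its
#' circle edge is within `contact_eps` nm of the membrane and its center
#' projects perpendicularly onto the PSD span.
#'
#' @param bouton a bouton from [cluster_boutons()].
#' @param vesicles the scene vesicle table.
#' @param membranes list with `plasma_membrane` and `psd_span` polylines (nm).
#' @param contact_eps maximal membrane-to-membrane gap still counted as
#'   contact, nm.
#' @return integer count of docked vesicles.
#' @export
count_docked <- function(bouton, vesicles, membranes, contact_eps = 2) {
  .check_vesicles(vesicles)
  if (is.null(membranes$psd_span)) {
    stop("membrane annotation lacks psd_span", call. = FALSE)
  }
  mem <- vesicles[vesicles$id %in% bouton$member_ids, , drop = FALSE]
  if (nrow(mem) == 0) return(0L)
  d <- dist_to_polyline_interior(as.matrix(mem[, c("x_nm", "y_nm")]),
                                 as.matrix(membranes$psd_span))
  gap <- d - mem$diameter_nm / 2
  sum(is.finite(gap) & gap <= contact_eps)
}

#' Classify endosomes and per-bouton endosome area fraction
#'
#' An intracellular structure is an endosome when its diameter is strictly
#' greater than 50 nm and it has a clear lumen (an annotation flag; lumen
#' clarity is a visual criterion that cannot be computed from point
#' annotations).
#'
#' @param annotations data.frame with `bouton`, `diameter_nm`, `lumen`, and
#'   optionally `area_um2` columns.
#' @param boutons optional data.frame with `bouton` and `area_um2` giving
#'   bouton areas; fractions are NA where the bouton area is missing.
#' @param min_diam diameter above which (strictly) a structure can qualify,
#'   nm.
#' @return list with `endosomes` (the qualifying annotation rows) and
#'   `fractions` (data.frame `bouton`, `endosome_area_um2`, `fraction`).
#' @export
classify_endosomes <- function(annotations, boutons = NULL, min_diam = 50) {
  stopifnot(all(c("bouton", "diameter_nm", "lumen") %in% names(annotations)))
  is_endo <- annotations$diameter_nm > min_diam & annotations$lumen
  endo <- annotations[is_endo, , drop = FALSE]
  if (!"area_um2" %in% names(endo)) {
    endo$area_um2 <- pi * (endo$diameter_nm / 2)^2 / 1e6
  }
  fr <- NULL
  if (!is.null(boutons) && nrow(boutons)) {
    fr <- data.frame(bouton = boutons$bouton,
                     endosome_area_um2 = 0, fraction = NA_real_)
    if (nrow(endo)) {
      agg <- stats::aggregate(area_um2 ~ bouton, data = endo, FUN = sum)
      idx <- match(agg$bouton, fr$bouton)
      fr$endosome_area_um2[idx[!is.na(idx)]] <- agg$area_um2[!is.na(idx)]
    }
    has_area <- is.finite(boutons$area_um2) & boutons$area_um2 > 0
    fr$fraction[has_area] <- fr$endosome_area_um2[has_area] /
      boutons$area_um2[has_area]
  }
  list(endosomes = endo, fractions = fr)
}

#' Count mitochondrion-tethered vesicles
#'
#' Counts vesicles of diameter <= `max_diam` whose membrane-to-surface
#' distance (circle edge to polygon boundary) is at most `dist_max` nm
#' (inclusive), and normalizes the count to a 3-um mitochondrial perimeter.
#'
#' @param mito a [mitochondrion()] object.
#' @param vesicles vesicle table, nm coordinates.
#' @param dist_max maximal tether distance, nm.
#' @param max_diam maximal qualifying vesicle diameter, nm.
#' @param measure `"edge"` (default, membrane-to-membrane) or `"center"`
#'   (vesicle center to boundary).
#' @return list with `count`, `per_3um` (= count x 3 / perimeter_um), and
#'   `tethered_ids`.
#' @export
count_tethered <- function(mito, vesicles, dist_max = 70, max_diam = 50,
                           measure = c("edge", "center")) {
  stopifnot(inherits(mito, "mitochondrion"))
  measure <- match.arg(measure)
  .check_vesicles(vesicles)
  if (nrow(vesicles) == 0) {
    return(list(count = 0L, per_3um = 0, tethered_ids = integer()))
  }
  xy <- as.matrix(vesicles[, c("x_nm", "y_nm")])
  d <- dist_to_polygon(xy, mito$boundary)
  if (measure == "edge") d <- d - vesicles$diameter_nm / 2
  inside <- point_in_polygon(xy, mito$boundary)
  teth <- !inside & vesicles$diameter_nm <= max_diam & d <= dist_max
  list(count = sum(teth), per_3um = sum(teth) * 3 / mito$perimeter,
       tethered_ids = vesicles$id[teth])
}
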