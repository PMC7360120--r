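# Synthetic electron-microscopy scenes. Geometry is 2-D in nm (x rightward,
# y downward) matching a single ultrathin section; vesicles are circles,
# membranes analytic polylines. Every generated object carries a ground-truth
# label so downstream classifiers can be checked by parameter recovery.

#' Generate a synthetic EM scene with ground truth
#'
#' Builds one annotated section: a straight axon shaft of the stated width,
#' `n_boutons` en passant boutons (vesicle clusters sampled so every within-
#' cluster nearest-neighbor distance is at most `bouton_nn_spacing`), docked
#' vesicles touching the PSD-opposed plasma membrane, endosome-like
#' structures, and a Poisson process of axonal transport vesicles along the
#' shaft thinned of any point within 150 nm of a bouton vesicle center.
#'
#' @param params an [em_scene_params()] object.
#' @return a list with elements `scene` (class `em_scene`: `vesicles`,
#'   `axon_segment`, `membranes`, `boutons`, `endosomes`) and `truth` (class
#'   `ground_truth`: generating parameters plus per-vesicle labels).
#' @examples
#' out <- gen_em_scene(em_scene_params(seed = 7))
#' table(out$truth$vesicle_labels$label)
#' @export
gen_em_scene <- function(params) {
  stopifnot(inherits(params, "em_scene_params"))
  withr::with_seed(params$seed, .gen_em_scene_impl(params))
}

.gen_em_scene_impl <- function(p) {
  L <- p$axon_length * 1000            # nm
  half_w <- p$axon_width * 1000 / 2
  psd_half <- 150                      # PSD half-span, nm
  membrane_y <- 400                    # PSD-opposed membrane depth below axis

  ves <- list(); labels <- list()
  membranes <- list(); bouton_rows <- list(); endo <- list()
  next_id <- 1L

  for (b in seq_len(p$n_boutons)) {
    cx <- (b - 0.5) * L / p$n_boutons
    n_b <- max(20L, stats::rpois(1, p$vesicles_per_bouton))
    n_docked <- round(p$docked_fraction * n_b)
    r_b <- max(150, p$bouton_nn_spacing * sqrt(n_b) * 0.7)
    cl <- .sample_cluster(n_b - n_docked, cx, membrane_y, r_b,
                          p$bouton_nn_spacing,
                          p$vesicle_diameter_mean, p$vesicle_diameter_sd)
    docked <- .place_docked(n_docked, cx, membrane_y, psd_half,
                            p$vesicle_diameter_mean, p$vesicle_diameter_sd)
    all_b <- rbind(cl, docked)
    ids <- seq.int(next_id, length.out = nrow(all_b))
    next_id <- next_id + nrow(all_b)
    ves[[b]] <- data.frame(id = ids, x_nm = all_b[, 1], y_nm = all_b[, 2],
                           diameter_nm = all_b[, 3])
    labels[[b]] <- data.frame(
      id = ids, label = "bouton", bouton = b,
      docked = c(rep(FALSE, nrow(cl)), rep(TRUE, nrow(docked))))
    membranes[[b]] <- list(
      plasma_membrane = cbind(c(cx - 500, cx + 500),
                              c(membrane_y, membrane_y)),
      psd_span = cbind(c(cx - psd_half, cx + psd_half),
                       c(membrane_y, membrane_y)))
    bouton_rows[[b]] <- data.frame(
      bouton = b, center_x_nm = cx, center_y_nm = membrane_y - r_b / 2,
      area_um2 = pi * r_b^2 / 2 / 1e6)
    endo[[b]] <- .sample_endosomes(b, cx, membrane_y, r_b, p$endosome_rate)
  }

  bouton_ves <- if (length(ves)) do.call(rbind, ves) else
    data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
               diameter_nm = numeric())

  # axonal transport vesicles: Poisson along the shaft, dropped if within
  # 150 nm (center-to-center) of any bouton vesicle
  n_ax <- stats::rpois(1, p$axonal_vesicle_rate * p$axon_length)
  ax <- NULL
  if (n_ax > 0) {
    d <- pmin(50, rtruncnorm_pos(n_ax, p$vesicle_diameter_mean,
                                 p$vesicle_diameter_sd, lower = 10))
    x <- stats::runif(n_ax, 0, L)
    ymax <- pmax(0, half_w - d / 2)
    y <- stats::runif(n_ax, -ymax, ymax)
    keep <- rep(TRUE, n_ax)
    if (nrow(bouton_ves)) {
      for (i in seq_len(n_ax)) {
        keep[i] <- all((bouton_ves$x_nm - x[i])^2 +
                         (bouton_ves$y_nm - y[i])^2 >= 150^2)
      }
    }
    if (any(keep)) {
      ids <- seq.int(next_id, length.out = sum(keep))
      next_id <- next_id + sum(keep)
      ax <- data.frame(id = ids, x_nm = x[keep], y_nm = y[keep],
                       diameter_nm = d[keep])
      labels[[length(labels) + 1L]] <-
        data.frame(id = ids, label = "axonal", bouton = NA_integer_,
                   docked = FALSE)
    }
  }

  vesicles <- rbind(bouton_ves, ax)
  rownames(vesicles) <- NULL
  vlab <- if (length(labels)) do.call(rbind, labels) else
    data.frame(id = integer(), label = character(), bouton = integer(),
               docked = logical())
  rownames(vlab) <- NULL

  segment <- axon_segment(
    centerline = cbind(c(0, L), c(0, 0)),
    width = p$axon_width, length = p$axon_length)

  scene <- structure(list(
    vesicles = vesicles,
    axon_segment = segment,
    membranes = membranes,
    boutons = if (length(bouton_rows)) do.call(rbind, bouton_rows) else
      data.frame(bouton = integer(), center_x_nm = numeric(),
                 center_y_nm = numeric(), area_um2 = numeric()),
    endosomes = if (length(endo)) do.call(rbind, endo) else
      .empty_endosomes()), class = "em_scene")

  truth <- structure(list(
    params = unclass(p),
    vesicle_labels = vlab,
    n_axonal = sum(vlab$label == "axonal"),
    n_boutons = p$n_boutons), class = "ground_truth")

  list(scene = scene, truth = truth)
}

# Sequential cluster sampler: each new vesicle is placed within one
# nearest-neighbor spacing of an existing one, inside a half-disc of radius
# r_b resting on the membrane, keeping a soft minimal separation. The
# construction guarantees every member's nearest neighbor is <= spacing.
.sample_cluster <- function(n, cx, membrane_y, r_b, spacing,
                            d_mean, d_sd) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  d <- rtruncnorm_pos(n, d_mean, d_sd, lower = 10)
  xs <- numeric(n); ys <- numeric(n)
  cy <- membrane_y - 10
  xs[1] <- cx; ys[1] <- membrane_y - max(r_b / 2, d[1] / 2 + 8)
  min_sep <- 0.55 * spacing
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in 1:200) {
      parent <- sample.int(i - 1L, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0.7, 1) * spacing
      x <- xs[parent] + r * cos(ang)
      y <- ys[parent] + r * sin(ang)
      in_region <- ((x - cx)^2 + (y - cy)^2 <= r_b^2) &&
        y <= membrane_y - (d[i] / 2 + 8)
      if (!in_region) next
      if (try <= 150 &&
          min((xs[1:(i - 1)] - x)^2 + (ys[1:(i - 1)] - y)^2) < min_sep^2)
        next
      xs[i] <- x; ys[i] <- y; placed <- TRUE; break
    }
    if (!placed) { # fall back onto the parent's ring regardless of overlap
      parent <- sample.int(i - 1L, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      xs[i] <- xs[parent] + 0.8 * spacing * cos(ang)
      ys[i] <- min(ys[parent] + 0.8 * spacing * sin(ang),
                   membrane_y - (d[i] / 2 + 8))
    }
  }
  cbind(xs, ys, d)
}

# Docked vesicles: evenly spread on the PSD span, circle edge touching the
# membrane (zero gap).
.place_docked <- function(n, cx, membrane_y, psd_half, d_mean, d_sd) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  d <- rtruncnorm_pos(n, d_mean, d_sd, lower = 10)
  span <- min(2 * psd_half, max(60, (n - 1) * 60))
  xs <- if (n == 1) cx else cx + seq(-span / 2, span / 2, length.out = n)
  cbind(xs, membrane_y - d / 2, d)
}

.sample_endosomes <- function(b, cx, membrane_y, r_b, rate) {
  n_e <- stats::rpois(1, rate)
  n_d <- stats::rpois(1, rate)   # distractors failing one criterion each
  n <- n_e + n_d
  if (n == 0) return(.empty_endosomes())
  ang <- stats::runif(n, pi, 2 * pi)
  rad <- sqrt(stats::runif(n)) * r_b * 0.8
  diam <- c(stats::runif(n_e, 60, 150),
            ifelse(stats::runif(n_d) < 0.5, stats::runif(n_d, 30, 50),
                   stats::runif(n_d, 60, 100)))
  lumen <- c(rep(TRUE, n_e), diam[(n_e + 1):n][seq_len(n_d)] <= 50)
  if (n_d > 0) lumen[(n_e + 1):n] <- diam[(n_e + 1):n] <= 50
  data.frame(bouton = b, x_nm = cx + rad * cos(ang),
             y_nm = membrane_y - 10 + rad * sin(ang), diameter_nm = diam,
             lumen = lumen,
             area_um2 = pi * (diam / 2)^2 / 1e6)
}

.empty_endosomes <- function() {
  data.frame(bouton = integer(), x_nm = numeric(), y_nm = numeric(),
             diameter_nm = numeric(), lumen = logical(), area_um2 = numeric())
}

#' Generate a synthetic mitochondrion-tethering scene
#'
#' One elliptical mitochondrion of the stated perimeter, surface-tethered
#' vesicles whose membrane-to-surface distance is at most
#' `tether_distance_max`, and background vesicles placed strictly beyond that
#' distance, so ground-truth tether labels are exact.
#'
#' @param params a [mito_scene_params()] object.
#' @return list with `scene` (class `mito_scene`: `mito` polygon +
#'   perimeter, `vesicles`) and `truth` (per-vesicle `tethered` labels).
#' @export
gen_mito_scene <- function(params) {
  stopifnot(inherits(params, "mito_scene_params"))
  withr::with_seed(params$seed, .gen_mito_scene_impl(params))
}

.gen_mito_scene_impl <- function(p) {
  P_nm <- p$perimeter * 1000
  # ellipse with axis ratio 2:1 scaled to the requested perimeter
  a <- P_nm / 4.844224
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  poly <- cbind(a * cos(theta), a / 2 * sin(theta))
  perim_um <- polygon_perimeter(poly) / 1000
  centroid <- colMeans(poly)

  n_teth <- stats::rpois(1, p$tethered_density * perim_um / 3)
  rows <- list()
  id <- 1L
  if (n_teth > 0) {
    for (i in seq_len(n_teth)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        bp <- c(a * cos(th), a / 2 * sin(th))
        u <- bp - centroid; u <- u / sqrt(sum(u^2))
        d <- pmin(50, rtruncnorm_pos(1, p$vesicle_diameter_mean,
                                     p$vesicle_diameter_sd, lower = 10))
        gap <- stats::runif(1, 1, p$tether_distance_max - 5)
        ctr <- bp + u * (d / 2 + gap)
        edge <- dist_to_polygon(rbind(ctr), poly) - d / 2
        if (edge > 0 && edge <= p$tether_distance_max &&
            !point_in_polygon(rbind(ctr), poly)) break
      }
      rows[[id]] <- data.frame(id = id, x_nm = ctr[1], y_nm = ctr[2],
                               diameter_nm = d, tethered = TRUE)
      id <- id + 1L
    }
  }

  margin <- 1000
  xr <- range(poly[, 1]) + c(-margin, margin)
  yr <- range(poly[, 2]) + c(-margin, margin)
  area_um2 <- diff(xr) * diff(yr) / 1e6
  n_bg <- stats::rpois(1, p$background_density * area_um2)
  if (n_bg > 0) {
    for (i in seq_len(n_bg)) {
      repeat {
        ctr <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
        d <- pmin(50, rtruncnorm_pos(1, p$vesicle_diameter_mean,
                                     p$vesicle_diameter_sd, lower = 10))
        edge <- dist_to_polygon(rbind(ctr), poly) - d / 2
        if (!point_in_polygon(rbind(ctr), poly) &&
            edge > p$tether_distance_max + 1) break
      }
      rows[[id]] <- data.frame(id = id, x_nm = ctr[1], y_nm = ctr[2],
                               diameter_nm = d, tethered = FALSE)
      id <- id + 1L
    }
  }

  vesicles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
               diameter_nm = numeric(), tethered = logical())
  rownames(vesicles) <- NULL

  scene <- structure(list(
    mito = mitochondrion(poly),
    vesicles = vesicles[, c("id", "x_nm", "y_nm", "diameter_nm")]),
    class = "mito_scene")
  truth <- structure(list(
    params = unclass(p),
    tether_labels = vesicles[, c("id", "tethered")],
    n_tethered = sum(vesicles$tethered)), class = "ground_truth")
  list(scene = scene, truth = truth)
}
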