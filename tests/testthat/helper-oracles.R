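# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately share no code with the package
# implementation: components by hand-rolled breadth-first search on the full
# O(n^2) distance matrix, filters by explicit all-pairs loops.

# connected components of the <= nn_max center-distance graph, BFS
oracle_components <- function(xy, nn_max) {
  n <- nrow(xy)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in seq_len(n)) {
        if (!is.na(comp[k])) next
        if (sqrt((xy[j, 1] - xy[k, 1])^2 + (xy[j, 2] - xy[k, 2])^2) <=
            nn_max) {
          comp[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  comp
}

# bouton member-id sets by the oracle, as a canonical sorted list
oracle_boutons <- function(vesicles, nn_max = 100, min_size = 20) {
  if (nrow(vesicles) == 0) return(list())
  comp <- oracle_components(as.matrix(vesicles[, c("x_nm", "y_nm")]), nn_max)
  sets <- unname(lapply(split(vesicles$id, comp), sort))
  sets <- Filter(function(s) length(s) >= min_size, sets)
  sets[order(vapply(sets, min, numeric(1)))]
}

# axonal vesicle ids by explicit all-pairs filtering
oracle_axonal_ids <- function(vesicles, bouton_sets, half_w_nm,
                              min_dist = 150, max_diam = 50) {
  member <- unlist(bouton_sets)
  keep <- c()
  for (i in seq_len(nrow(vesicles))) {
    v <- vesicles[i, ]
    if (v$id %in% member) next
    if (v$diameter_nm > max_diam) next
    if (abs(v$y_nm) > half_w_nm) next
    ok <- TRUE
    for (id in member) {
      b <- vesicles[vesicles$id == id, ]
      if (sqrt((b$x_nm - v$x_nm)^2 + (b$y_nm - v$y_nm)^2) < min_dist) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, v$id)
  }
  sort(keep)
}

# random vesicle scene in a box, clustered enough that components are
# nontrivial
random_scene <- function(n, box_nm = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(id = seq_len(n),
             x_nm = runif(n, 0, box_nm),
             y_nm = runif(n, 0, box_nm) - box_nm / 2,
             diameter_nm = runif(n, 25, 60))
}

# bouton member sets from the package implementation, canonicalized
impl_bouton_sets <- function(boutons) {
  lapply(boutons, function(b) sort(b$member_ids))
}

# noiseless synthetic kymograph from (t, x) particle paths; amplitude 100
# Gaussian ridges of sigma ~1.3 steps on an n_pos grid
make_kymograph <- function(paths, n_frames, n_pos, step_nm = 160,
                           dt = 1, noise_sd = 0) {
  g <- matrix(0, n_frames, n_pos)
  for (p in paths) {
    for (k in seq_len(n_frames)) {
      t <- (k - 1) * dt
      if (t < min(p$t) || t > max(p$t)) next
      x <- approx(p$t, p$x, xout = t, ties = "ordered")$y
      xs <- x * 1000 / step_nm          # um -> steps
      j <- 0:(n_pos - 1)
      g[k, ] <- g[k, ] + 100 * exp(-(j - xs)^2 / (2 * 1.3^2))
    }
  }
  if (noise_sd > 0) g <- g + matrix(rnorm(length(g), 0, noise_sd),
                                    nrow(g))
  structure(list(grid = pmax(g, 0), position_step = step_nm,
                 time_step = dt), class = "kymograph")
}

# image channel with constant background and rectangular bright patches
# given as list(rows, cols, value)
patch_channel <- function(nrow, ncol, patches, pixel_size = 20,
                          background = 0) {
  g <- matrix(background, nrow, ncol)
  for (p in patches) g[p$rows, p$cols] <- p$value
  image_channel(g, pixel_size)
}
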