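# Kymograph construction, stationary detection, synapse confirmation, path
# tracing and the transport statistics.

test_that("static movies give kymographs with identical rows", {
  set.seed(1)
  f <- matrix(runif(9 * 50), 9, 50)
  movie <- list(frames = list(f, f, f), frame_interval = 1,
                pixel_size = 160)
  k <- build_kymograph(movie, path = cbind(0:49, rep(4, 50)))
  expect_equal(k$grid[1, ], k$grid[2, ])
  expect_equal(k$grid[1, ], k$grid[3, ])
})

test_that("kymograph ridge slope matches the particle velocity", {
  # particle at v = 0.5 um/s on a noiseless movie
  p <- motility_params(entry_rate = 0, n_stationary = 0, snr = 300,
                       seed = 2, duration = 30)
  out <- gen_timelapse(p)
  v <- 0.5
  frames <- lapply(seq_along(out$movie$frames), function(k) {
    img <- matrix(0, 9, ncol(out$movie$frames[[1]]))
    presyncapture:::.add_punctum(img, (5 + v * (k - 1)) * 1000 / 160, 4,
                                 200 / 160, 1)
  })
  movie <- list(frames = frames, frame_interval = 1, pixel_size = 160,
                path = out$movie$path)
  k <- build_kymograph(movie)
  ridge <- apply(k$grid, 1, which.max)
  fit <- stats::lm(ridge ~ seq_along(ridge))
  v_steps <- coef(fit)[2] * k$position_step / 1000
  expect_lt(abs(v_steps - v), k$position_step / 1000)  # within 1 step/frame

  k1 <- build_kymograph(movie, line_width = 1)
  expect_equal(apply(k1$grid, 1, which.max), ridge)
})

test_that("path leaving the frame errors", {
  movie <- list(frames = list(matrix(1, 9, 50), matrix(1, 9, 50)),
                frame_interval = 1, pixel_size = 160)
  expect_error(build_kymograph(movie, path = cbind(0:60, rep(4, 61))),
               "bounds")
})

test_that("stationary detection requires full-duration presence", {
  # two bars: one full duration, one missing in the last frame
  g <- matrix(0, 120, 100)
  g[, 20] <- 100
  g[1:119, 60] <- 100
  k <- structure(list(grid = g, position_step = 160, time_step = 1),
                 class = "kymograph")
  res <- detect_stationary(k)
  expect_identical(res$count, 1L)
  expect_lt(abs(res$objects$position_um - 19 * 0.16), 0.16)
})

test_that("stationary density normalizes to 10 um of axon", {
  out <- gen_timelapse(motility_params(n_stationary = 5, entry_rate = 0,
                                       seed = 6))
  k <- build_kymograph(out$movie)
  res <- detect_stationary(k)
  expect_identical(res$count, 5L)
  expect_equal(res$density_per_10um, 5 * 10 / ((ncol(k$grid) - 1) * 0.16),
               tolerance = 1e-9)
})

test_that("synapse confirmation rejects transient puncta", {
  img <- matrix(0, 20, 100)
  pre <- img; pre[8:12, 10:14] <- 100; pre[8:12, 50:54] <- 100
  post <- img; post[8:12, 10:14] <- 100; post[8:12, 80:84] <- 100
  res <- confirm_synapse_objects(pre, post)
  expect_identical(res$n_objects, 1L)
  expect_true(all(which(res$mask, arr.ind = TRUE)[, 2] %in% 10:14))

  same <- confirm_synapse_objects(pre, pre)
  expect_identical(same$n_objects, 2L)
})

test_that("synaptic fraction counts >0-pixel overlaps", {
  stat <- list(objects = data.frame(position_um = c(1, 5),
                                    col_lo = c(5, 30), col_hi = c(8, 33)),
               count = 2L)
  profile_all <- rep(FALSE, 50); profile_all[c(5:8, 30:33)] <- TRUE
  expect_equal(synaptic_fraction(stat, profile_all)$fraction, 1)
  expect_equal(synaptic_fraction(stat, rep(FALSE, 50))$fraction, 0)
  none <- list(objects = data.frame(position_um = numeric(),
                                    col_lo = integer(),
                                    col_hi = integer()), count = 0L)
  expect_true(is.na(synaptic_fraction(none, profile_all)$fraction))
})

test_that("generated synaptic fraction is recovered by the pipeline", {
  fr <- c()
  for (s in 1:8) {
    res <- run_motility_pipeline(motility_params(entry_rate = 2, seed = s))
    fr <- c(fr, res$summary$synaptic_fraction)
  }
  # 0.8 of 5 stationary puncta are synaptic; binomial CI over 40 puncta
  expect_lt(abs(mean(fr) - 0.8), 3 * sqrt(0.8 * 0.2 / 40))
})

test_that("tracing resolves runs and pauses on constructed ridges", {
  # single constant-velocity ridge
  k <- make_kymograph(list(list(t = c(0, 60), x = c(2, 26))),
                      n_frames = 60, n_pos = 200)
  ev <- trace_moving_paths(k)
  expect_length(ev, 1)
  sp <- event_speeds(ev[[1]])
  expect_identical(sp$n_moving_segments, 1L)
  expect_equal(sp$instant_speed, 0.4, tolerance = 0.02)

  # ridge with a 10-s pause: one event, two moving segments, one pause
  path <- list(t = c(0, 25, 35, 60), x = c(2, 12, 12, 22))
  k2 <- make_kymograph(list(path), n_frames = 60, n_pos = 200)
  ev2 <- trace_moving_paths(k2)
  expect_length(ev2, 1)
  sp2 <- event_speeds(ev2[[1]])
  expect_identical(sp2$n_moving_segments, 2L)
  expect_equal(sp2$pause_time, 10, tolerance = 2)
  expect_lt(sp2$net_speed, sp2$instant_speed)
})

test_that("flux is events per 100 um per minute", {
  evs <- replicate(4, track_event(c(0, 10), c(0, 2)), simplify = FALSE)
  expect_equal(compute_flux(evs, 50, 2), 4)
  expect_equal(compute_flux(list(), 50, 2), 0)
  expect_error(compute_flux(evs, 0, 2), "positive")
})

test_that("event speeds follow their definitions", {
  e1 <- track_event(c(0, 10), c(0, 2), labels = "run")
  s1 <- event_speeds(e1)
  expect_equal(s1$instant_speed, 0.2)
  expect_equal(s1$net_speed, 0.2)

  e2 <- track_event(c(0, 50, 100), c(0, 5, 5), labels = c("run", "pause"))
  s2 <- event_speeds(e2)
  expect_equal(s2$instant_speed, 0.1)
  expect_equal(s2$net_speed, 0.05)

  # net speed never exceeds instant speed on simulated run-and-pause paths
  out <- gen_timelapse(motility_params(pause_rate = 0.1, seed = 21))
  for (ev in out$truth$events) {
    sp <- event_speeds(ev)
    if (!is.na(sp$instant_speed)) {
      expect_lte(sp$net_speed, sp$instant_speed + 1e-9)
    }
  }
})

test_that("flux is additive over concatenated equal-rate movies", {
  e1 <- replicate(3, track_event(c(0, 10), c(0, 2)), simplify = FALSE)
  e2 <- replicate(5, track_event(c(0, 10), c(0, 2)), simplify = FALSE)
  f_pooled <- compute_flux(c(e1, e2), 50, 4)
  f_avg <- (compute_flux(e1, 50, 2) + compute_flux(e2, 50, 2)) / 2
  expect_equal(f_pooled, f_avg)
})
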