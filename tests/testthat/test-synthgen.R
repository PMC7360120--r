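# Generators: determinism, ground-truth completeness, zero-rate edge cases
# and Monte-Carlo agreement of realized counts with their analytic means.

test_that("generators are deterministic given seed and parameters", {
  p <- em_scene_params(seed = 42)
  expect_identical(gen_em_scene(p), gen_em_scene(p))
  expect_false(identical(gen_em_scene(p),
                         gen_em_scene(em_scene_params(seed = 43))))

  ps <- sideview_params(n_synapses = 2, seed = 5)
  expect_identical(gen_sideview_stack(ps), gen_sideview_stack(ps))

  pm <- motility_params(seed = 5, duration = 20)
  expect_identical(gen_timelapse(pm), gen_timelapse(pm))

  pq <- mito_scene_params(seed = 5)
  expect_identical(gen_mito_scene(pq), gen_mito_scene(pq))
})

test_that("every generated vesicle carries exactly one ground-truth label", {
  out <- gen_em_scene(em_scene_params(seed = 3))
  expect_setequal(out$truth$vesicle_labels$id, out$scene$vesicles$id)
  expect_false(anyDuplicated(out$truth$vesicle_labels$id) > 0)

  m <- gen_mito_scene(mito_scene_params(seed = 3))
  expect_setequal(m$truth$tether_labels$id, m$scene$vesicles$id)
})

test_that("zero rates produce zero objects", {
  out <- gen_em_scene(em_scene_params(axonal_vesicle_rate = 0, seed = 1))
  expect_identical(out$truth$n_axonal, 0L)

  mv <- gen_timelapse(motility_params(entry_rate = 0, duration = 10,
                                      seed = 1))
  expect_length(mv$truth$events, 0)

  mt <- gen_mito_scene(mito_scene_params(tethered_density = 0, seed = 1))
  expect_identical(mt$truth$n_tethered, 0L)
})

test_that("without pauses every ground-truth path moves at run speed", {
  out <- gen_timelapse(motility_params(pause_rate = 0, run_speed = 0.4,
                                       seed = 8))
  for (ev in out$truth$events) {
    sp <- event_speeds(ev)
    expect_equal(sp$instant_speed, 0.4, tolerance = 1e-9)
    expect_equal(sp$net_speed, 0.4, tolerance = 1e-9)
  }
})

test_that("realized axonal-vesicle counts match the Poisson mean", {
  # rate 2 per um on a 50-um axon without boutons: mean count 100
  counts <- vapply(1:200, function(s) {
    gen_em_scene(em_scene_params(axon_length = 50, n_boutons = 0,
                                 axonal_vesicle_rate = 2,
                                 seed = s))$truth$n_axonal
  }, numeric(1))
  se <- sqrt(100 / 200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("realized entry counts match the Poisson mean", {
  # 8 per 100 um per min on 50 um for 2 min: mean 8 events per movie
  counts <- vapply(1:60, function(s) {
    gen_timelapse(motility_params(seed = s))$truth$n_events
  }, numeric(1))
  se <- sqrt(8 / 60)
  expect_lt(abs(mean(counts) - 8), 3 * se)
})

test_that("realized tethered counts match the density definition", {
  # density 4 per 3 um at perimeter 3 um: mean 4 tethered vesicles
  counts <- vapply(1:100, function(s) {
    gen_mito_scene(mito_scene_params(seed = s))$truth$n_tethered
  }, numeric(1))
  se <- sqrt(4 / 100)
  expect_lt(abs(mean(counts) - 4), 3 * se)
})

test_that("noiseless-limit target channel peaks at the true offset", {
  p <- sideview_params(n_synapses = 3, target_offset = -100, snr = 300,
                       seed = 2)
  out <- gen_sideview_stack(p)
  for (s in 1:3) {
    tr <- out$truth$synapses[s, ]
    g <- out$synapses[[s]]$channels$target$grid
    idx <- arrayInd(which.max(g), dim(g))
    ps <- p$pixel_size
    x <- (idx[2] - 0.5) * ps
    y <- (idx[1] - 0.5) * ps
    true_x <- tr$center_x_nm + tr$target_offset_nm * tr$axis_x
    true_y <- tr$center_y_nm + tr$target_offset_nm * tr$axis_y
    # the target ridge is elongated along the bar, so constrain the offset
    # component along the profile axis
    off <- (x - tr$center_x_nm) * tr$axis_x + (y - tr$center_y_nm) * tr$axis_y
    expect_lt(abs(off - tr$target_offset_nm), 1.5 * ps)
    expect_true(is.finite(true_x) && is.finite(true_y))
  }
})

test_that("parameter validation rejects impossible geometry", {
  expect_error(em_scene_params(bouton_nn_spacing = 150), "bouton_nn_spacing")
  expect_error(em_scene_params(axon_width = 1.5), "axon_width")
  expect_error(sideview_params(psf_sigma_sted = 200,
                               psf_sigma_confocal = 100), "psf_sigma_sted")
  expect_error(motility_params(duration = 10, frame_interval = 3),
               "integer multiple")
  expect_error(mito_scene_params(perimeter = 0), "perimeter")
})
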