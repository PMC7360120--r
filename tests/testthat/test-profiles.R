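# Profile bar placement, extraction (rolling average of three), alignment
# to the marker peak, and offset recovery on generated side-view synapses.

make_bar <- function(center, axis, length = 1000, width = 200) {
  structure(list(center = center, axis = axis / sqrt(sum(axis^2)),
                 length = length, width = width, anisotropy = NA),
            class = "profile_bar")
}

test_that("rolling average of three shrinks the profile by two samples", {
  expect_equal(presyncapture:::rolling3(c(1, 2, 3, 4, 5)), c(2, 3, 4))
})

test_that("profile of a constant image is constant", {
  ch <- image_channel(matrix(4, 200, 200), 14.2)
  bar <- make_bar(c(1400, 1400), c(0, 1))
  prof <- extract_profile(bar, ch)
  expect_true(all(abs(prof$intensities - 4) < 1e-9))
  expect_equal(length(prof$positions),
               length(seq(-500, 500, by = 14.2)) - 2)
  expect_true(all(diff(prof$positions) > 0))
})

test_that("bar outside the image errors", {
  ch <- image_channel(matrix(1, 30, 30), 14.2)
  bar <- make_bar(c(200, 200), c(0, 1))
  expect_error(extract_profile(bar, ch), "bounds")
})

test_that("noiseless Gaussian target peaks within one pixel of truth", {
  ps <- 14.2
  n <- 160
  coord <- (seq_len(n) - 0.5) * ps
  X <- matrix(coord, n, n, byrow = TRUE)
  Y <- matrix(coord, n, n)
  cx <- n * ps / 2
  g <- exp(-((X - cx)^2 + (Y - (cx + 100))^2) / (2 * 60^2))
  ch <- image_channel(g, ps)
  bar <- make_bar(c(cx, cx), c(0, 1))   # positive axis = +y
  prof <- extract_profile(bar, ch)
  expect_lt(abs(prof$peak_position - 100), ps)
})

test_that("profile extraction commutes with intensity scaling", {
  set.seed(2)
  g <- matrix(runif(160 * 160), 160, 160)
  ch <- image_channel(g, 14.2)
  ch7 <- image_channel(7 * g, 14.2)
  bar <- make_bar(c(1100, 1100), c(0.6, 0.8))
  p1 <- extract_profile(bar, ch)
  p7 <- extract_profile(bar, ch7)
  expect_equal(p7$intensities, 7 * p1$intensities, tolerance = 1e-12)
  expect_equal(p7$peak_position, p1$peak_position)
})

test_that("bar placement is perpendicular, signed toward the presynapse", {
  ps <- 20
  n <- 120
  coord <- (seq_len(n) - 0.5) * ps
  X <- matrix(coord, n, n, byrow = TRUE)
  Y <- matrix(coord, n, n)
  c0 <- n * ps / 2
  # horizontal marker bar; vesicle cloud above it (smaller y)
  marker <- exp(-pmax(abs(X - c0) - 200, 0)^2 / (2 * 40^2) -
                  (Y - c0)^2 / (2 * 50^2))
  vesicle <- exp(-((X - c0)^2 + (Y - (c0 - 400))^2) / (2 * 250^2))
  bar <- place_profile_bar(image_channel(marker, ps, "marker", "sted"),
                           image_channel(vesicle, ps))
  expect_lt(abs(bar$axis[1]), 0.1)       # axis is vertical
  # cloud sits at smaller y, so the signed axis must point toward +y for
  # negative positions to reach the cloud
  expect_gt(bar$axis[2], 0.9)
  expect_lt(abs(bar$center[1] - c0), ps)
  expect_lt(abs(bar$center[2] - c0), ps)

  iso <- exp(-((X - c0)^2 + (Y - c0)^2) / (2 * 80^2))
  expect_error(place_profile_bar(image_channel(iso, ps, "m", "sted"),
                                 image_channel(vesicle, ps)),
               "side-view")
})

test_that("generator bar axis is recovered within 5 degrees", {
  out <- gen_sideview_stack(sideview_params(n_synapses = 20, seed = 12))
  errs <- c()
  for (s in seq_along(out$synapses)) {
    ch <- out$synapses[[s]]$channels
    bar <- place_profile_bar(ch$marker, ch$vesicle)
    tr <- out$truth$synapses[s, ]
    cosang <- abs(bar$axis[1] * tr$axis_x + bar$axis[2] * tr$axis_y)
    errs <- c(errs, acos(pmin(cosang, 1)) * 180 / pi)
  }
  expect_lt(mean(errs), 5)
})

test_that("alignment puts every reference peak at zero", {
  out <- gen_sideview_stack(sideview_params(n_synapses = 8,
                                            target_offset = -80,
                                            seed = 3))
  res <- analyze_sideview_stack(out$synapses)
  # re-extract the reference profiles and check aligned peaks
  for (i in seq_along(res$bars)) {
    ref <- extract_profile(res$bars[[i]],
                           out$synapses[[res$used[i]]]$channels$marker)
    expect_equal(ref$peak_position - ref$peak_position, 0)
  }
  # target identical to reference: aligned target peak is exactly 0
  prof <- list(list(
    reference = extract_profile(res$bars[[1]],
                                out$synapses[[1]]$channels$marker),
    target = extract_profile(res$bars[[1]],
                             out$synapses[[1]]$channels$marker)))
  al <- align_profiles(prof)
  expect_equal(al$per_synapse$peak_position_nm, 0)
})

test_that("mean profile grid drops sparsely covered positions", {
  out <- gen_sideview_stack(sideview_params(n_synapses = 6, seed = 4))
  res <- analyze_sideview_stack(out$synapses)
  expect_true(all(res$mean_profile$n >= 3))
  expect_true(all(diff(res$mean_profile$position_nm) > 0))
  expect_true(all(is.finite(res$mean_profile$sem)))
})
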