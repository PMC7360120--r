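# EM classification rules against constructed geometries and brute-force
# oracles.

test_that("bouton clustering handles the canonical constructions", {
  # 25-vesicle chain, successive spacing 80 nm: one bouton of 25
  chain <- data.frame(id = 1:25, x_nm = (0:24) * 80, y_nm = 0,
                      diameter_nm = 40)
  b <- cluster_boutons(chain)
  expect_length(b, 1)
  expect_identical(b[[1]]$n_vesicles, 25L)
  expect_identical(impl_bouton_sets(b), oracle_boutons(chain))

  # 19 mutually close vesicles: below the 20-vesicle minimum
  ang <- seq(0, 2 * pi, length.out = 20)[-20]
  small <- data.frame(id = 1:19, x_nm = 40 * cos(ang), y_nm = 40 * sin(ang),
                      diameter_nm = 40)
  expect_length(cluster_boutons(small), 0)

  # two 20-vesicle clusters 150 nm apart: two boutons
  c1 <- data.frame(id = 1:20, x_nm = (0:19) * 50, y_nm = 0,
                   diameter_nm = 40)
  c2 <- data.frame(id = 21:40, x_nm = (0:19) * 50 + 19 * 50 + 150,
                   y_nm = 0, diameter_nm = 40)
  two <- rbind(c1, c2)
  expect_length(cluster_boutons(two), 2)
  expect_identical(impl_bouton_sets(cluster_boutons(two)),
                   oracle_boutons(two))

  expect_length(cluster_boutons(chain[0, ]), 0)
})

test_that("clustering equals the brute-force component oracle on random
          scenes", {
  set.seed(99)
  for (i in 1:20) {
    sc <- random_scene(sample(50:300, 1))
    expect_identical(impl_bouton_sets(cluster_boutons(sc, min_size = 5)),
                     oracle_boutons(sc, min_size = 5))
  }
})

test_that("clustering is invariant to permutation and rigid motion", {
  sc <- random_scene(150, seed = 7)
  ref <- impl_bouton_sets(cluster_boutons(sc, min_size = 5))
  perm <- sc[sample(nrow(sc)), ]
  expect_identical(impl_bouton_sets(cluster_boutons(perm, min_size = 5)),
                   ref)
  th <- 0.7
  rot <- sc
  rot$x_nm <- cos(th) * sc$x_nm - sin(th) * sc$y_nm + 5000
  rot$y_nm <- sin(th) * sc$x_nm + cos(th) * sc$y_nm - 2000
  expect_identical(impl_bouton_sets(cluster_boutons(rot, min_size = 5)),
                   ref)
})

test_that("tie at exactly 100 nm counts as connected", {
  pair <- data.frame(id = 1:2, x_nm = c(0, 100), y_nm = 0, diameter_nm = 40)
  b <- cluster_boutons(pair, min_size = 2)
  expect_length(b, 1)
})

test_that("axonal classification applies the diameter and distance rules", {
  seg <- axon_segment(cbind(c(0, 10000), c(0, 0)), width = 0.4)
  bouton_ves <- data.frame(id = 1:20, x_nm = 5000 + (0:19) * 50, y_nm = 0,
                           diameter_nm = 40)
  boutons <- cluster_boutons(bouton_ves)
  expect_length(boutons, 1)

  probe <- data.frame(
    id = 21:24,
    x_nm = c(1000, 5000 - 140, 5000 - 150, 2000),
    y_nm = 0,
    diameter_nm = c(60, 40, 40, 40))
  all_ves <- rbind(bouton_ves, probe)
  ax <- classify_axonal_vesicles(all_ves, boutons, seg)
  expect_false(21 %in% ax$id)   # 60 nm diameter excluded
  expect_false(22 %in% ax$id)   # 140 nm from a bouton vesicle center
  expect_true(23 %in% ax$id)    # exactly 150 nm qualifies (inclusive)
  expect_true(24 %in% ax$id)

  bad_seg <- axon_segment(cbind(c(0, 500), c(0, 0)), width = 0.4)
  expect_false(bad_seg$valid)
  expect_error(classify_axonal_vesicles(all_ves, boutons, bad_seg),
               "validity")
})

test_that("axonal filter equals the brute-force all-pairs oracle", {
  set.seed(31)
  seg <- axon_segment(cbind(c(0, 2000), c(0, 0)), width = 0.5)
  for (i in 1:20) {
    sc <- random_scene(sample(50:300, 1))
    boutons <- cluster_boutons(sc, min_size = 5)
    got <- classify_axonal_vesicles(sc, boutons, seg)
    want <- oracle_axonal_ids(sc, impl_bouton_sets(boutons),
                              half_w_nm = 250)
    expect_identical(as.numeric(sort(got$id)), as.numeric(want))
  }
})

test_that("axonal set shrinks monotonically with stricter thresholds", {
  sc <- random_scene(200, seed = 17)
  seg <- axon_segment(cbind(c(0, 2000), c(0, 0)), width = 0.5)
  boutons <- cluster_boutons(sc, min_size = 5)
  base <- classify_axonal_vesicles(sc, boutons, seg)$id
  stricter_d <- classify_axonal_vesicles(sc, boutons, seg,
                                         min_dist = 250)$id
  smaller_diam <- classify_axonal_vesicles(sc, boutons, seg,
                                           max_diam = 40)$id
  expect_true(all(stricter_d %in% base))
  expect_true(all(smaller_diam %in% base))
})

test_that("axonal density is count over segment length", {
  seg <- axon_segment(cbind(c(0, 3000), c(0, 0)), width = 0.4)
  six <- data.frame(id = 1:6, x_nm = (1:6) * 400, y_nm = 0,
                    diameter_nm = 40)
  expect_equal(axonal_vesicle_density(six, seg), 2)
  expect_equal(axonal_vesicle_density(six[0, ], seg), 0)
})

test_that("docked counting respects contact tolerance and PSD span", {
  membranes <- list(
    plasma_membrane = cbind(c(-1000, 1000), c(0, 0)),
    psd_span = cbind(c(-150, 150), c(0, 0)))
  # k = 3 touching on the span, m = 2 touching outside it, 1 with a 10-nm gap
  ves <- data.frame(
    id = 1:6,
    x_nm = c(-100, 0, 100, 500, -600, 50),
    y_nm = c(-20, -20, -20, -20, -20, -30),
    diameter_nm = 40)
  bouton <- list(member_ids = 1:6)
  expect_identical(count_docked(bouton, ves, membranes), 3L)
  expect_identical(count_docked(bouton, ves, membranes, contact_eps = 12),
                   4L)  # the 10-nm-gap vesicle joins
  expect_error(count_docked(bouton, ves, list(plasma_membrane = NULL)),
               "psd_span")
})

test_that("endosome rule is strict in diameter and requires a lumen", {
  ann <- data.frame(bouton = c(1, 1, 1, 1),
                    diameter_nm = c(50, 80, 80, 113),
                    lumen = c(TRUE, TRUE, FALSE, TRUE),
                    area_um2 = c(0.002, 0.01, 0.01, 0.01))
  res <- classify_endosomes(ann,
                            boutons = data.frame(bouton = 1,
                                                 area_um2 = 0.5))
  expect_identical(nrow(res$endosomes), 2L)      # 50 nm and no-lumen fail
  expect_equal(res$fractions$fraction, 0.04)     # 2 x 0.01 / 0.5
  no_area <- classify_endosomes(ann,
                                boutons = data.frame(bouton = 1,
                                                     area_um2 = NA))
  expect_true(is.na(no_area$fractions$fraction))
})

test_that("tether counting is inclusive at 70 nm and normalizes to 3 um", {
  # rectangle 2 x 1 um: perimeter 6 um
  rect <- mitochondrion(cbind(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000)))
  expect_equal(rect$perimeter, 6)
  ves <- data.frame(
    id = 1:6,
    x_nm = c(500, 900, 1300, 1700, 1000, 500),
    y_nm = c(-30, -50, -90, -300, 1200, 500),
    diameter_nm = c(40, 40, 40, 40, 60, 40))
  # edges: 10, 30, 70 (inclusive), 280 (out), diameter 60 (out), inside (out)
  res <- count_tethered(rect, ves)
  expect_identical(res$tethered_ids, c(1L, 2L, 3L))
  expect_equal(res$per_3um, 3 * 3 / 6)
  four <- count_tethered(rect, ves[c(1, 2, 3, 3), ][
    , , drop = FALSE] |> transform(id = 1:4))
  expect_equal(four$per_3um, 2)                  # 4 tethered on 6 um
})

test_that("tether counts match generator ground truth exactly", {
  for (s in 1:10) {
    out <- gen_mito_scene(mito_scene_params(seed = s))
    res <- count_tethered(out$scene$mito, out$scene$vesicles)
    truth_ids <- out$truth$tether_labels$id[out$truth$tether_labels$tethered]
    expect_identical(sort(res$tethered_ids), sort(truth_ids))
  }
})

test_that("tether normalization is stable under polygon re-sampling", {
  out <- gen_mito_scene(mito_scene_params(seed = 4))
  poly <- out$scene$mito$boundary
  # re-sample the same ellipse at a different vertex count
  P <- out$truth$params$perimeter * 1000
  a <- P / 4.844224
  th <- seq(0, 2 * pi, length.out = 301)[-301]
  dense <- mitochondrion(cbind(a * cos(th), a / 2 * sin(th)))
  r1 <- count_tethered(out$scene$mito, out$scene$vesicles)
  r2 <- count_tethered(dense, out$scene$vesicles)
  expect_lt(abs(r1$per_3um - r2$per_3um) / max(r1$per_3um, 1e-9), 0.01)
})
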