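test_that("slab geometry validates detectors and bounds", {
  expect_error(slab_geometry(detector_radii = c(1, 1.05),
                             detector_capture = 0.05), "disjoint")
  expect_error(slab_geometry(detector_radii = 12), "lateral")
  g <- slab_geometry()
  expect_identical(g$detector_radii, seq(0.5, 3, 0.5))
})

test_that("transport is reproducible under a seed and layer-count checked", {
  hd <- slab_example()$head
  geom <- slab_geometry()
  r1 <- transport_photons(geom, hd, 2e4, seed = 5)
  r2 <- transport_photons(geom, hd, 2e4, seed = 5)
  expect_identical(r1$L, r2$L)
  expect_identical(r1$Y, r2$Y)
  expect_identical(r1$detector_id, r2$detector_id)
  r3 <- transport_photons(geom, hd, 2e4, seed = 6)
  expect_false(identical(r1$detector_id, r3$detector_id))
  expect_error(transport_photons(slab_geometry(layer_thicknesses = 0.3),
                                 hd, 10), "layer count")
})

test_that("photon records satisfy their physical invariants", {
  run <- homog_run()
  expect_true(all(run$L >= 0))
  expect_true(all(run$Y >= 0))
  expect_true(all(rowSums(run$L) > 0))
  # absorption weight of every detected photon lies in (0, 1]
  w <- exp(-as.vector(run$L %*% c(0.1, 0.1, 0.1)))
  expect_true(all(w > 0 & w <= 1))
  # detected fraction decreases with detector radius
  expect_true(all(diff(run$detected_per_detector) < 0))
  # distant detections require longer paths
  tot <- rowSums(run$L)
  expect_gt(mean(tot[run$detector_id == 5]),
            mean(tot[run$detector_id == 1]))
})

test_that("homogeneous-optics CW reflectance tracks diffusion theory", {
  run <- homog_run()
  cw <- mc_cw_reflectance(run)
  want <- cw_semiinf(0.1, 10, 1.0) / cw_semiinf(0.1, 10, 2.0)
  got <- cw[2] / cw[4]
  expect_lt(abs(got / want - 1), 0.15)
})

test_that("autocorrelation from records obeys its limits and flow response", {
  run <- slab_run()
  tau <- test_scheme()$tau
  # zero flow everywhere freezes the field: g1 identically 1
  g0 <- g1_from_records(run, 2, c(0, 0, 0), tau)
  expect_true(all(g0$values == 1))
  # normalized value at tau -> 0 is 1 and curves decay
  g0lim <- g1_from_records(run, 2, c(1.7e-8, 0, 5.2e-8), 1e-15)
  expect_gt(g0lim$values[1], 1 - 1e-8)
  g <- g1_from_records(run, 2, c(1.7e-8, 0, 5.2e-8), tau)
  expect_true(all(diff(g$values) <= 0))
  # raising brain flow on the same records shifts the decay earlier
  t_lo <- half_decay_tau(siegert_g2(g))
  t_hi <- half_decay_tau(mc_g2(run, 2, c(1.7e-8, 0, 9e-8), tau))
  expect_lt(t_hi, t_lo)
  # re-evaluation needs no new transport and agrees to rounding
  # (matrix products may use non-deterministic threaded summation)
  g_again <- g1_from_records(run, 2, c(1.7e-8, 0, 5.2e-8), tau)
  expect_equal(g$values, g_again$values, tolerance = 1e-9)
})

test_that("homogeneous-optics MC matches the analytical field autocorrelation", {
  run <- homog_run()
  tau <- test_scheme()$tau
  hd <- run$head
  mc <- g1_from_records(run, 2, rep(1e-8, 3), tau)   # 1.0 cm detector
  an <- g1_semiinf(0.1, 10, 1e-8, 1.0, tau, hd$k0)
  keep <- an > 0.1
  rms <- sqrt(mean((mc$values[keep] - an[keep])^2))
  expect_lt(rms, 0.05)
})

test_that("requesting an empty detector errors and empty annuli warn", {
  run <- homog_run()
  expect_error(g1_from_records(run, 99, rep(1e-8, 3), 1e-5), "no photon")
  geom <- slab_geometry(detector_radii = 9.5, detector_capture = 0.01)
  expect_warning(transport_photons(geom, slab_example()$head, 100, seed = 1),
                 "no photons detected")
})
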