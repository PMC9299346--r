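test_that("multi-tau scheme has doubling widths and cumulative delays", {
  sch <- build_scheme(base_bin_width = 200e-9, bins_per_stage = 16,
                      n_stages = 12)
  expect_length(sch$tau, 16 * 12)
  expect_equal(sch$tau[1], 2e-7)
  expect_true(all(diff(sch$tau) > 0))
  expect_true(all(diff(sch$T) >= 0))
  # stage k bin width = 2^k * base width
  widths <- unique(sch$T)
  expect_equal(widths, 200e-9 * 2^(0:11))
  expect_identical(sch$m, seq_along(sch$tau))
  # grid spans the working delay range of the decays under study
  expect_lt(min(sch$tau), 1e-6)
  expect_gt(max(sch$tau), 1e-2)
})

test_that("decay rate recovers a single-exponential and tracks flow", {
  sch <- test_scheme()
  toy <- toy_exponential_curve(1e4, 0.5, sch)
  expect_lt(abs(decay_rate(toy, 0.5) - 1e4) / 1e4, 0.01)

  # doubling all flow indices in a homogeneous head roughly doubles Gamma
  mk <- function(b) {
    hd <- three_layer_head(rep(0.1, 3), rep(10, 3), c(0.35, 0.73),
                           sbfi = b, cbfi = b, skull_bfi = b)
    decay_rate(siegert_g2(g1_layered(hd, 2.5, sch$tau), 0.5), 0.5)
  }
  g1x <- mk(1e-8); g2x <- mk(2e-8)
  expect_lt(abs(g2x / g1x - 2), 0.1)

  # deeper paths decorrelate faster: Gamma grows with separation
  hd <- grid_head(parameter_grid(), 1e-8, 5e-8)
  gam <- vapply(c(0.5, 2.5), function(r) {
    decay_rate(siegert_g2(g1_layered(hd, r, sch$tau), 0.5), 0.5)
  }, numeric(1))
  expect_gt(gam[2], gam[1])

  # a curve that never decays below 1/e is an explicit error
  slow <- toy_exponential_curve(1, 0.5, sch)
  expect_error(decay_rate(slow, 0.5), "tau range")
})

test_that("noise model scales exactly as t^(-1/2) and has finite positive bins", {
  sch <- test_scheme()
  s1 <- sigma_g2(2e4, 1, 0.5, 1e4, sch)
  s4 <- sigma_g2(2e4, 4, 0.5, 1e4, sch)
  expect_identical(s4, s1 / 2)
  s10 <- sigma_g2(2e4, 10, 0.5, 1e4, sch)
  expect_true(all(is.finite(s10)) && all(s10 > 0))
})

test_that("shot-noise terms vanish in the bright limit", {
  sch <- test_scheme()
  # intensity such that even the narrowest bin holds ~1e9 photons
  s_bright <- sigma_g2(1e9 / min(sch$T), 10, 0.5, 1e4, sch)
  eT <- exp(-2e4 * sch$T); et <- exp(-2e4 * sch$tau)
  no_shot <- sqrt(sch$T / 10) *
    sqrt(0.25 * ((1 + eT) * (1 + et) + 2 * sch$m * (1 - eT) * et) / (1 - eT))
  expect_lt(max(abs(s_bright - no_shot) / no_shot), 1e-6)
})

test_that("seeded noise is reproducible, unbiased, and has the modeled std", {
  sch <- test_scheme()
  clean <- siegert_g2(g1_layered(degeneracy_example()$head, 2.5, sch$tau), 0.5)
  gam <- decay_rate(clean, 0.5)
  sig <- sigma_g2(2e4, 10, 0.5, gam, sch)

  expect_identical(add_noise(clean, sig, 7)$values,
                   add_noise(clean, sig, 7)$values)
  expect_false(identical(add_noise(clean, sig, 7)$values,
                         add_noise(clean, sig, 8)$values))

  draws <- vapply(1:1000, function(i) add_noise(clean, sig, i)$values,
                  numeric(length(sig)))
  emp_sd <- apply(draws, 1, sd)
  rel <- emp_sd / sig - 1
  # sampling error of an sd over 1000 draws is ~2.2%; demand agreement
  # in rms and no gross outlier
  expect_lt(sqrt(mean(rel^2)), 0.05)
  expect_lt(max(abs(rel)), 0.15)
  # mean over seeds returns the clean curve within CLT bounds
  emp_mean <- rowMeans(draws)
  expect_true(all(abs(emp_mean - clean$values) < 4 * sig / sqrt(1000)))
})

test_that("detected intensity anchors at the reference and scales by reflectance", {
  hd <- degeneracy_example()$head
  expect_equal(scale_intensity(hd, 2.5), 2e4)
  expect_gt(scale_intensity(hd, 0.5), 2e4)
  hd_h <- three_layer_head(rep(0.1, 3), rep(10, 3), c(0.35, 0.73),
                           sbfi = 1e-8, cbfi = 1e-8, skull_bfi = 1e-8)
  got <- scale_intensity(hd_h, 1.0) / scale_intensity(hd_h, 2.5)
  want <- cw_semiinf(0.1, 10, 1.0) / cw_semiinf(0.1, 10, 2.5)
  expect_lt(abs(got / want - 1), 1e-3)
})

test_that("bundling averages curves and cuts noise by 1/sqrt(k)", {
  sch <- test_scheme()
  clean <- siegert_g2(g1_layered(degeneracy_example()$head, 2.5, sch$tau), 0.5)
  gam <- decay_rate(clean, 0.5)
  sig <- sigma_g2(2e4, 10, 0.5, gam, sch)

  one <- add_noise(clean, sig, 3)
  expect_identical(bundle_detectors(list(one))$values, one$values)

  n_trial <- 300
  nb <- length(sig)
  single <- vapply(seq_len(n_trial), function(i) {
    add_noise(clean, sig, i)$values
  }, numeric(nb))
  bundled <- vapply(seq_len(n_trial), function(i) {
    b <- lapply(1:7, function(d) add_noise(clean, sig, 10000 + 7 * i + d))
    bundle_detectors(b)$values
  }, numeric(nb))
  # per-bin noise is independent, so the per-bin sd ratios are
  # independent estimates; their median has negligible sampling error
  ratio <- median(apply(bundled, 1, sd) / apply(single, 1, sd))
  expect_lt(abs(ratio - 1 / sqrt(7)), 0.1 / sqrt(7))
  # bundle is unbiased
  pick <- 30
  expect_lt(abs(mean(bundled[pick, ]) - clean$values[pick]),
            4 * sig[pick] / sqrt(7 * n_trial))
  # mismatched grids refuse to bundle
  other <- add_noise(siegert_g2(g1_layered(degeneracy_example()$head, 1.5,
                                           sch$tau), 0.5), sig, 1)
  expect_error(bundle_detectors(list(one, other)), "share")
})
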