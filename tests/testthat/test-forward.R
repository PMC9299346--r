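# Independent oracle: direct evaluation of the layered Hankel-space
# Green's function (rebuilt here from scratch in R) integrated with
# stats::integrate at tight tolerance. Shares no code with the package's
# panel quadrature or C++ kernel.
brute_force_g1 <- function(head, sds, tau) {
  mua <- vapply(head$layers, `[[`, numeric(1), "mua")
  musp <- vapply(head$layers, `[[`, numeric(1), "musp")
  bfi <- vapply(head$layers, `[[`, numeric(1), "bfi")
  L <- vapply(head$layers, `[[`, numeric(1), "thickness")
  k0 <- head$k0
  reff <- effective_reflection(head$layers[[1]]$refractive_index)
  z0 <- 1 / musp[1]
  zb <- (2 / (3 * musp[1])) * (1 + reff) / (1 - reff)
  Dp <- 1 / (3 * musp)
  nl <- length(mua)
  phi <- function(s, tt) {
    al <- vapply(seq_len(nl), function(i) {
      sqrt(s^2 + 3 * mua[i] * musp[i] + 6 * musp[i]^2 * k0^2 * bfi[i] * tt)
    }, numeric(length(s)))
    al <- matrix(al, ncol = nl)
    zeta <- Dp[nl] * al[, nl]
    for (i in (nl - 1):2) {
      th <- tanh(al[, i] * L[i])
      Da <- Dp[i] * al[, i]
      zeta <- Da * (zeta + Da * th) / (Da + zeta * th)
    }
    a <- al[, 1]
    P <- Dp[1] * a
    u <- exp(-a * z0); v <- exp(-a * zb); e1 <- exp(-a * (L[1] - z0))
    E1 <- e1^2; E2 <- E1 * (u * v)^2
    (1 - v^2) * u * ((P + zeta) + (P - zeta) * E1) /
      (2 * P * ((P + zeta) + (P - zeta) * E2))
  }
  G1 <- vapply(c(0, tau), function(tt) {
    tot <- 0
    for (i in 1:150) {
      tot <- tot + stats::integrate(function(s) {
        phi(s, tt) * besselJ(s * sds, 0) * s
      }, (i - 1) * 2, i * 2, rel.tol = 1e-12)$value
    }
    tot
  }, numeric(1))
  G1[-1] / G1[1]
}

test_that("layered solver reduces to the closed-form homogeneous solution", {
  sch <- test_scheme()
  tau <- sch$tau[sch$tau <= 1e-2]
  hd <- three_layer_head(rep(0.1, 3), rep(10, 3), c(0.35, 0.73),
                         sbfi = 1e-8, cbfi = 1e-8, skull_bfi = 1e-8)
  for (r in c(0.5, 1.5, 2.5)) {
    g1 <- g1_layered(hd, r, tau)
    oracle <- g1_semiinf(0.1, 10, 1e-8, r, tau, hd$k0)
    # relative to the unit-normalized curve everywhere, and pointwise
    # relative where the curve is non-negligible
    expect_lt(max(abs(g1$values - oracle)), 1e-4)
    keep <- oracle > 1e-3
    expect_lt(max(abs(g1$values - oracle)[keep] / oracle[keep]), 1e-4)
  }
})

test_that("heterogeneous three-layer solution matches a brute-force oracle", {
  hd <- degeneracy_example()$head
  tau <- c(1e-6, 1e-5, 1e-4, 3e-4, 1e-3)
  for (r in c(1.0, 2.5)) {
    g1 <- g1_layered(hd, r, tau)
    oracle <- brute_force_g1(hd, r, tau)
    expect_lt(max(abs(g1$values - oracle)), 1e-7)
  }
})

test_that("normalization and monotonicity hold across heads", {
  sch <- test_scheme()
  tau <- sch$tau[sch$tau < 5e-3]
  grid <- parameter_grid()
  heads <- list(degeneracy_example()$head,
                grid_head(grid, 2e-8, 9e-8),
                grid_head(grid, 1e-8, 3e-8, "L_skull", 1.1))
  for (hd in heads) {
    g1 <- g1_layered(hd, 2.0, c(1e-12, tau))
    expect_gt(g1$values[1], 1 - 1e-6)     # tau -> 0 limit
    expect_true(all(g1$values >= 0 - 1e-12))
    expect_true(all(diff(g1$values) <= 1e-12))  # non-increasing
  }
})

test_that("a very thick scalp makes the layered solution homogeneous in scalp", {
  tau <- c(1e-6, 1e-5, 1e-4, 1e-3)
  hd <- three_layer_head(c(0.1, 0.12, 0.2), c(10, 9, 3), c(10, 0.7),
                         sbfi = 3e-8, cbfi = 8e-8)
  g1 <- g1_layered(hd, 2.0, tau)
  oracle <- g1_semiinf(0.1, 10, 3e-8, 2.0, tau, hd$k0)
  expect_lt(max(abs(g1$values - oracle)), 1e-3)
})

test_that("raising brain flow strictly lowers g1 at depth-probing separations", {
  grid <- parameter_grid()
  tau <- 10^seq(-6, -3, by = 0.5)
  for (r in c(1.5, 2.5)) {
    prev <- NULL
    for (cb in c(2e-8, 5e-8, 9e-8)) {
      g1 <- g1_layered(grid_head(grid, 1e-8, cb), r, tau)$values
      if (!is.null(prev)) expect_true(all(g1 < prev))
      prev <- g1
    }
  }
})

test_that("Siegert relation is exact and validates inputs", {
  cv <- correlation_curve(1.5, c(1e-6, 1e-5), c(1, 0), "field")
  g2 <- siegert_g2(cv, 0.5)
  expect_identical(g2$values, c(1.5, 1))
  expect_identical(siegert_g2(cv, 0)$values, c(1, 1))
  g1v <- c(0.9, 0.4)
  cv2 <- correlation_curve(1.5, c(1e-6, 1e-5), g1v, "field")
  expect_equal(siegert_g2(cv2, 0.3)$values - 1, 0.3 * g1v^2,
               tolerance = 1e-14)
})

test_that("CW reflectance decreases with separation and matches the closed form", {
  hd_h <- three_layer_head(rep(0.1, 3), rep(10, 3), c(0.35, 0.73),
                           sbfi = 1e-8, cbfi = 1e-8, skull_bfi = 1e-8)
  cw <- vapply(c(0.5, 1.5, 2.5), function(r) cw_reflectance(hd_h, r),
               numeric(1))
  expect_true(all(diff(cw) < 0))
  expect_true(all(cw > 0))
  oracle <- vapply(c(0.5, 1.5, 2.5), function(r) cw_semiinf(0.1, 10, r),
                   numeric(1))
  expect_lt(abs(cw[1] / cw[3] - oracle[1] / oracle[3]) /
              (oracle[1] / oracle[3]), 1e-3)
  # heterogeneous head: still strictly decreasing
  cw3 <- vapply(seq(0.5, 3, 0.5), function(r) {
    cw_reflectance(degeneracy_example()$head, r)
  }, numeric(1))
  expect_true(all(diff(cw3) < 0))
})

test_that("effective reflection coefficient matches tabulated tissue value", {
  expect_equal(effective_reflection(1), 0)
  # n = 1.4: the standard diffusion-boundary value is about 0.493
  expect_lt(abs(effective_reflection(1.4) - 0.493), 0.005)
})
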