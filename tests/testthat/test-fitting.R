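test_that("cost function vanishes at truth, adds over curves, and matches a naive sum", {
  curves <- degeneracy_curves()
  fx <- degeneracy_example()
  truth <- unname(fx$truth)
  expect_lt(chi_squared(curves, truth, fx$head), 1e-12)

  cand <- c(1e-8, 3e-8)
  c_both <- chi_squared(curves, cand, fx$head)
  c_sep <- chi_squared(curves[[1]], cand, fx$head) +
    chi_squared(curves[[2]], cand, fx$head)
  expect_equal(c_both, c_sep, tolerance = 1e-12)

  # brute-force double loop on a short curve
  toy_tau <- c(1e-6, 5e-6, 2e-5, 1e-4, 5e-4)
  toy <- lapply(c(1.5, 3.0), function(r) {
    siegert_g2(g1_layered(fx$head, r, toy_tau), 0.5)
  })
  model <- lapply(c(1.5, 3.0), function(r) {
    hd <- set_flows(fx$head, cand[1], cand[2])
    siegert_g2(g1_layered(hd, r, toy_tau,
                          quad_control(nodes_per_panel = 8,
                                       refine = FALSE)), 0.5)
  })
  naive <- 0
  for (j in 1:2) for (k in 1:5) {
    naive <- naive + (toy[[j]]$values[k] - model[[j]]$values[k])^2
  }
  expect_equal(chi_squared(toy, cand, fx$head), naive, tolerance = 1e-10)
})

test_that("percent error is the signed relative deviation in percent", {
  expect_equal(percent_error(2.0e-8, 2.0e-8), 0)
  expect_equal(percent_error(2.5e-9, 2.0e-8), -87.5)
  expect_equal(percent_error(2.2e-8, 5.2e-8), -57.69231, tolerance = 1e-6)
  expect_error(percent_error(1, 0), "positive")
})

test_that("dual-separation clean fit recovers the representative sample exactly", {
  fx <- degeneracy_example()
  fit <- fit_flows(degeneracy_curves(), fx$head, fit_config(), truth = fx$truth)
  expect_lt(abs(fit$percent_error_cbfi), 1)
  expect_lt(abs(fit$percent_error_sbfi), 1)
  expect_lt(fit$chi2, 1e-10)
  expect_true(fit$converged)
})

test_that("initialization at the truth stays at the global minimum", {
  fx <- degeneracy_example()
  fit <- fit_flows(degeneracy_curves(), fx$head,
                   fit_config(init = unname(fx$truth)), truth = fx$truth)
  expect_lt(abs(fit$percent_error_cbfi), 0.1)
  expect_lt(abs(fit$percent_error_sbfi), 0.1)
})

test_that("estimates and all multistart endpoints respect the bounds", {
  fx <- degeneracy_example()
  cfg <- fit_config(multistart = 5, seed = 11)
  fit <- fit_flows(degeneracy_curves()[[2]], fx$head, cfg)
  for (col in c("sbfi0", "cbfi0", "sbfi_est", "cbfi_est")) {
    expect_true(all(fit$starts[[col]] >= cfg$bounds[1] - 1e-20))
    expect_true(all(fit$starts[[col]] <= cfg$bounds[2] + 1e-20))
  }
  # best chi2 never exceeds the cost at its own start
  ctx_cost <- function(s, c2) chi_squared(degeneracy_curves()[[2]], c(s, c2),
                                          fx$head, tau_inclusion = "auto")
  expect_lte(fit$chi2, ctx_cost(1e-8, 1e-8) + 1e-15)
})

test_that("a documented grid sample is degenerate at a single 3.0 cm separation", {
  # study sample: brain musp at its grid value 2.4 cm^-1, CBFi = 9e-8,
  # SBFi = CBFi/3. A second cost minimum with CBFi more than 2x below
  # the truth reaches chi2 < 1e-9 * Ntau over all delay bins: two flow
  # pairs reproduce the same curve to numerical precision, so a single
  # far separation does not identify the cerebral flow.
  grid <- parameter_grid()
  sch <- test_scheme()
  cbfi <- 9e-8; sbfi <- cbfi / 3
  hd <- grid_head(grid, sbfi, cbfi, "musp_brain", 2.4)
  cv <- siegert_g2(g1_layered(hd, 3.0, sch$tau), 0.5)
  cfg0 <- fit_config(init = c(sbfi * 1.5, cbfi / 2.3), maxit = 5000,
                     tau_inclusion = "all")
  fit <- fit_flows(cv, hd, cfg0, truth = c(sbfi, cbfi))
  for (k in 1:4) {
    fit <- fit_flows(cv, hd,
                     fit_config(init = c(fit$sbfi_est, fit$cbfi_est),
                                maxit = 5000, tau_inclusion = "all"),
                     truth = c(sbfi, cbfi))
  }
  n_tau <- length(sch$tau)
  expect_lt(fit$chi2, 1e-9 * n_tau)
  expect_gt(cbfi / fit$cbfi_est, 2)
  # the truth itself is (trivially) a second pair below the threshold
  expect_lt(chi_squared(cv, c(sbfi, cbfi), hd), 1e-9 * n_tau)
})

test_that("parameter recovery holds for seeded samples across the grid", {
  grid <- parameter_grid()
  sch <- test_scheme()
  samples <- enumerate_samples(grid)
  idx <- with_seed(2024, sample.int(nrow(samples), 6))
  for (i in idx) {
    sm <- samples[i, ]
    hd <- grid_head(grid, sm$sbfi, sm$cbfi, sm$param, sm$value)
    obs <- lapply(c(1.5, 2.5), function(r) {
      siegert_g2(g1_layered(hd, r, sch$tau), 0.5)
    })
    fit <- fit_flows(obs, hd, fit_config(), truth = c(sm$sbfi, sm$cbfi))
    expect_lt(abs(fit$percent_error_cbfi), 1)
    expect_lt(abs(fit$percent_error_sbfi), 1)
  }
})

test_that("cost maps are tight for wide pairs and flat for short pairs", {
  fx <- degeneracy_example()
  sch <- test_scheme()
  mk_obs <- function(radii) {
    lapply(radii, function(r) {
      siegert_g2(g1_layered(fx$head, r, sch$tau), 0.5)
    })
  }
  sb <- 10^seq(-9.5, -7, length.out = 61)
  cb <- 10^seq(-10, -6.8, length.out = 25)
  # CBFi span of the low-cost valley: columns whose best-scalp-flow cost
  # is within 10x of the map minimum
  span_cbfi <- function(cm) {
    prof <- apply(cm$chi2_surface, 2, min)
    hit <- cb[prof < 10 * min(prof)]
    max(hit) / min(hit)
  }
  wide <- cost_map(mk_obs(c(1.0, 3.0)), fx$head, sb, cb)
  short <- cost_map(mk_obs(c(0.5, 1.0)), fx$head, sb, cb)
  expect_lt(span_cbfi(wide), 2)
  expect_gt(span_cbfi(short), 10)
  # grid argmin agrees with the optimizer within one cell
  fit <- fit_flows(mk_obs(c(1.0, 3.0)), fx$head, fit_config())
  i <- which.min(abs(log(sb) - log(fit$sbfi_est)))
  j <- which.min(abs(log(cb) - log(fit$cbfi_est)))
  am <- arrayInd(which.min(wide$chi2_surface), dim(wide$chi2_surface))
  expect_lte(abs(am[1] - i), 1)
  expect_lte(abs(am[2] - j), 1)
})
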