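# Shared, lazily-built objects reused across test files. Everything is
# generated in code (no stored fixtures); expensive objects (the Monte
# Carlo transport runs) are built once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

test_scheme <- function() cached("scheme", build_scheme)

# Clean curves of the representative degenerate sample at its two
# separations, on the correlator grid.
degeneracy_curves <- function() {
  cached("degeneracy_curves", function() {
    fx <- degeneracy_example()
    sch <- test_scheme()
    curves <- lapply(fx$sds, function(r) {
      siegert_g2(g1_layered(fx$head, r, sch$tau), 0.5)
    })
    names(curves) <- sprintf("%.1f", fx$sds)
    curves
  })
}

# Large transport run for the slab worked example: sized so that the
# two short fit separations (0.5, 1.0 cm) each collect over 1e5
# detected photons.
slab_run <- function() {
  cached("slab_run", function() {
    fx <- slab_example()
    transport_photons(fx$geometry, fx$head, 5e6, seed = 424242)
  })
}

# Small homogeneous-optics run for transport physics checks.
homog_run <- function() {
  cached("homog_run", function() {
    hd <- three_layer_head(rep(0.1, 3), rep(10, 3), c(0.3, 0.7),
                           sbfi = 1e-8, cbfi = 1e-8, skull_bfi = 1e-8)
    transport_photons(slab_geometry(), hd, 6e5, seed = 99)
  })
}

# Delay at which an intensity curve has decayed halfway (field
# autocorrelation = 0.5), by interpolation.
half_decay_tau <- function(cv, beta = 0.5) {
  g1 <- sqrt(pmax(0, (cv$values - 1) / beta))
  ord <- order(g1)
  g1 <- g1[ord]; tau <- cv$tau[ord]
  ok <- !duplicated(g1)
  stats::approx(g1[ok], tau[ok], xout = 0.5)$y
}

# Economical fit settings for noisy-data fits in study-scale tests:
# model-evaluation quadrature well below the noise floor, looser
# simplex tolerance than the clean-data default.
noisy_fitcfg <- function() {
  fit_config(maxit = 400, reltol = 1e-9,
             quad = quad_control(nodes_per_panel = 6, tail = 1e-8,
                                 refine = FALSE))
}
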