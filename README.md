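# dcslayers

Simulation and inversion tools for diffuse correlation spectroscopy
(DCS) on layered head models, built to study a practical design
question: **which source–detector separations (SDS) should a DCS probe
use so that a three-layer (scalp / skull / brain) inverse model returns
an accurate cerebral blood flow index?**

DCS measures the intensity autocorrelation `g2(r, τ)` of multiply
scattered coherent light. On the head, the measured decay mixes scalp
and brain dynamics; a three-layer solution of the correlation diffusion
equation can separate them by simultaneously fitting a scalp blood flow
index (SBFi) and a cerebral blood flow index (CBFi) — the effective
Brownian diffusion coefficients `D` (cm²/s) of the moving scatterers in
those layers, with skull flow pinned to zero. The package provides the
full in-silico loop:

* **Layered forward model** — N-layer Green's function of the
  correlation diffusion equation in Hankel space (extrapolated-zero
  boundary, index-matched interfaces), inverted by tolerance-controlled
  Gauss–Legendre panel quadrature after closed-form removal of the
  semi-infinite part; `g1_layered()`, `cw_reflectance()`,
  `siegert_g2()` (`g2 = 1 + β g1²`, `β = 0.5`).
* **Correlator noise model** — multi-tau timing grid
  (`build_scheme()`), the photon-counting standard-deviation model
  `σ(τ)` of a hardware correlator (`sigma_g2()`), seeded noise
  realizations, detector bundling under an 8-detector budget, and
  intensity scaling anchored at 20 kHz at 2.5 cm.
* **Layered-slab Monte Carlo** — scattering-only photon transport with
  Henyey–Greenstein anisotropy (`g = 0.89`), Fresnel surface
  reflection (`n = 1.4`), per-layer pathlength and momentum-transfer
  recording (`transport_photons()`), and field autocorrelations
  rebuilt from the records for *any* flow combination without
  re-transport (`g1_from_records()`, `mc_g2()`).
* **Bounded inversion** — unweighted least-squares cost over all fitted
  separations and delays, minimized by Nelder–Mead under a sinusoidal
  bound transform in log10 space, bounds `[1e-11, 1e-6]` cm²/s;
  `fit_flows()`, `chi_squared()`, `cost_map()`, `percent_error()`.
* **Study drivers** — the full factorial design (8 parameters × 11
  values × 12 CBFi × 6 SBFi ratios × 6 separations = 38,016 curve
  specifications; 6 single-SDS and 30 ordered two-SDS configurations)
  with experiments for solution uniqueness, noise accuracy versus
  averaging time, Monte Carlo accuracy, and sensitivity to wrong
  assumed parameters; `run_uniqueness()`, `run_accuracy()`,
  `run_mc_accuracy()`, `run_sensitivity()`, `summarize_heatmap()`.

See the vignette (`vignettes/dcs-three-layer-model.Rmd`) for the model
equations, numerical choices, and limitations.

## Worked example

A representative sample (absorption 0.1/0.1/0.15 cm⁻¹, reduced
scattering 10/10/4 cm⁻¹, thicknesses 0.35/0.73 cm, SBFi = 6.7e-9,
CBFi = 2.0e-8 cm²/s) fitted from clean curves at 1.5 and 3.0 cm
simultaneously, then from the 3.0 cm curve alone:

```r
library(dcslayers)
fx  <- degeneracy_example()
sch <- build_scheme()
curves <- lapply(fx$sds, function(r)
  siegert_g2(g1_layered(fx$head, r, sch$tau), beta = 0.5))

fit_flows(curves, fx$head, fit_config(), truth = fx$truth)
#> <fit_result> SBFi = 6.7e-09, CBFi = 2e-08 cm^2/s, chi2 = 8.83e-14 (95 evals)
#>   percent error: SBFi +0.00%, CBFi -0.00%

single <- fit_flows(curves[[2]], fx$head,
                    fit_config(multistart = 5, seed = 2),
                    truth = fx$truth,
                    extra_starts = matrix(fx$degenerate, nrow = 1))
single$starts[which.max(abs(single$starts$cbfi_est - fx$truth["cbfi"])), ]
#>          sbfi0 cbfi0     sbfi_est     cbfi_est         chi2 n_eval converged
#> 6      2.1e-08 2.5e-09 1.028433e-08 4.815883e-10 8.335002e-06    151      TRUE
```

With two separations both flow indices are recovered exactly (0%
error). With a single far separation the optimizer also finds a second
solution whose curve matches the data to a per-bin residual of ~3e-4 —
visually indistinguishable — while CBFi is wrong by −98%: a single SDS
does not identify cerebral flow. The same machinery quantifies, across
the whole sample grid, how noise (via averaging time), Monte Carlo
transport effects, and wrong assumed optical properties or thicknesses
propagate into CBFi error for every separation choice.

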