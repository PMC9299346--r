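#' Multi-tau correlator timing scheme
#'
#' Generic multi-tau grid: `bins_per_stage` bins per stage, bin width
#' doubling from stage to stage, delays accumulating across bins. The
#' default (200 ns base width, 16 bins/stage, 12 stages) spans delays
#' from 2e-7 s to ~1.3e-2 s with 192 bins, approximating an 8-channel
#' hardware correlator.
#'
#' @param base_bin_width bin width of the first stage, s.
#' @param bins_per_stage bins per stage.
#' @param n_stages number of stages.
#' @return object of class `correlator_scheme` with fields `tau` (bin
#'   delays, s), `T` (bin widths, s), `m` (bin index, 1-based).
#' @export
build_scheme <- function(base_bin_width = 200e-9, bins_per_stage = 16,
                         n_stages = 12) {
  stopifnot(base_bin_width > 0, bins_per_stage >= 1, n_stages >= 1)
  stage <- rep(seq_len(n_stages) - 1, each = bins_per_stage)
  Tm <- base_bin_width * 2^stage
  tau <- cumsum(Tm)
  structure(list(tau = tau, T = Tm, m = seq_along(tau),
                 base_bin_width = base_bin_width,
                 bins_per_stage = bins_per_stage, n_stages = n_stages),
            class = "correlator_scheme")
}

#' @export
print.correlator_scheme <- function(x, ...) {
  cat(sprintf(
    "<correlator_scheme> %d bins (%d stages x %d), tau %.3g..%.3g s\n",
    length(x$tau), x$n_stages, x$bins_per_stage, min(x$tau), max(x$tau)))
  invisible(x)
}

#' Decay rate of an intensity autocorrelation curve
#'
#' Gamma = 1 / tau_e, where tau_e is the delay at which the field
#' autocorrelation sqrt((g2 - 1)/beta) has fallen to 1/e, located by
#' log-log interpolation between the bracketing bins. This is the rate
#' parameter fed to the correlator noise model.
#'
#' @param clean_g2 a clean `correlation_curve` of kind `"intensity"`.
#' @param beta coherence factor used to generate the curve.
#' @return decay rate, s^-1.
#' @export
decay_rate <- function(clean_g2, beta = 0.5) {
  stopifnot(inherits(clean_g2, "correlation_curve"),
            clean_g2$kind == "intensity")
  g1 <- sqrt(pmax(0, (clean_g2$values - 1) / beta))
  target <- exp(-1)
  below <- which(g1 < target)
  if (!length(below)) {
    stop("curve does not decay below 1/e within the delay grid; extend the tau range")
  }
  i2 <- below[1]
  if (i2 == 1) return(1 / clean_g2$tau[1])
  i1 <- i2 - 1
  lt <- log(clean_g2$tau[c(i1, i2)])
  lg <- log(pmax(g1[c(i1, i2)], 1e-300))
  tau_e <- exp(lt[1] + (lt[2] - lt[1]) * (-1 - lg[1]) / (lg[2] - lg[1]))
  1 / tau_e
}

#' Correlator noise model: per-bin standard deviation of g2
#'
#' Model standard deviation of the measured intensity autocorrelation for
#' a photon-counting multi-tau correlator, combining the correlated-decay
#' terms (in the decay rate Gamma, bin width T, and bin index m) with the
#' shot-noise terms (in the mean photon count per bin):
#' \deqn{\sigma(\tau_m) = \sqrt{T_m/t}\,\big[
#'   \beta^2\frac{(1+e^{-2\Gamma T_m})(1+e^{-2\Gamma\tau_m})
#'     + 2m(1-e^{-2\Gamma T_m})e^{-2\Gamma\tau_m}}{1-e^{-2\Gamma T_m}}
#'   + 2\langle n\rangle^{-1}\beta(1+e^{-2\Gamma\tau_m})
#'   + \langle n\rangle^{-2}(1+\beta e^{-\Gamma\tau_m})\big]^{1/2}}
#' with \eqn{\langle n\rangle = I\,T_m} photons per bin and t the total
#' averaging time.
#'
#' @param intensity detected photon rate I, photons/s.
#' @param avg_time total averaging time t, s.
#' @param beta coherence factor.
#' @param gamma decay rate Gamma, s^-1.
#' @param scheme a `correlator_scheme`.
#' @return numeric vector sigma(tau) over the scheme's bins.
#' @export
sigma_g2 <- function(intensity, avg_time, beta, gamma, scheme) {
  stopifnot(intensity > 0, avg_time > 0, beta > 0, beta <= 1, gamma > 0,
            inherits(scheme, "correlator_scheme"))
  Tm <- scheme$T
  tau <- scheme$tau
  m <- scheme$m
  n_bin <- intensity * Tm
  eT <- exp(-2 * gamma * Tm)
  et <- exp(-2 * gamma * tau)
  e1 <- exp(-gamma * tau)
  corr <- beta^2 * ((1 + eT) * (1 + et) + 2 * m * (1 - eT) * et) / (1 - eT)
  shot <- 2 * beta * (1 + et) / n_bin + (1 + beta * e1) / n_bin^2
  sqrt(Tm / avg_time) * sqrt(corr + shot)
}

#' Add seeded Gaussian noise to a clean g2 curve
#'
#' Adds independent zero-mean Gaussian noise with per-bin standard
#' deviation `sigma` (the additive application of the correlator noise
#' model; inter-bin covariance of real correlators is ignored).
#'
#' @param clean clean `correlation_curve` of kind `"intensity"`.
#' @param sigma per-bin standard deviations, aligned to the curve bins.
#' @param seed integer seed; the same seed reproduces the same curve.
#' @return noisy `correlation_curve` with the `sigma` field populated.
#' @export
add_noise <- function(clean, sigma, seed) {
  stopifnot(inherits(clean, "correlation_curve"),
            clean$kind == "intensity",
            length(sigma) == length(clean$tau))
  eps <- with_seed(seed, stats::rnorm(length(sigma)))
  correlation_curve(clean$sds, clean$tau, clean$values + eps * sigma,
                    kind = "intensity", sigma = sigma,
                    intensity = clean$intensity)
}

#' Detected intensity at a separation, scaled from a reference
#'
#' Detected photon rate at `sds`, anchored to `ref_intensity` at
#' `ref_sds` and scaled by the CW reflectance of the head model:
#' I(r) = I_ref * G1(r, 0) / G1(r_ref, 0).
#'
#' @param head a `head_model`.
#' @param sds separation of interest, cm.
#' @param ref_sds reference separation, cm (default 2.5).
#' @param ref_intensity detected photon rate at the reference, photons/s
#'   (default 20 kHz).
#' @param quad quadrature settings.
#' @return photons/s.
#' @export
scale_intensity <- function(head, sds, ref_sds = 2.5, ref_intensity = 2e4,
                            quad = quad_control()) {
  ref_intensity * cw_reflectance(head, sds, quad) /
    cw_reflectance(head, ref_sds, quad)
}

#' Average a bundle of detector curves
#'
#' Pointwise mean of k curves sharing a separation and delay grid, as
#' when several detector fibers are bundled at one separation: k
#' independent realizations reduce the effective noise standard
#' deviation by 1/sqrt(k).
#'
#' @param curves list of `correlation_curve` objects at the same sds on
#'   the same tau grid.
#' @return a single `correlation_curve`; its `sigma` field is the
#'   per-detector sigma divided by sqrt(k) when available.
#' @export
bundle_detectors <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  ref <- curves[[1]]
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$tau, ref$tau)) || cv$sds != ref$sds) {
      stop("all curves in a bundle must share sds and tau grid")
    }
  }
  vals <- rowMeans(vapply(curves, `[[`, numeric(length(ref$tau)), "values"))
  sig <- if (!is.null(ref$sigma)) ref$sigma / sqrt(length(curves)) else NULL
  correlation_curve(ref$sds, ref$tau, vals, kind = "intensity",
                    sigma = sig, intensity = ref$intensity)
}

#' Simulate a noisy bundled measurement at one separation
#'
#' Full measurement chain for one separation: clean analytical g2, decay
#' rate, detected intensity scaled from the 2.5 cm / 20 kHz reference,
#' per-bin model noise for the given averaging time, `k` independent
#' seeded realizations (sub-seeded per detector), bundled to one curve.
#' The standard-normal draws depend on the seed and detector index but
#' not on the averaging time, so measurements at different t with the
#' same seed are coupled through common random numbers.
#'
#' @param head true `head_model`.
#' @param sds separation, cm.
#' @param k number of detector fibers bundled at this separation.
#' @param avg_time averaging time t, s.
#' @param scheme `correlator_scheme` providing the delay grid.
#' @param beta coherence factor.
#' @param seed integer seed.
#' @param ref_sds,ref_intensity intensity reference.
#' @param quad quadrature settings.
#' @param clean optional precomputed clean g2 curve on the scheme grid.
#' @param intensity optional precomputed detected intensity, photons/s.
#' @return noisy bundled `correlation_curve`.
#' @export
simulate_noisy_bundle <- function(head, sds, k, avg_time,
                                  scheme = build_scheme(), beta = 0.5,
                                  seed = 1, ref_sds = 2.5,
                                  ref_intensity = 2e4,
                                  quad = quad_control(), clean = NULL,
                                  intensity = NULL) {
  if (is.null(clean)) {
    g1 <- g1_layered(head, sds, scheme$tau, quad)
    clean <- siegert_g2(g1, beta)
  }
  if (is.null(intensity)) {
    intensity <- scale_intensity(head, sds, ref_sds, ref_intensity, quad)
  }
  gamma <- decay_rate(clean, beta)
  sig <- sigma_g2(intensity, avg_time, beta, gamma, scheme)
  clean$intensity <- intensity
  curves <- lapply(seq_len(k), function(d) {
    add_noise(clean, sig, derive_seed(seed, d))
  })
  bundle_detectors(curves)
}
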