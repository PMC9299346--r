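# Boundary geometry shared by the layered solver and its homogeneous
# closed form: isotropic-source depth z0 = 1/musp of the surface layer,
# extrapolated-zero distance zb = 2 Dp (1 + Reff) / (1 - Reff).
boundary_geometry <- function(musp1, n_rel) {
  reff <- effective_reflection(n_rel)
  z0 <- 1 / musp1
  zb <- (2 / (3 * musp1)) * (1 + reff) / (1 - reff)
  list(z0 = z0, zb = zb, reff = reff)
}

#' Quadrature settings for the inverse Hankel transform
#'
#' The layered Green's function is inverted to real space by panelwise
#' Gauss-Legendre quadrature over the radial spatial frequency. Panels are
#' no wider than half a period of the Bessel kernel J0(s r) and no wider
#' than the decay scale of the integrand envelope; the grid is truncated
#' where the envelope falls below `tail` of its peak.
#'
#' @param nodes_per_panel Gauss-Legendre nodes per panel.
#' @param tail relative envelope cutoff for grid truncation.
#' @param refine if TRUE, node counts are doubled until two successive
#'   estimates of the normalized curve agree to `tol` (relative), with a
#'   hard error if agreement is not reached by `max_nodes_per_panel`.
#' @param tol refinement tolerance.
#' @param max_nodes_per_panel refinement cap.
#' @return list of settings.
#' @export
quad_control <- function(nodes_per_panel = 8, tail = 1e-12, refine = TRUE,
                         tol = 1e-8, max_nodes_per_panel = 64) {
  stopifnot(nodes_per_panel >= 2, tail > 0, tail < 1, tol > 0)
  list(nodes_per_panel = nodes_per_panel, tail = tail, refine = refine,
       tol = tol, max_nodes_per_panel = max_nodes_per_panel)
}

# Gauss-Legendre panel nodes for the inverse Hankel transform at radius
# rho; returns s nodes and weights folded with J0(s rho) * s. `scale` is
# the decay length (in s) of the integrand envelope: panels resolve both
# the Bessel oscillation (half-period pi/rho) and the envelope, and the
# grid stops where the envelope falls below `tail` of its peak.
hankel_nodes <- function(rho, scale, nodes_per_panel, tail) {
  s_max <- -log(tail) * scale
  h <- min(pi / rho, 3 * scale)
  n_panel <- ceiling(s_max / h)
  gl <- pracma::gaussLegendre(nodes_per_panel, 0, 1)
  starts <- (seq_len(n_panel) - 1) * h
  s <- as.vector(outer(gl$x * h, starts, `+`))
  w <- rep(gl$w * h, n_panel)
  list(s = s, w = w * s * besselJ(s * rho, 0))
}

# Envelope decay length (in s) of the layered correction integrand,
# e^{-s (2 L1 - z0)}: the semi-infinite part is handled in closed form.
correction_scale <- function(L1, z0) {
  if (z0 >= L1) stop("source depth 1/musp exceeds the first layer thickness")
  1 / (2 * L1 - z0)
}

# Unnormalized surface G1(tau) for a head model (up to a constant factor)
# at fixed quadrature settings: closed-form semi-infinite solution with
# the surface layer's properties, plus the numerically inverted layered
# correction.
layered_G1_raw <- function(head, sds, tau, nodes_per_panel, tail) {
  mua <- head_prop(head, "mua")
  musp <- head_prop(head, "musp")
  L <- head_prop(head, "thickness")
  bfi <- head_prop(head, "bfi")
  geom <- boundary_geometry(musp[1], head$layers[[1]]$refractive_index)
  nd <- hankel_nodes(sds, correction_scale(L[1], geom$z0),
                     nodes_per_panel, tail)
  corr <- g1_layered_kernel(nd$s, nd$w, tau, mua, musp, L, bfi,
                            head$k0, geom$z0, geom$zb)
  r1 <- sqrt(geom$z0^2 + sds^2)
  rb <- sqrt((geom$z0 + 2 * geom$zb)^2 + sds^2)
  K <- sqrt(3 * mua[1] * musp[1] + 6 * musp[1]^2 * head$k0^2 * bfi[1] * tau)
  semi <- (exp(-K * r1) / r1 - exp(-K * rb) / rb) * (3 * musp[1]) / (4 * pi)
  semi + corr / (2 * pi)
}

#' Field autocorrelation of a layered head model
#'
#' Solves the correlation diffusion equation for the layered half space
#' in Hankel space (extrapolated-zero boundary, index-matched internal
#' interfaces) and inverts numerically to real space, returning the
#' normalized field autocorrelation g1(r, tau) = G1(r, tau) / G1(r, 0).
#'
#' @param head a `head_model`.
#' @param sds source-detector separation, cm.
#' @param tau delay time grid, s (strictly increasing, > 0).
#' @param quad quadrature settings from [quad_control()].
#' @return `correlation_curve` of kind `"field"`.
#' @export
g1_layered <- function(head, sds, tau, quad = quad_control()) {
  stopifnot(inherits(head, "head_model"), sds > 0)
  tau0 <- c(0, tau)
  npp <- quad$nodes_per_panel
  est <- layered_G1_raw(head, sds, tau0, npp, quad$tail)
  if (quad$refine) {
    repeat {
      npp2 <- npp * 2
      est2 <- layered_G1_raw(head, sds, tau0, npp2, quad$tail)
      rel <- max(abs(est2 / est2[1] - est / est[1])) /
        max(abs(est2 / est2[1]))
      if (is.finite(rel) && rel < quad$tol) { est <- est2; break }
      if (npp2 >= quad$max_nodes_per_panel) {
        stop(sprintf(
          "Hankel quadrature did not converge at sds = %g cm (worst tau = %.3g s, rel = %.3g)",
          sds, tau0[which.max(abs(est2 / est2[1] - est / est[1]))], rel))
      }
      npp <- npp2
      est <- est2
    }
  }
  correlation_curve(sds, tau, est[-1] / est[1], kind = "field")
}

#' Continuous-wave diffuse reflectance of a layered head model
#'
#' Unnormalized G1 at delay zero, proportional to the detected CW photon
#' rate at the given separation; used to scale detected intensities
#' across separations.
#'
#' @inheritParams g1_layered
#' @return positive scalar (arbitrary common units).
#' @export
cw_reflectance <- function(head, sds, quad = quad_control()) {
  stopifnot(inherits(head, "head_model"), sds > 0)
  npp <- quad$nodes_per_panel
  est <- layered_G1_raw(head, sds, 0, npp, quad$tail)
  if (quad$refine) {
    repeat {
      npp2 <- npp * 2
      est2 <- layered_G1_raw(head, sds, 0, npp2, quad$tail)
      if (abs(est2 - est) < quad$tol * abs(est2)) { est <- est2; break }
      if (npp2 >= quad$max_nodes_per_panel) {
        stop(sprintf("Hankel quadrature did not converge at sds = %g cm", sds))
      }
      npp <- npp2
      est <- est2
    }
  }
  as.numeric(est) / (2 * pi)
}

#' Closed-form semi-infinite (homogeneous) solutions
#'
#' Image-source solution of the correlation diffusion equation for a
#' homogeneous semi-infinite medium with the extrapolated-zero boundary:
#' `g1_semiinf` returns the normalized field autocorrelation,
#' `cw_semiinf` the unnormalized CW reflectance (up to a constant). These
#' share the boundary conventions of the layered solver (z0 = 1/musp,
#' zb from the Fresnel-averaged internal reflectance) but none of its
#' code path, so they serve as an independent check of the layered
#' solution in the homogeneous limit.
#'
#' @param mua,musp optical properties, cm^-1.
#' @param bfi blood flow index, cm^2/s.
#' @param sds separation, cm.
#' @param tau delay times, s.
#' @param k0 in-medium wavenumber, cm^-1.
#' @param n_rel internal refractive index against air.
#' @return `g1_semiinf`: numeric vector of g1 values; `cw_semiinf`:
#'   positive scalar.
#' @export
g1_semiinf <- function(mua, musp, bfi, sds, tau, k0, n_rel = 1.4) {
  geom <- boundary_geometry(musp, n_rel)
  r1 <- sqrt(geom$z0^2 + sds^2)
  rb <- sqrt((geom$z0 + 2 * geom$zb)^2 + sds^2)
  K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * bfi * tau)
  K0 <- sqrt(3 * mua * musp)
  (exp(-K * r1) / r1 - exp(-K * rb) / rb) /
    (exp(-K0 * r1) / r1 - exp(-K0 * rb) / rb)
}

#' @rdname g1_semiinf
#' @export
cw_semiinf <- function(mua, musp, sds, n_rel = 1.4) {
  geom <- boundary_geometry(musp, n_rel)
  r1 <- sqrt(geom$z0^2 + sds^2)
  rb <- sqrt((geom$z0 + 2 * geom$zb)^2 + sds^2)
  K0 <- sqrt(3 * mua * musp)
  exp(-K0 * r1) / r1 - exp(-K0 * rb) / rb
}
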