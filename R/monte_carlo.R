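#' Layered slab geometry for Monte Carlo transport
#'
#' Pencil beam at the origin, normal incidence; annular detectors on the
#' top surface centered at the given source-detector distances. The slab
#' is laterally bounded (photons leaving the box are dropped), emulating
#' a finite simulation volume.
#'
#' @param layer_thicknesses finite layer thicknesses, cm, surface first
#'   (default scalp 0.3, skull 0.7; the last tissue layer is terminal and
#'   extends to `depth_bound`).
#' @param detector_radii source-detector distances, cm.
#' @param detector_capture radial half-width of each detection annulus, cm.
#' @param lateral_halfwidth half-width of the lateral bound, cm.
#' @param depth_bound termination depth, cm.
#' @return object of class `slab_geometry`.
#' @export
slab_geometry <- function(layer_thicknesses = c(0.3, 0.7),
                          detector_radii = seq(0.5, 3.0, by = 0.5),
                          detector_capture = 0.05,
                          lateral_halfwidth = 10, depth_bound = 10) {
  stopifnot(all(layer_thicknesses > 0), all(detector_radii > 0),
            detector_capture > 0, lateral_halfwidth > 0, depth_bound > 0)
  if (any(detector_radii + detector_capture > lateral_halfwidth)) {
    stop("detectors must lie within the lateral extent")
  }
  rmin <- detector_radii - detector_capture
  rmax <- detector_radii + detector_capture
  if (any(rmin < 0) || any(utils::head(rmax, -1) > utils::tail(rmin, -1))) {
    stop("detector annuli must be disjoint and non-negative")
  }
  structure(list(layer_thicknesses = layer_thicknesses,
                 detector_radii = detector_radii,
                 detector_capture = detector_capture,
                 lateral_halfwidth = lateral_halfwidth,
                 depth_bound = depth_bound),
            class = "slab_geometry")
}

#' Photon transport through a layered slab
#'
#' Scattering-only Monte Carlo: exponential step sampling by the
#' scattering coefficient mus = musp / (1 - g) of the current layer,
#' Henyey-Greenstein scattering, Fresnel reflection at the top surface
#' (layer index against air), index-matched internal interfaces.
#' Absorption is never sampled; it is applied analytically downstream
#' from the recorded per-layer pathlengths, so one transport run serves
#' every flow and absorption combination. For each photon escaping
#' within a detector annulus, the per-layer pathlength L_i and
#' dimensionless momentum transfer Y_i = sum(1 - cos theta) are recorded.
#'
#' @param geometry a `slab_geometry`; the number of finite thicknesses
#'   plus one must equal the number of head layers.
#' @param head a `head_model` supplying musp, anisotropy, and refractive
#'   index per layer.
#' @param n_photons number of photons to launch.
#' @param seed integer seed (dedicated generator; R's RNG is untouched).
#' @return object of class `mc_run` with fields `detector_id`, `L`, `Y`
#'   (records), `detected_per_detector`, `n_launched`, `geometry`,
#'   `head`, `seed`. Detectors with zero detected photons trigger a
#'   warning, never silence.
#' @export
transport_photons <- function(geometry, head, n_photons, seed = 1) {
  stopifnot(inherits(geometry, "slab_geometry"),
            inherits(head, "head_model"), n_photons >= 1)
  nl <- length(head$layers)
  if (length(geometry$layer_thicknesses) != nl - 1) {
    stop("geometry finite-layer count must be one less than head layer count")
  }
  musp <- head_prop(head, "musp")
  g <- head_prop(head, "anisotropy")
  mus <- musp / (1 - g)
  res <- transport_kernel(as.numeric(n_photons), mus, g,
                          cumsum(geometry$layer_thicknesses),
                          head$layers[[1]]$refractive_index,
                          geometry$detector_radii - geometry$detector_capture,
                          geometry$detector_radii + geometry$detector_capture,
                          geometry$lateral_halfwidth, geometry$depth_bound,
                          as.numeric(seed))
  empty <- which(res$detected_per_detector == 0)
  if (length(empty)) {
    warning(sprintf("no photons detected at sds = %s cm",
                    paste(geometry$detector_radii[empty], collapse = ", ")))
  }
  structure(c(res, list(geometry = geometry, head = head, seed = seed)),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %.3g photons launched, %d detected, seed %d\n",
              x$n_launched, length(x$detector_id), x$seed))
  cnt <- x$detected_per_detector
  cat("  per detector:",
      paste(sprintf("%g cm: %g", x$geometry$detector_radii, cnt),
            collapse = ", "), "\n")
  invisible(x)
}

#' Field autocorrelation from Monte Carlo photon records
#'
#' Evaluates the normalized field autocorrelation at one detector from
#' recorded per-layer momentum transfer and pathlength:
#' \deqn{G_1(\tau) = \frac{1}{N_p}\sum_n
#'   \exp\Big(-\tfrac{1}{3}\sum_i Y_{n,i} k_0^2 \langle\Delta r^2(\tau)\rangle_i\Big)
#'   \exp\Big(-\sum_i \mu_{a,i} L_{n,i}\Big)}
#' with Brownian dynamics \eqn{\langle\Delta r^2(\tau)\rangle_i = 6 D_i \tau},
#' normalized by its tau = 0 value. Records are flow-independent, so any
#' flow or absorption combination can be re-evaluated without
#' re-transport.
#'
#' @param run an `mc_run`.
#' @param detector_id detector index (into the geometry's radii).
#' @param bfi_per_layer flow index D_i per layer, cm^2/s.
#' @param tau delay grid, s.
#' @param mua_per_layer absorption per layer, cm^-1 (default: from the
#'   run's head model).
#' @param k0 in-medium wavenumber, cm^-1 (default: from the run's head).
#' @return `correlation_curve` of kind `"field"`.
#' @export
g1_from_records <- function(run, detector_id, bfi_per_layer, tau,
                            mua_per_layer = NULL, k0 = NULL) {
  stopifnot(inherits(run, "mc_run"))
  nl <- ncol(run$L)
  stopifnot(length(bfi_per_layer) == nl)
  if (is.null(mua_per_layer)) mua_per_layer <- head_prop(run$head, "mua")
  if (is.null(k0)) k0 <- run$head$k0
  sel <- run$detector_id == detector_id
  if (!any(sel)) stop(sprintf("no photon records at detector %d", detector_id))
  A <- as.vector(run$Y[sel, , drop = FALSE] %*% bfi_per_layer)
  wabs <- exp(-as.vector(run$L[sel, , drop = FALSE] %*% mua_per_layer))
  raw <- g1_records_kernel(A, wabs, c(0, tau), k0)
  correlation_curve(run$geometry$detector_radii[detector_id], tau,
                    raw[-1] / raw[1], kind = "field")
}

#' Intensity autocorrelation from Monte Carlo records
#'
#' Composition of [g1_from_records()] and [siegert_g2()].
#'
#' @inheritParams g1_from_records
#' @param beta coherence factor.
#' @return `correlation_curve` of kind `"intensity"`.
#' @export
mc_g2 <- function(run, detector_id, bfi_per_layer, tau, beta = 0.5,
                  mua_per_layer = NULL, k0 = NULL) {
  siegert_g2(g1_from_records(run, detector_id, bfi_per_layer, tau,
                             mua_per_layer, k0), beta)
}

#' CW reflectance per detector from a Monte Carlo run
#'
#' Absorption-weighted detected photon rate per unit annulus area,
#' proportional to the CW diffuse reflectance at each detector radius.
#'
#' @param run an `mc_run`.
#' @param mua_per_layer absorption per layer (default: run's head).
#' @return numeric vector, one value per detector.
#' @export
mc_cw_reflectance <- function(run, mua_per_layer = NULL) {
  stopifnot(inherits(run, "mc_run"))
  if (is.null(mua_per_layer)) mua_per_layer <- head_prop(run$head, "mua")
  wabs <- exp(-as.vector(run$L %*% mua_per_layer))
  geom <- run$geometry
  area <- pi * ((geom$detector_radii + geom$detector_capture)^2 -
                  (geom$detector_radii - geom$detector_capture)^2)
  tot <- vapply(seq_along(geom$detector_radii), function(d) {
    sum(wabs[run$detector_id == d])
  }, numeric(1))
  tot / (area * run$n_launched)
}
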