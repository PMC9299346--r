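#' @keywords internal
"_PACKAGE"

#' @useDynLib dcslayers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: fold an arbitrary integer vector into
# [1, 2^31 - 2]. Documented scheme so experiment rows are reproducible
# independently of execution order.
derive_seed <- function(master, ...) {
  idx <- c(master, unlist(list(...)))
  h <- 0
  for (v in idx) {
    h <- (h * 31 + (as.numeric(v) %% 2147483647)) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Effective internal reflection coefficient of a refractive-index mismatch
#'
#' Computes the effective reflection coefficient \eqn{R_{eff}} used by the
#' extrapolated-zero boundary condition of diffusion theory, from the
#' fluence- and flux-weighted moments of the unpolarized Fresnel
#' reflectance across the tissue/air interface.
#'
#' @param n_rel ratio of internal to external refractive index
#'   (e.g. 1.4 for tissue against air).
#' @return scalar \eqn{R_{eff}} in \[0, 1).
#' @export
effective_reflection <- function(n_rel) {
  stopifnot(is.numeric(n_rel), length(n_rel) == 1, n_rel > 0)
  if (n_rel == 1) return(0)
  rf <- function(theta) fresnel_unpolarized(theta, n_rel)
  r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                            0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                          0, pi / 2, rel.tol = 1e-10)$value
  (r_phi + r_j) / (2 - r_phi + r_j)
}

# Unpolarized Fresnel reflectance for light inside a medium of relative
# index n_rel hitting the boundary at internal angle theta (vectorized).
fresnel_unpolarized <- function(theta, n_rel) {
  st <- sin(theta)
  ct <- cos(theta)
  out <- rep(1, length(theta))          # total internal reflection
  s_t <- n_rel * st                     # Snell: n_in sin(th_i) = n_out sin(th_t)
  ok <- s_t < 1
  if (any(ok)) {
    tht <- asin(s_t[ok])
    cti <- ct[ok]
    ctt <- cos(tht)
    rs <- ((n_rel * cti - ctt) / (n_rel * cti + ctt))^2
    rp <- ((n_rel * ctt - cti) / (n_rel * ctt + cti))^2
    out[ok] <- (rs + rp) / 2
  }
  out
}
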