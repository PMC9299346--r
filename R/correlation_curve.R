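#' Construct a correlation curve
#'
#' The universal exchange object: autocorrelation samples over a delay
#' grid at one source-detector separation. `kind = "field"` holds the
#' normalized field autocorrelation g1 (in \[0, 1\], 1 at tau -> 0);
#' `kind = "intensity"` holds the intensity autocorrelation g2 (clean
#' curves lie in \[1, 1 + beta\]).
#'
#' @param sds source-detector separation, cm.
#' @param tau delay times, s; strictly increasing, all > 0.
#' @param values g1 or g2 samples.
#' @param kind `"field"` or `"intensity"`.
#' @param sigma optional per-bin noise standard deviation.
#' @param intensity optional detected photon rate, photons/s.
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(sds, tau, values, kind = c("field", "intensity"),
                              sigma = NULL, intensity = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sds), length(sds) == 1, sds > 0,
            is.numeric(tau), is.numeric(values),
            length(tau) == length(values))
  if (any(tau <= 0) || any(diff(tau) <= 0)) {
    stop("tau must be strictly increasing and positive")
  }
  if (!is.null(sigma)) stopifnot(length(sigma) == length(tau), all(sigma > 0))
  if (!is.null(intensity)) stopifnot(intensity > 0)
  structure(list(sds = sds, tau = tau, values = values, kind = kind,
                 sigma = sigma, intensity = intensity),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "<correlation_curve> %s, sds = %g cm, %d bins, tau %.3g..%.3g s\n",
    x$kind, x$sds, length(x$tau), min(x$tau), max(x$tau)))
  if (!is.null(x$intensity)) cat(sprintf("  intensity = %g photons/s\n", x$intensity))
  invisible(x)
}

#' Apply the Siegert relation to a field curve
#'
#' g2(tau) = 1 + beta * g1(tau)^2, with coherence factor beta set by the
#' detection optics.
#'
#' @param g1curve a `correlation_curve` of kind `"field"`.
#' @param beta coherence factor in \[0, 1\].
#' @return a `correlation_curve` of kind `"intensity"`.
#' @export
siegert_g2 <- function(g1curve, beta = 0.5) {
  if (!inherits(g1curve, "correlation_curve") || g1curve$kind != "field") {
    stop("siegert_g2() needs a field (g1) correlation_curve")
  }
  stopifnot(beta >= 0, beta <= 1)
  correlation_curve(g1curve$sds, g1curve$tau, 1 + beta * g1curve$values^2,
                    kind = "intensity", sigma = g1curve$sigma,
                    intensity = g1curve$intensity)
}

#' Write / read correlation curves as columnar CSV
#'
#' Long format with columns `sample_id, sds_cm, tau_s, g2, sigma,
#' intensity_hz` (`sigma` and `intensity_hz` are NA when absent).
#'
#' @param curves named list of `correlation_curve` objects (names become
#'   `sample_id`).
#' @param path CSV file path.
#' @return `read_curves` returns a named list of curves;
#'   `write_curves` returns `path` invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(is.list(curves))
  if (is.null(names(curves))) names(curves) <- sprintf("curve_%03d", seq_along(curves))
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(sample_id = nm, sds_cm = cv$sds, tau_s = cv$tau,
               g2 = cv$values,
               sigma = if (is.null(cv$sigma)) NA_real_ else cv$sigma,
               intensity_hz = if (is.null(cv$intensity)) NA_real_ else cv$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$sample_id), function(d) {
    correlation_curve(d$sds_cm[1], d$tau_s, d$g2, kind = "intensity",
                      sigma = if (all(is.na(d$sigma))) NULL else d$sigma,
                      intensity = if (is.na(d$intensity_hz[1])) NULL else d$intensity_hz[1])
  })
  out[unique(df$sample_id)]
}
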