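#' Construct a tissue layer
#'
#' A single layer of the head model with its optical and dynamic
#' properties. All lengths are in cm, coefficients in cm^-1, blood flow
#' index (effective Brownian diffusion coefficient of moving scatterers)
#' in cm^2/s.
#'
#' @param mua absorption coefficient, cm^-1 (> 0).
#' @param musp reduced scattering coefficient, cm^-1 (> 0).
#' @param thickness layer thickness, cm; `Inf` for the terminal
#'   (semi-infinite) layer.
#' @param bfi blood flow index D_i, cm^2/s (>= 0).
#' @param refractive_index dimensionless; 1.4 is typical for tissue.
#' @param anisotropy scattering anisotropy g in \[0, 1); used only by the
#'   Monte Carlo transport (the diffusion model depends on musp alone).
#' @return object of class `tissue_layer`.
#' @export
tissue_layer <- function(mua, musp, thickness = Inf, bfi = 0,
                         refractive_index = 1.4, anisotropy = 0.89) {
  stopifnot(is.numeric(mua), mua > 0,
            is.numeric(musp), musp > 0,
            is.numeric(thickness), thickness > 0,
            is.numeric(bfi), bfi >= 0,
            refractive_index > 0,
            anisotropy >= 0, anisotropy < 1)
  structure(list(mua = mua, musp = musp, thickness = thickness, bfi = bfi,
                 refractive_index = refractive_index,
                 anisotropy = anisotropy),
            class = "tissue_layer")
}

#' Construct a layered head model
#'
#' Ordered stack of [tissue_layer()] objects, surface first (scalp, skull,
#' brain for the three-layer case). The last layer must be semi-infinite;
#' all preceding layers need finite thickness.
#'
#' @param layers list of [tissue_layer()] objects, at least two.
#' @param wavelength operating wavelength, nm (default 785, a common DCS
#'   wavelength; the in-medium wavenumber k0 = 2 pi n / lambda follows
#'   from it).
#' @return object of class `head_model` with derived field `k0` (cm^-1).
#' @export
head_model <- function(layers, wavelength = 785) {
  if (!is.list(layers) || length(layers) < 2) {
    stop("a head model needs at least two layers")
  }
  layers <- unname(layers)
  for (ly in layers) {
    if (!inherits(ly, "tissue_layer")) {
      stop("all elements of `layers` must be tissue_layer objects")
    }
  }
  nl <- length(layers)
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  if (any(!is.finite(thick[-nl]))) {
    stop("all layers but the last must have finite thickness")
  }
  if (is.finite(thick[nl])) {
    stop("the last layer must be semi-infinite (thickness = Inf)")
  }
  n_ref <- vapply(layers, `[[`, numeric(1), "refractive_index")
  if (length(unique(n_ref)) > 1) {
    stop("internal interfaces are index-matched: all layers must share one refractive index")
  }
  stopifnot(is.numeric(wavelength), wavelength > 0)
  k0 <- 2 * pi * n_ref[1] / (wavelength * 1e-7)  # nm -> cm
  structure(list(layers = layers, wavelength = wavelength, k0 = k0),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d layers, lambda = %g nm, k0 = %.4g cm^-1\n",
              length(x$layers), x$wavelength, x$k0))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf(
      "  [%d] mua = %g, musp = %g cm^-1, L = %g cm, bfi = %g cm^2/s\n",
      i, ly$mua, ly$musp, ly$thickness, ly$bfi))
  }
  invisible(x)
}

# Per-layer property vectors, in stack order.
head_prop <- function(head, field) {
  vapply(head$layers, `[[`, numeric(1), field)
}

#' Three-layer head model from property vectors
#'
#' Convenience wrapper assembling a scalp/skull/brain model. Skull blood
#' flow defaults to zero (negligible flow in bone).
#'
#' @param mua,musp length-3 vectors (scalp, skull, brain), cm^-1.
#' @param thickness length-2 vector: scalp and skull thickness, cm.
#' @param sbfi,cbfi scalp and brain blood flow indices, cm^2/s.
#' @param skull_bfi skull blood flow index, cm^2/s (default 0).
#' @param refractive_index,anisotropy shared by all layers.
#' @param wavelength nm.
#' @return `head_model`.
#' @export
three_layer_head <- function(mua, musp, thickness, sbfi, cbfi,
                             skull_bfi = 0, refractive_index = 1.4,
                             anisotropy = 0.89, wavelength = 785) {
  stopifnot(length(mua) == 3, length(musp) == 3, length(thickness) == 2)
  bfi <- c(sbfi, skull_bfi, cbfi)
  thick <- c(thickness, Inf)
  layers <- lapply(1:3, function(i) {
    tissue_layer(mua[i], musp[i], thick[i], bfi[i],
                 refractive_index, anisotropy)
  })
  head_model(layers, wavelength = wavelength)
}

#' Replace the flow indices of a head model
#'
#' Returns a copy with scalp (first layer) and brain (last layer) blood
#' flow indices replaced; intermediate layers (skull) are set to
#' `middle_bfi` (default 0, the fitting assumption).
#'
#' @param head a `head_model`.
#' @param sbfi,cbfi new scalp/brain flow indices, cm^2/s.
#' @param middle_bfi flow index for all intermediate layers.
#' @return `head_model`.
#' @export
set_flows <- function(head, sbfi, cbfi, middle_bfi = 0) {
  nl <- length(head$layers)
  head$layers[[1]]$bfi <- sbfi
  head$layers[[nl]]$bfi <- cbfi
  if (nl > 2) for (i in 2:(nl - 1)) head$layers[[i]]$bfi <- middle_bfi
  head
}

#' Write / read a head model as structured text
#'
#' Key-value text serialization, one `[layer]` section per layer, which
#' round-trips bit-exactly (values are stored with full precision).
#'
#' @param head a `head_model`.
#' @param path file path.
#' @return `read_head_model` returns a `head_model`;
#'   `write_head_model` returns `path` invisibly.
#' @export
write_head_model <- function(head, path) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- c("[head]", paste0("wavelength_nm = ", fmt(head$wavelength)))
  for (ly in head$layers) {
    out <- c(out, "[layer]",
             paste0("mua_cm1 = ", fmt(ly$mua)),
             paste0("musp_cm1 = ", fmt(ly$musp)),
             paste0("thickness_cm = ", fmt(ly$thickness)),
             paste0("bfi_cm2s = ", fmt(ly$bfi)),
             paste0("refractive_index = ", fmt(ly$refractive_index)),
             paste0("anisotropy = ", fmt(ly$anisotropy)))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  sec <- cumsum(grepl("^\\[", lines))
  kv <- function(block) {
    block <- block[!grepl("^\\[", block)]
    parts <- strsplit(block, "=", fixed = TRUE)
    vals <- as.numeric(trimws(vapply(parts, `[`, character(1), 2)))
    names(vals) <- trimws(vapply(parts, `[`, character(1), 1))
    vals
  }
  blocks <- split(lines, sec)
  headers <- vapply(blocks, `[`, character(1), 1)
  hv <- kv(blocks[[which(headers == "[head]")[1]]])
  layer_blocks <- blocks[headers == "[layer]"]
  layers <- lapply(layer_blocks, function(b) {
    v <- kv(b)
    tissue_layer(v[["mua_cm1"]], v[["musp_cm1"]], v[["thickness_cm"]],
                 v[["bfi_cm2s"]], v[["refractive_index"]],
                 v[["anisotropy"]])
  })
  head_model(layers, wavelength = hv[["wavelength_nm"]])
}
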