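#' Fit configuration for the two-parameter flow inversion
#'
#' @param bounds lower/upper bounds for both flow indices, cm^2/s.
#' @param init initial (sbfi, cbfi), cm^2/s; must lie within bounds.
#' @param multistart number of optimizer starts; the first is `init`,
#'   the rest are drawn log-uniformly over the bounds (seeded). All
#'   starts are retained for degeneracy diagnosis.
#' @param seed seed for the multistart draws.
#' @param beta coherence factor of the fitted model.
#' @param tau_inclusion `"auto"` keeps bins whose clean-model g2 - 1
#'   exceeds 1e-3 * beta at the largest fitted separation, plus all
#'   earlier bins (plateau bins contribute only noise); `"all"` keeps
#'   every bin.
#' @param maxit maximum cost evaluations per start.
#' @param reltol relative convergence tolerance of the simplex.
#' @param quad quadrature settings used for model evaluation inside the
#'   fit (fixed node counts; both sides of the residual share them).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(bounds = c(1e-11, 1e-6), init = c(1e-8, 1e-8),
                       multistart = 1, seed = 1, beta = 0.5,
                       tau_inclusion = c("auto", "all"), maxit = 2000,
                       reltol = 1e-12,
                       quad = quad_control(nodes_per_panel = 8,
                                           refine = FALSE)) {
  tau_inclusion <- match.arg(tau_inclusion)
  stopifnot(length(bounds) == 2, all(bounds > 0), bounds[1] < bounds[2],
            length(init) == 2, all(init >= bounds[1]), all(init <= bounds[2]),
            multistart >= 1, maxit >= 10)
  structure(list(bounds = bounds, init = init, multistart = multistart,
                 seed = seed, beta = beta, tau_inclusion = tau_inclusion,
                 maxit = maxit, reltol = reltol, quad = quad),
            class = "fit_config")
}

# Sinusoidal bound transform in log10 space (bounded simplex device):
# an unbounded simplex coordinate x maps to a flow index inside the
# bounds; every candidate the optimizer visits is feasible.
flow_from_x <- function(x, bounds) {
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  10^(lo + (hi - lo) * (sin(x) + 1) / 2)
}
x_from_flow <- function(f, bounds) {
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  u <- 2 * (log10(f) - lo) / (hi - lo) - 1
  asin(pmin(1, pmax(-1, u)))
}

# Precompute everything reused across cost evaluations: selected bins,
# quadrature nodes per curve, and the assumed head's static properties.
make_fit_context <- function(observed, assumed_head, beta = 0.5,
                             tau_inclusion = "auto",
                             quad = quad_control(nodes_per_panel = 8,
                                                 refine = FALSE)) {
  if (inherits(observed, "correlation_curve")) observed <- list(observed)
  stopifnot(length(observed) >= 1)
  for (cv in observed) {
    stopifnot(inherits(cv, "correlation_curve"), cv$kind == "intensity")
  }
  mua <- head_prop(assumed_head, "mua")
  musp <- head_prop(assumed_head, "musp")
  L <- head_prop(assumed_head, "thickness")
  nl <- length(mua)
  geom <- boundary_geometry(musp[1],
                            assumed_head$layers[[1]]$refractive_index)

  tau_cut <- Inf
  if (tau_inclusion == "auto") {
    imax <- which.max(vapply(observed, `[[`, numeric(1), "sds"))
    far <- observed[[imax]]
    clean <- siegert_g2(g1_layered(assumed_head, far$sds, far$tau, quad),
                        beta)
    keep <- which(clean$values - 1 > 1e-3 * beta)
    tau_cut <- if (length(keep)) far$tau[max(keep)] else max(far$tau)
  }

  curves <- lapply(observed, function(cv) {
    sel <- cv$tau <= tau_cut
    if (!any(sel)) sel[1] <- TRUE
    nd <- hankel_nodes(cv$sds, correction_scale(L[1], geom$z0),
                       quad$nodes_per_panel, quad$tail)
    list(sds = cv$sds, tau0 = c(0, cv$tau[sel]), obs = cv$values[sel],
         nodes = nd,
         r1 = sqrt(geom$z0^2 + cv$sds^2),
         rb = sqrt((geom$z0 + 2 * geom$zb)^2 + cv$sds^2))
  })
  n_tau <- sum(vapply(curves, function(cu) length(cu$obs), numeric(1)))
  bfi_template <- rep(0, nl)
  list(curves = curves, mua = mua, musp = musp, L = L,
       k0 = assumed_head$k0, z0 = geom$z0, zb = geom$zb, beta = beta,
       nl = nl, n_tau = n_tau, bfi_template = bfi_template)
}

# Model g2 on the selected bins of one context curve for candidate
# flows: closed-form semi-infinite part plus the layered correction.
ctx_model_g2 <- function(ctx, cu, sbfi, cbfi) {
  bfi <- ctx$bfi_template
  bfi[1] <- sbfi
  bfi[ctx$nl] <- cbfi
  corr <- g1_layered_kernel(cu$nodes$s, cu$nodes$w, cu$tau0, ctx$mua,
                            ctx$musp, ctx$L, bfi, ctx$k0, ctx$z0, ctx$zb)
  K <- sqrt(3 * ctx$mua[1] * ctx$musp[1] +
              6 * ctx$musp[1]^2 * ctx$k0^2 * sbfi * cu$tau0)
  semi <- (exp(-K * cu$r1) / cu$r1 - exp(-K * cu$rb) / cu$rb) *
    (3 * ctx$musp[1]) / (4 * pi)
  raw <- semi + corr / (2 * pi)
  1 + ctx$beta * (raw[-1] / raw[1])^2
}

ctx_chisq <- function(ctx, sbfi, cbfi) {
  tot <- 0
  for (cu in ctx$curves) {
    tot <- tot + sum((cu$obs - ctx_model_g2(ctx, cu, sbfi, cbfi))^2)
  }
  tot
}

#' Cost function of the flow inversion
#'
#' Unweighted sum of squared g2 residuals over all fitted separations
#' and delay bins, with the candidate scalp/brain flow indices
#' substituted into the assumed head model (intermediate layers at zero
#' flow).
#'
#' @param observed a `correlation_curve` (kind intensity) or list of them.
#' @param candidate numeric (sbfi, cbfi), cm^2/s.
#' @param assumed_head `head_model` with the assumed optical properties
#'   and thicknesses.
#' @param beta coherence factor.
#' @param tau_inclusion,quad see [fit_config()].
#' @return non-negative scalar.
#' @export
chi_squared <- function(observed, candidate, assumed_head, beta = 0.5,
                        tau_inclusion = "all",
                        quad = quad_control(nodes_per_panel = 8,
                                            refine = FALSE)) {
  ctx <- make_fit_context(observed, assumed_head, beta, tau_inclusion, quad)
  ctx_chisq(ctx, candidate[1], candidate[2])
}

#' Simultaneous inversion for scalp and cerebral blood flow indices
#'
#' Minimizes the g2 residual cost over (SBFi, CBFi) with a bounded
#' derivative-free simplex: Nelder-Mead in a sinusoidally-transformed
#' log10 parameterization, so every visited candidate respects the
#' bounds. With `multistart > 1`, returns the global best and retains
#' every start's endpoint for degeneracy diagnosis.
#'
#' @param observed a `correlation_curve` or list of them (one per
#'   separation; bundled curves enter as a single curve).
#' @param assumed_head `head_model` with assumed optics/thicknesses.
#' @param config a [fit_config()].
#' @param truth optional true (sbfi, cbfi) for percent-error reporting.
#' @param extra_starts optional matrix/data.frame of additional start
#'   points (columns sbfi, cbfi), appended after the multistart draws.
#' @return list of class `fit_result`: `sbfi_est`, `cbfi_est`, `chi2`,
#'   `n_eval`, `converged`, `starts` (data frame of all starts), and,
#'   when truth is given, `percent_error_sbfi` / `percent_error_cbfi`.
#' @export
fit_flows <- function(observed, assumed_head, config = fit_config(),
                      truth = NULL, extra_starts = NULL) {
  stopifnot(inherits(config, "fit_config"))
  ctx <- make_fit_context(observed, assumed_head, config$beta,
                          config$tau_inclusion, config$quad)
  bounds <- config$bounds
  fn <- function(x) ctx_chisq(ctx, flow_from_x(x[1], bounds),
                              flow_from_x(x[2], bounds))

  starts <- matrix(config$init, nrow = 1)
  if (config$multistart > 1) {
    extra <- with_seed(config$seed, {
      lo <- log10(bounds[1]); hi <- log10(bounds[2])
      matrix(10^stats::runif(2 * (config$multistart - 1), lo, hi),
             ncol = 2)
    })
    starts <- rbind(starts, extra)
  }
  if (!is.null(extra_starts)) {
    starts <- rbind(starts, as.matrix(extra_starts)[, 1:2, drop = FALSE])
  }

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    x0 <- c(x_from_flow(starts[i, 1], bounds),
            x_from_flow(starts[i, 2], bounds))
    opt <- stats::optim(x0, fn, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = config$reltol))
    list(sbfi0 = starts[i, 1], cbfi0 = starts[i, 2],
         sbfi_est = flow_from_x(opt$par[1], bounds),
         cbfi_est = flow_from_x(opt$par[2], bounds),
         chi2 = opt$value, n_eval = opt$counts[["function"]],
         converged = opt$convergence == 0)
  })
  starts_df <- do.call(rbind, lapply(runs, as.data.frame))
  best <- runs[[which.min(starts_df$chi2)]]
  out <- list(sbfi_est = best$sbfi_est, cbfi_est = best$cbfi_est,
              chi2 = best$chi2, n_eval = best$n_eval,
              converged = best$converged, starts = starts_df,
              n_tau = ctx$n_tau)
  if (!is.null(truth)) {
    out$percent_error_sbfi <- percent_error(best$sbfi_est, truth[1])
    out$percent_error_cbfi <- percent_error(best$cbfi_est, truth[2])
  }
  structure(out, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> SBFi = %.3g, CBFi = %.3g cm^2/s, chi2 = %.3g (%d evals%s)\n",
    x$sbfi_est, x$cbfi_est, x$chi2, x$n_eval,
    if (x$converged) "" else ", NOT converged"))
  if (!is.null(x$percent_error_cbfi)) {
    cat(sprintf("  percent error: SBFi %+.2f%%, CBFi %+.2f%%\n",
                x$percent_error_sbfi, x$percent_error_cbfi))
  }
  invisible(x)
}

#' Signed percent error of an estimate
#'
#' (estimate - truth) / truth * 100.
#'
#' @param est estimated value.
#' @param truth true value (> 0).
#' @return signed percentage.
#' @export
percent_error <- function(est, truth) {
  if (any(truth <= 0)) stop("truth must be positive")
  (est - truth) / truth * 100
}

#' Dense cost surface over a flow-index grid
#'
#' Evaluates the inversion cost on a (SBFi, CBFi) grid, e.g. for contour
#' plots diagnosing valley shape and solution uniqueness.
#'
#' @inheritParams chi_squared
#' @param sbfi_grid,cbfi_grid positive grids, cm^2/s.
#' @return list of class `cost_map`: `sbfi_grid`, `cbfi_grid`,
#'   `chi2_surface` (rows = sbfi, cols = cbfi), `argmin` (sbfi, cbfi at
#'   the grid minimum).
#' @export
cost_map <- function(observed, assumed_head, sbfi_grid, cbfi_grid,
                     beta = 0.5, tau_inclusion = "all",
                     quad = quad_control(nodes_per_panel = 8,
                                         refine = FALSE)) {
  stopifnot(all(sbfi_grid > 0), all(cbfi_grid > 0))
  ctx <- make_fit_context(observed, assumed_head, beta, tau_inclusion, quad)
  surf <- matrix(NA_real_, length(sbfi_grid), length(cbfi_grid))
  for (i in seq_along(sbfi_grid)) {
    for (j in seq_along(cbfi_grid)) {
      surf[i, j] <- ctx_chisq(ctx, sbfi_grid[i], cbfi_grid[j])
    }
  }
  am <- arrayInd(which.min(surf), dim(surf))
  structure(list(sbfi_grid = sbfi_grid, cbfi_grid = cbfi_grid,
                 chi2_surface = surf,
                 argmin = c(sbfi = sbfi_grid[am[1]],
                            cbfi = cbfi_grid[am[2]])),
            class = "cost_map")
}
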