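#' Parameter grid of the simulation study
#'
#' Physiologically-motivated ranges for the eight varied head parameters
#' (absorption, reduced scattering, and thickness of scalp/skull/brain
#' layers, where applicable), sampled at evenly spaced values with the
#' remaining parameters held at the median of their range, crossed with
#' evenly spaced cerebral flow indices and scalp-to-brain flow ratios.
#'
#' @param values_per_parameter grid points per varied parameter.
#' @param n_cbfi number of cerebral flow values in \[2e-8, 9e-8\] cm^2/s.
#' @param n_sbfi_ratio number of scalp/brain flow ratios in \[1/8, 1/3\].
#' @return list of class `parameter_grid` with `ranges`, `medians`,
#'   `cbfi_values`, `sbfi_ratios`, `sds_set`.
#' @export
parameter_grid <- function(values_per_parameter = 11, n_cbfi = 12,
                           n_sbfi_ratio = 6) {
  ranges <- list(mua_scalp = c(0.05, 0.15), mua_skull = c(0.05, 0.15),
                 mua_brain = c(0.05, 0.25), musp_scalp = c(8, 12),
                 musp_skull = c(8, 12), musp_brain = c(2, 6),
                 L_scalp = c(0.15, 0.53), L_skull = c(0.35, 1.10))
  structure(list(ranges = ranges,
                 medians = vapply(ranges, mean, numeric(1)),
                 values_per_parameter = values_per_parameter,
                 cbfi_values = seq(2e-8, 9e-8, length.out = n_cbfi),
                 sbfi_ratios = seq(1 / 8, 1 / 3,
                                   length.out = n_sbfi_ratio),
                 sds_set = seq(0.5, 3.0, by = 0.5)),
            class = "parameter_grid")
}

# Map a varied-parameter name to (field, layer index).
param_slot <- function(param) {
  map <- list(mua_scalp = c("mua", 1), mua_skull = c("mua", 2),
              mua_brain = c("mua", 3), musp_scalp = c("musp", 1),
              musp_skull = c("musp", 2), musp_brain = c("musp", 3),
              L_scalp = c("thickness", 1), L_skull = c("thickness", 2))
  if (!param %in% names(map)) stop("unknown parameter: ", param)
  map[[param]]
}

#' Build a three-layer head from grid coordinates
#'
#' All parameters at their medians, with one optionally overridden, plus
#' the given flow pair.
#'
#' @param grid a [parameter_grid()].
#' @param sbfi,cbfi flow indices, cm^2/s.
#' @param param optional name of the varied parameter (e.g.
#'   `"mua_brain"`, `"L_scalp"`).
#' @param value its value (must be supplied with `param`).
#' @return `head_model`.
#' @export
grid_head <- function(grid, sbfi, cbfi, param = NULL, value = NULL) {
  m <- grid$medians
  p <- list(mua = c(m[["mua_scalp"]], m[["mua_skull"]], m[["mua_brain"]]),
            musp = c(m[["musp_scalp"]], m[["musp_skull"]], m[["musp_brain"]]),
            thickness = c(m[["L_scalp"]], m[["L_skull"]]))
  if (!is.null(param)) {
    stopifnot(!is.null(value))
    slot <- param_slot(param)
    p[[slot[1]]][as.integer(slot[2])] <- value
  }
  three_layer_head(p$mua, p$musp, p$thickness, sbfi = sbfi, cbfi = cbfi)
}

#' Enumerate the flow-pair grid
#'
#' @param grid a [parameter_grid()].
#' @return data frame of cbfi x sbfi-ratio combinations (72 rows for the
#'   default grid) with columns `flow_id`, `cbfi`, `sbfi_ratio`, `sbfi`.
#' @export
enumerate_flow_pairs <- function(grid) {
  fp <- expand.grid(sbfi_ratio = grid$sbfi_ratios, cbfi = grid$cbfi_values,
                    KEEP.OUT.ATTRS = FALSE)
  data.frame(flow_id = seq_len(nrow(fp)), cbfi = fp$cbfi,
             sbfi_ratio = fp$sbfi_ratio, sbfi = fp$sbfi_ratio * fp$cbfi)
}

#' Enumerate the study samples
#'
#' One row per (varied parameter, parameter value, flow pair): 8 x 11
#' head configurations crossed with 72 flow pairs = 6336 samples for the
#' default grid. Heads at the shared median value are retained for each
#' varied parameter (no deduplication; the study's sample arithmetic
#' counts them separately).
#'
#' @param grid a [parameter_grid()].
#' @return data frame with columns `sample_id`, `param`, `value_idx`,
#'   `value`, `flow_id`, `cbfi`, `sbfi`.
#' @export
enumerate_samples <- function(grid) {
  heads <- do.call(rbind, lapply(names(grid$ranges), function(pn) {
    vals <- seq(grid$ranges[[pn]][1], grid$ranges[[pn]][2],
                length.out = grid$values_per_parameter)
    data.frame(param = pn, value_idx = seq_along(vals), value = vals)
  }))
  flows <- enumerate_flow_pairs(grid)
  out <- merge(heads, flows, by = NULL)  # cross join
  out <- out[order(match(out$param, names(grid$ranges)), out$value_idx,
                   out$flow_id), ]
  out$sample_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("sample_id", "param", "value_idx", "value", "flow_id", "cbfi",
          "sbfi_ratio", "sbfi")]
}

#' Enumerate clean-curve specifications
#'
#' The sample table crossed with the separation set: 38,016 curve
#' specifications for the default grid.
#'
#' @param grid a [parameter_grid()].
#' @return data frame (samples x separations).
#' @export
enumerate_curve_specs <- function(grid) {
  samples <- enumerate_samples(grid)
  out <- merge(samples, data.frame(sds = grid$sds_set), by = NULL)
  out[order(out$sample_id, out$sds), ]
}

#' Enumerate source-detector configurations
#'
#' Single-separation configurations plus two-separation pairs from the
#' separation set: 6 singles and 30 ordered pairs (SDS1 != SDS2), or 15
#' unordered pairs under canonicalization.
#'
#' @param grid a [parameter_grid()].
#' @param ordered if FALSE, pairs are canonicalized to SDS1 < SDS2.
#' @return data frame with columns `config` (label), `sds1`, `sds2`
#'   (`NA` for single-SDS configurations).
#' @export
enumerate_sds_configs <- function(grid, ordered = TRUE) {
  singles <- data.frame(config = sprintf("%.1f", grid$sds_set),
                        sds1 = grid$sds_set, sds2 = NA_real_)
  pr <- expand.grid(sds1 = grid$sds_set, sds2 = grid$sds_set,
                    KEEP.OUT.ATTRS = FALSE)
  pr <- pr[pr$sds1 != pr$sds2, ]
  if (!ordered) pr <- pr[pr$sds1 < pr$sds2, ]
  pairs <- data.frame(config = sprintf("%.1f+%.1f", pr$sds1, pr$sds2),
                      sds1 = pr$sds1, sds2 = pr$sds2)
  out <- rbind(singles, pairs)
  rownames(out) <- NULL
  out
}

# Separations used by a config row, and the detector allocation under
# the 8-detector budget (8 at a single SDS, or 1 + 7 across a pair).
config_sds <- function(cfg_row) {
  if (is.na(cfg_row$sds2)) {
    data.frame(sds = cfg_row$sds1, k = 8)
  } else {
    data.frame(sds = c(cfg_row$sds1, cfg_row$sds2), k = c(1, 7))
  }
}

#' Uniqueness experiment: clean-data fits with true parameters
#'
#' Simulates clean analytical g2 for each sample, fits scalp and
#' cerebral flow simultaneously with the true optical properties and
#' thicknesses at each configuration, and flags samples whose cerebral
#' flow error exceeds `flag_threshold` percent as non-uniqueness
#' witnesses.
#'
#' @param grid a [parameter_grid()].
#' @param sds_configs data frame from [enumerate_sds_configs()] (or a
#'   subset).
#' @param samples sample table (default: full [enumerate_samples()]).
#' @param n_samples optional seeded subsample size.
#' @param seed subsample seed.
#' @param fitcfg a [fit_config()].
#' @param scheme correlator scheme providing the delay grid.
#' @param quad quadrature settings for data generation.
#' @param flag_threshold non-uniqueness flag threshold, percent.
#' @return long data frame, one row per sample x configuration.
#' @export
run_uniqueness <- function(grid, sds_configs, samples = NULL,
                           n_samples = NULL, seed = 1,
                           fitcfg = fit_config(), scheme = build_scheme(),
                           quad = quad_control(), flag_threshold = 1) {
  if (is.null(samples)) samples <- enumerate_samples(grid)
  if (!is.null(n_samples) && n_samples < nrow(samples)) {
    idx <- with_seed(seed, sample.int(nrow(samples), n_samples))
    samples <- samples[sort(idx), ]
  }
  rows <- list()
  for (si in seq_len(nrow(samples))) {
    sm <- samples[si, ]
    head <- grid_head(grid, sm$sbfi, sm$cbfi, sm$param, sm$value)
    need <- sort(unique(c(sds_configs$sds1, sds_configs$sds2)))
    need <- need[!is.na(need)]
    clean <- lapply(need, function(r) {
      siegert_g2(g1_layered(head, r, scheme$tau, quad), fitcfg$beta)
    })
    names(clean) <- sprintf("%.1f", need)
    for (ci in seq_len(nrow(sds_configs))) {
      cfg <- sds_configs[ci, ]
      obs <- lapply(sprintf("%.1f", config_sds(cfg)$sds),
                    function(nm) clean[[nm]])
      fit <- fit_flows(obs, head, fitcfg, truth = c(sm$sbfi, sm$cbfi))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sm$sample_id, param = sm$param, value = sm$value,
        sbfi = sm$sbfi, cbfi = sm$cbfi, config = cfg$config,
        sds1 = cfg$sds1, sds2 = cfg$sds2, sbfi_est = fit$sbfi_est,
        cbfi_est = fit$cbfi_est, chi2 = fit$chi2,
        converged = fit$converged,
        err_sbfi_pct = fit$percent_error_sbfi,
        err_cbfi_pct = fit$percent_error_cbfi,
        nonunique = abs(fit$percent_error_cbfi) > flag_threshold)
    }
  }
  do.call(rbind, rows)
}

#' Accuracy experiment: noise-added fits across averaging times
#'
#' Median-optics heads over the given flow pairs; noisy bundled curves
#' under the 8-detector budget at each configuration and averaging time;
#' fits with true optics. Noise sub-seeds are derived from the master
#' seed, flow id, repeat index, and separation, but not from the
#' averaging time, so different averaging times share standard-normal
#' draws (common random numbers).
#'
#' @param grid a [parameter_grid()].
#' @param sds_configs configurations to test.
#' @param flows flow-pair table (default: all of
#'   [enumerate_flow_pairs()]).
#' @param t_avg_set averaging times, s.
#' @param n_seeds noise repeats per flow pair.
#' @param master_seed master seed.
#' @param fitcfg,scheme,quad as in [run_uniqueness()].
#' @param ref_sds,ref_intensity detected-intensity reference.
#' @return long data frame, one row per flow x repeat x configuration x
#'   averaging time.
#' @export
run_accuracy <- function(grid, sds_configs, flows = NULL,
                         t_avg_set = c(1, 3, 10, 30), n_seeds = 1,
                         master_seed = 1, fitcfg = fit_config(),
                         scheme = build_scheme(), quad = quad_control(),
                         ref_sds = 2.5, ref_intensity = 2e4) {
  if (is.null(flows)) flows <- enumerate_flow_pairs(grid)
  need <- sort(unique(c(sds_configs$sds1, sds_configs$sds2)))
  need <- need[!is.na(need)]
  optics_head <- grid_head(grid, 1e-8, 1e-8)   # flows irrelevant for CW
  intens <- vapply(need, function(r) {
    scale_intensity(optics_head, r, ref_sds, ref_intensity, quad)
  }, numeric(1))
  names(intens) <- sprintf("%.1f", need)

  rows <- list()
  for (fi in seq_len(nrow(flows))) {
    fl <- flows[fi, ]
    head <- grid_head(grid, fl$sbfi, fl$cbfi)
    clean <- lapply(need, function(r) {
      siegert_g2(g1_layered(head, r, scheme$tau, quad), fitcfg$beta)
    })
    names(clean) <- sprintf("%.1f", need)
    for (rep_i in seq_len(n_seeds)) {
      for (t_avg in t_avg_set) {
        bundles <- list()
        for (ci in seq_len(nrow(sds_configs))) {
          cfg <- sds_configs[ci, ]
          alloc <- config_sds(cfg)
          obs <- lapply(seq_len(nrow(alloc)), function(ai) {
            r <- alloc$sds[ai]
            nm <- sprintf("%.1f", r)
            key <- sprintf("%s_k%d_t%g", nm, alloc$k[ai], t_avg)
            if (is.null(bundles[[key]])) {
              bundles[[key]] <<- simulate_noisy_bundle(
                head, r, alloc$k[ai], t_avg, scheme, fitcfg$beta,
                seed = derive_seed(master_seed, fl$flow_id, rep_i,
                                   round(r * 10)),
                clean = clean[[nm]], intensity = intens[[nm]])
            }
            bundles[[key]]
          })
          fit <- fit_flows(obs, head, fitcfg, truth = c(fl$sbfi, fl$cbfi))
          rows[[length(rows) + 1]] <- data.frame(
            flow_id = fl$flow_id, sbfi = fl$sbfi, cbfi = fl$cbfi,
            rep = rep_i, t_avg = t_avg, config = cfg$config,
            sds1 = cfg$sds1, sds2 = cfg$sds2, sbfi_est = fit$sbfi_est,
            cbfi_est = fit$cbfi_est, chi2 = fit$chi2,
            converged = fit$converged,
            err_sbfi_pct = fit$percent_error_sbfi,
            err_cbfi_pct = fit$percent_error_cbfi)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Monte Carlo accuracy experiment
#'
#' Fits the analytical three-layer model to Monte Carlo g2 curves from a
#' transport run, re-evaluating the flow-independent photon records for
#' each flow pair. The assumed head carries the run's optics and
#' thicknesses (the true values).
#'
#' @param run an `mc_run` covering all separations needed by
#'   `sds_configs`.
#' @param grid a [parameter_grid()].
#' @param sds_configs configurations to test.
#' @param flows flow pairs (default all 72).
#' @param fitcfg,scheme as elsewhere.
#' @param beta coherence factor for the Siegert relation.
#' @param min_photons configurations touching a detector with fewer
#'   detected photons are skipped with a warning.
#' @return long data frame, one row per flow x configuration.
#' @export
run_mc_accuracy <- function(run, grid, sds_configs, flows = NULL,
                            fitcfg = fit_config(), scheme = build_scheme(),
                            beta = 0.5, min_photons = 1000) {
  stopifnot(inherits(run, "mc_run"))
  if (is.null(flows)) flows <- enumerate_flow_pairs(grid)
  radii <- run$geometry$detector_radii
  counts <- run$detected_per_detector
  rows <- list()
  for (fi in seq_len(nrow(flows))) {
    fl <- flows[fi, ]
    bfi <- c(fl$sbfi, 0, fl$cbfi)
    truth_head <- run$head
    truth_head <- set_flows(truth_head, fl$sbfi, fl$cbfi)
    curves <- list()
    for (ci in seq_len(nrow(sds_configs))) {
      cfg <- sds_configs[ci, ]
      sds_used <- config_sds(cfg)$sds
      det <- match(sds_used, radii)
      if (any(is.na(det))) stop("configuration uses a separation without a detector")
      if (any(counts[det] < min_photons)) {
        warning(sprintf("config %s skipped: < %d photons at a detector",
                        cfg$config, min_photons))
        next
      }
      obs <- lapply(det, function(d) {
        key <- as.character(d)
        if (is.null(curves[[key]])) {
          curves[[key]] <<- mc_g2(run, d, bfi, scheme$tau, beta)
        }
        curves[[key]]
      })
      fit <- fit_flows(obs, truth_head, fitcfg,
                       truth = c(fl$sbfi, fl$cbfi))
      rows[[length(rows) + 1]] <- data.frame(
        flow_id = fl$flow_id, sbfi = fl$sbfi, cbfi = fl$cbfi,
        config = cfg$config, sds1 = cfg$sds1, sds2 = cfg$sds2,
        sbfi_est = fit$sbfi_est, cbfi_est = fit$cbfi_est,
        chi2 = fit$chi2, converged = fit$converged,
        err_sbfi_pct = fit$percent_error_sbfi,
        err_cbfi_pct = fit$percent_error_cbfi)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity experiment: fits with perturbed assumed parameters
#'
#' Truth is the median head over the given flow pairs; data are
#' simulated from the truth (noisy or clean); fitting assumes a head
#' with one parameter multiplied by (1 + delta) for each delta in the
#' grid.
#'
#' @param grid a [parameter_grid()].
#' @param param varied parameter name (e.g. `"mua_brain"`).
#' @param delta_grid relative perturbations of the assumed value.
#' @param sds_configs configurations to test.
#' @param flows flow pairs (default all 72).
#' @param noise logical; FALSE gives the clean variant.
#' @param t_avg averaging time when noise is on, s.
#' @param n_seeds noise repeats.
#' @param master_seed,fitcfg,scheme,quad,ref_sds,ref_intensity as in
#'   [run_accuracy()].
#' @return long data frame with a `delta` column.
#' @export
run_sensitivity <- function(grid, param,
                            delta_grid = seq(-0.3, 0.3, by = 0.1),
                            sds_configs,
                            flows = NULL, noise = TRUE, t_avg = 10,
                            n_seeds = 1, master_seed = 1,
                            fitcfg = fit_config(),
                            scheme = build_scheme(),
                            quad = quad_control(), ref_sds = 2.5,
                            ref_intensity = 2e4) {
  if (is.null(flows)) flows <- enumerate_flow_pairs(grid)
  slot <- param_slot(param)
  true_value <- grid$medians[[param]]
  need <- sort(unique(c(sds_configs$sds1, sds_configs$sds2)))
  need <- need[!is.na(need)]
  optics_head <- grid_head(grid, 1e-8, 1e-8)
  intens <- if (noise) {
    v <- vapply(need, function(r) {
      scale_intensity(optics_head, r, ref_sds, ref_intensity, quad)
    }, numeric(1))
    names(v) <- sprintf("%.1f", need)
    v
  } else NULL

  n_rep <- if (noise) n_seeds else 1
  rows <- list()
  for (fi in seq_len(nrow(flows))) {
    fl <- flows[fi, ]
    truth_head <- grid_head(grid, fl$sbfi, fl$cbfi)
    clean <- lapply(need, function(r) {
      siegert_g2(g1_layered(truth_head, r, scheme$tau, quad), fitcfg$beta)
    })
    names(clean) <- sprintf("%.1f", need)
    for (rep_i in seq_len(n_rep)) {
      obs_at <- lapply(seq_len(nrow(sds_configs)), function(ci) {
        alloc <- config_sds(sds_configs[ci, ])
        lapply(seq_len(nrow(alloc)), function(ai) {
          r <- alloc$sds[ai]
          nm <- sprintf("%.1f", r)
          if (!noise) return(clean[[nm]])
          simulate_noisy_bundle(
            truth_head, r, alloc$k[ai], t_avg, scheme, fitcfg$beta,
            seed = derive_seed(master_seed, fl$flow_id, rep_i,
                               round(r * 10)),
            clean = clean[[nm]], intensity = intens[[nm]])
        })
      })
      for (delta in delta_grid) {
        assumed <- grid_head(grid, fl$sbfi, fl$cbfi, param,
                             true_value * (1 + delta))
        for (ci in seq_len(nrow(sds_configs))) {
          cfg <- sds_configs[ci, ]
          fit <- fit_flows(obs_at[[ci]], assumed, fitcfg,
                           truth = c(fl$sbfi, fl$cbfi))
          rows[[length(rows) + 1]] <- data.frame(
            flow_id = fl$flow_id, sbfi = fl$sbfi, cbfi = fl$cbfi,
            rep = rep_i, param = param, delta = delta,
            config = cfg$config, sds1 = cfg$sds1, sds2 = cfg$sds2,
            sbfi_est = fit$sbfi_est, cbfi_est = fit$cbfi_est,
            chi2 = fit$chi2, converged = fit$converged,
            err_sbfi_pct = fit$percent_error_sbfi,
            err_cbfi_pct = fit$percent_error_cbfi)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a result table into separation heatmap matrices
#'
#' Mean and standard deviation of the cerebral-flow percent error per
#' configuration, arranged as matrices over the separation set: single
#' configurations on the diagonal, pairs at (SDS1, SDS2). Cells without
#' rows are NA.
#'
#' @param table a long result table from one of the `run_*` functions.
#' @param grid a [parameter_grid()] (supplies the axis labels).
#' @param value column to summarize.
#' @return list with matrices `mean`, `sd`, `n`.
#' @export
summarize_heatmap <- function(table, grid = parameter_grid(),
                              value = "err_cbfi_pct") {
  sds <- grid$sds_set
  lab <- sprintf("%.1f", sds)
  mk <- function() matrix(NA_real_, length(sds), length(sds),
                          dimnames = list(SDS1 = lab, SDS2 = lab))
  m_mean <- mk(); m_sd <- mk(); m_n <- mk()
  for (cfg in unique(table$config)) {
    sub <- table[table$config == cfg, ]
    i <- match(sprintf("%.1f", sub$sds1[1]), lab)
    j <- if (is.na(sub$sds2[1])) i else match(sprintf("%.1f", sub$sds2[1]), lab)
    m_mean[i, j] <- mean(sub[[value]])
    m_sd[i, j] <- stats::sd(sub[[value]])
    m_n[i, j] <- nrow(sub)
  }
  list(mean = m_mean, sd = m_sd, n = m_n)
}
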