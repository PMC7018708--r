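# Synthetic-data generators: pre-stimulus reporter distributions, noisy
# single-cell trajectory datasets with known ground truth, and flow-style
# snapshot tables. Every generator is a pure function of (config, seed).

#' Configuration for the synthetic-data generators
#'
#' The defaults define the study conditions the generators emulate: a
#' visibly bimodal pre-stimulus log-fluorescence mixture with a
#' density-dependent high-mode ("licensed") fraction, a cross-density
#' log-additive shift, and multiplicative lognormal measurement noise on
#' fluorescence readouts.
#'
#' @param seed integer master seed.
#' @param n_cells cells per generated dataset.
#' @param mu means (log a.u.) of the low/high mixture modes.
#' @param sigma sds (log a.u.) of the two modes.
#' @param w_high named high-mode weight per density condition.
#' @param delta_low log-additive shift applied to the low-density condition
#'   (negative = dimmer cells at low density).
#' @param unit_factor arbitrary multiplicative unit factor applied to the
#'   low-density *observed* samples to mimic non-comparable units between
#'   acquisitions (1 = comparable).
#' @param sigma_meas multiplicative lognormal measurement noise (log-SD).
#' @param params ground-truth kinetic parameters.
#' @param times sampling times (h) for trajectory datasets.
#' @return List of class `qlmac_synth_config`.
#' @export
synthetic_config <- function(seed = 1, n_cells = 30,
                             mu = c(0, 2.5), sigma = c(0.5, 0.6),
                             w_high = c(high = 0.75, low = 0.25, very_low = 0.25),
                             delta_low = -0.8, unit_factor = 1,
                             sigma_meas = 0.1,
                             params = default_params(),
                             times = seq(0, 24, 0.5)) {
  if (sigma_meas < 0) stop("sigma_meas must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  validate_params(params)
  structure(list(seed = seed, n_cells = n_cells, mu = mu, sigma = sigma,
                 w_high = w_high, delta_low = delta_low,
                 unit_factor = unit_factor, sigma_meas = sigma_meas,
                 params = params, times = times),
            class = "qlmac_synth_config")
}

synth_mixture <- function(config, condition = "high") {
  w <- unname(config$w_high[condition])
  shift <- if (condition == "high") 0 else config$delta_low
  structure(list(weights = c(w_low = 1 - w, w_high = w),
                 means = c(mu_low = config$mu[1] + shift,
                           mu_high = config$mu[2] + shift),
                 sds = c(sd_low = config$sigma[1], sd_high = config$sigma[2]),
                 loglik = NA_real_, degenerate = FALSE),
            class = "qlmac_gmm")
}

#' Generate paired high/low-density pre-stimulus distributions
#'
#' High-density samples come from the configured two-Gaussian mixture; the
#' low-density samples from the shifted and reweighted mixture, multiplied
#' (on the linear scale) by the arbitrary unit factor so the two observed
#' vectors are in non-comparable units — the situation
#' [impute_cross_density()] resolves. The truth sidecar records the
#' generating shift and weights.
#'
#' @param config a [synthetic_config()].
#' @return List with `high`, `low` (log-fluorescence vectors) and `truth`
#'   (list: delta, w_high_high, w_high_low, unit_factor).
#' @export
generate_initial_distributions <- function(config) {
  stopifnot(inherits(config, "qlmac_synth_config"))
  withr_seed(config$seed, {
    hi <- gmm_sample(synth_mixture(config, "high"), config$n_cells)
    lo <- gmm_sample(synth_mixture(config, "low"), config$n_cells)
  })
  list(high = hi,
       low = lo + log(config$unit_factor),
       truth = list(delta = config$delta_low,
                    w_high_high = unname(config$w_high["high"]),
                    w_high_low = unname(config$w_high["low"]),
                    unit_factor = config$unit_factor))
}

apply_meas_noise <- function(x, sigma, seed) {
  if (sigma == 0) return(x)
  withr_seed(seed, x * rlnorm(length(x), meanlog = 0, sdlog = sigma))
}

#' Generate a noisy single-cell microscopy trajectory dataset
#'
#' Simulates a heterogeneous population under the given condition with the
#' ground-truth parameters, then multiplies every observable at every
#' timepoint by lognormal measurement noise. Returns the observed tidy table
#' together with the hidden truth (noise-free ensemble and per-cell latents),
#' enabling parameter- and structure-recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param spec condition; default high density, sTNFR + LPS 100.
#' @return List with `observed` (data.frame: cell_id, time_h, observables),
#'   `truth` (list: ensemble, initials, params, sigma_meas).
#' @export
generate_microscopy_dataset <- function(config,
                                        spec = perturbation(lps = 100, stnfr = 1,
                                                            density = "high")) {
  stopifnot(inherits(config, "qlmac_synth_config"))
  mix <- synth_mixture(config, spec$density_label)
  ini <- sample_initials(mix, config$n_cells, config$params,
                         seed = config$seed)
  sched <- build_schedule(spec, config$params)
  tgrid <- sort(unique(c(sched$t_start, 0, config$times)))
  ens <- simulate_population(ini$states, config$params, spec,
                             k_rela0 = ini$k_rela0, t_grid = tgrid)
  obs <- ens$observables
  obs <- obs[obs$time_h %in% config$times, ]
  noisy <- obs
  cols <- c("total", "nuclear", "cytoplasmic", "mch_mat", "tnf_intra")
  for (j in seq_along(cols)) {
    noisy[[cols[j]]] <- apply_meas_noise(obs[[cols[j]]], config$sigma_meas,
                                         seed = config$seed * 131 + j)
  }
  list(observed = noisy,
       truth = list(ensemble = ens, initials = ini, params = config$params,
                    sigma_meas = config$sigma_meas))
}

#' Generate a flow-cytometry-style snapshot table
#'
#' Simulates the configured population under a condition, takes the per-cell
#' snapshot at `t` hps and applies multiplicative measurement noise. A small
#' constant (`log_shift`) is recorded so downstream log-display transforms
#' are well defined at zero signal.
#'
#' @param config a [synthetic_config()].
#' @param spec condition ([perturbation()]).
#' @param t snapshot time, hps (3, 6, 12 convention, or any simulated time).
#' @param log_shift small constant for log-display compatibility.
#' @return List with `table` (data.frame per cell, noisy), `truth` (list:
#'   noise-free snapshot, licensed fraction of the initial mixture,
#'   log_shift).
#' @export
generate_flow_snapshot <- function(config, spec = perturbation(lps = 100,
                                                               density = "high"),
                                   t = 12, log_shift = 0.01) {
  stopifnot(inherits(config, "qlmac_synth_config"))
  mix <- synth_mixture(config, spec$density_label)
  ini <- sample_initials(mix, config$n_cells, config$params,
                         seed = config$seed)
  sched <- build_schedule(spec, config$params)
  tgrid <- sort(unique(c(sched$t_start, 0, t)))
  ens <- simulate_population(ini$states, config$params, spec,
                             k_rela0 = ini$k_rela0, t_grid = tgrid)
  snap <- snapshot(ens, t)
  noisy <- snap
  for (j in seq_along(names(snap))[-1]) {
    noisy[[j]] <- apply_meas_noise(snap[[j]], config$sigma_meas,
                                   seed = config$seed * 257 + j)
  }
  w <- unname(config$w_high[spec$density_label])
  list(table = noisy,
       truth = list(snapshot = snap, licensed_fraction = w,
                    latent = ini$latent, log_shift = log_shift))
}
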