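# Ensemble of heterogeneous cells coupled through a shared medium.

#' Logistic population growth
#'
#' Cell density grows logistically from the plating value towards a carrying
#' capacity expressed as a multiple of the plating density.
#'
#' @param density0 plating density (cells/ml), > 0.
#' @param t hours since plating, >= 0 (vectorised).
#' @param growth_params named vector with `rate` (/h) and `cap` (fold of
#'   `density0`); `rate = 0` gives constant density.
#' @return Density at `t` (cells/ml), monotone non-decreasing in `t`.
#' @export
#' @examples
#' grow_density(1e5, 12, c(rate = log(2) / 12 , cap = 100))  # ~ doubles
grow_density <- function(density0, t, growth_params = c(rate = 0.03, cap = 3)) {
  if (density0 <= 0) stop("density0 must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  r <- unname(growth_params["rate"])
  K <- unname(growth_params["cap"]) * density0
  if (r == 0 || K == density0) return(rep(density0, length(t)))
  K * density0 / (density0 + (K - density0) * exp(-r * t))
}

#' Simulate a coupled heterogeneous population
#'
#' Integrates N single-cell systems sharing one extracellular medium. Each
#' cell secretes TNF at `k_sec * tnf_intra` (blocked by BFA); the medium
#' accumulates the per-cell mean flux scaled by the density multiplier
#' `density(t) / rho_ref` (rho_ref = the high-density plating value), so
#' density acts as a single dimensionless coupling knob. Every cell senses the
#' same extracellular TNF through TNFR. Free sTNFR sequesters extracellular
#' TNF with conservation of total sTNFR, and a first-order density-scaled
#' uptake sink models competitive consumption of TNF by cells.
#'
#' Per-cell heterogeneity enters through the rows of `initials` and the
#' per-cell basal Rela transcription rates `k_rela0` (both typically from
#' [sample_initials()]).
#'
#' For large N the medium is closed with a mean-field two-pass scheme: a
#' representative subset of `n_rep` cells is simulated fully coupled to
#' estimate the medium trajectory, then all cells are integrated against that
#' forcing in independent blocks. For `N <= n_rep` the fully coupled system is
#' solved directly.
#'
#' @param initials N x 17 matrix of initial species (rows = cells), or a list
#'   from [sample_initials()], or a single state vector recycled to `n`.
#' @param params parameter vector.
#' @param spec a [perturbation()].
#' @param t_grid output times (h); default `seq(t_start, 24, 0.1)`.
#' @param n number of cells when `initials` is a single state.
#' @param k_rela0 per-cell basal Rela transcription (length N) or NULL for the
#'   shared value in `params`.
#' @param grow logical; evolve density by logistic growth from plating
#'   (assumed 36 h before stimulus) rather than holding it fixed.
#' @param n_rep coupled representative cells used for the mean-field pass.
#' @param solver_opts list; `rtol`, `atol`, `method`.
#' @return Object of class `qlmac_ensemble`: list with `times`, `cells`
#'   (array time x species x cell), `medium` (data.frame), `observables`
#'   (long data.frame: cell_id, time_h, total, nuclear, cytoplasmic, mch_mat,
#'   tnf_intra, cum_sec), `spec`, `params`.
#' @export
simulate_population <- function(initials, params, spec, t_grid = NULL,
                                n = NULL, k_rela0 = NULL, grow = FALSE,
                                n_rep = 100, solver_opts = list()) {
  validate_params(params)
  stopifnot(inherits(spec, "perturbation_spec"))
  if (is.list(initials) && !is.null(initials$states)) {
    if (is.null(k_rela0)) k_rela0 <- initials$k_rela0
    initials <- initials$states
  }
  if (is.null(dim(initials))) {
    if (is.null(n)) n <- 1
    s <- cell_state()
    s[names(initials)] <- initials
    initials <- matrix(rep(as.numeric(s), each = n), nrow = n)
  }
  n <- nrow(initials)
  if (n < 1) stop("N must be >= 1")
  if (!is.null(k_rela0) && length(k_rela0) != n) {
    stop("length(k_rela0) must equal the number of cells (", n, ")")
  }
  sched <- build_schedule(spec, params)
  if (is.null(t_grid)) t_grid <- seq(sched$t_start, 24, by = 0.1)
  opts <- modifyList(list(rtol = 1e-6, atol = 1e-9, method = "lsoda"), solver_opts)
  med0 <- c(0, sched$stnfr0, 0)
  t_plate <- sched$t_start - if (grow) (36 + sched$t_start) else 0
  dens_args <- if (grow) list(density0 = spec$density, t_plate = -36) else
    list(density0 = NULL, t_plate = NULL)

  run_coupled <- function(cells0, kr) {
    integrate_system(cells0, med0, params, sched, t_grid, k_rela0 = kr,
                     couple = TRUE, density0 = dens_args$density0,
                     t_plate = dens_args$t_plate,
                     rtol = opts$rtol, atol = opts$atol, method = opts$method)
  }

  to_cell_array <- function(sol_mat, n_cells) {
    a <- array(sol_mat[, 1 + seq_len(n_cells * N_SPECIES)],
               dim = c(nrow(sol_mat), n_cells, N_SPECIES))
    aperm(a, c(1, 3, 2))  # time x species x cell
  }

  if (n <= n_rep) {
    sol <- run_coupled(initials, k_rela0)
    times <- sol[, 1]
    med <- sol[, 1 + n * N_SPECIES + 1:3, drop = FALSE]
    cells <- to_cell_array(sol, n)
  } else {
    idx <- round(seq(1, n, length.out = n_rep))
    sol_rep <- run_coupled(initials[idx, , drop = FALSE],
                           if (is.null(k_rela0)) NULL else k_rela0[idx])
    times <- sol_rep[, 1]
    med <- sol_rep[, 1 + n_rep * N_SPECIES + 1:3, drop = FALSE]
    tnf_fun <- approxfun(times, med[, 1], rule = 2)
    block <- 250
    cells <- array(0, dim = c(length(times), N_SPECIES, n))
    for (ii in split(seq_len(n), ceiling(seq_len(n) / block))) {
      s <- integrate_system(initials[ii, , drop = FALSE], med0, params, sched,
                            t_grid, k_rela0 = if (is.null(k_rela0)) NULL else k_rela0[ii],
                            couple = FALSE, tnf_ext_fun = tnf_fun,
                            rtol = opts$rtol, atol = opts$atol, method = opts$method)
      cells[, , ii] <- to_cell_array(s, length(ii))
    }
  }
  dimnames(cells) <- list(NULL, SPECIES, paste0("cell_", seq_len(n)))
  medium <- data.frame(time_h = times,
                       tnf_ext = med[, 1], stnfr_free = med[, 2],
                       tnf_stnfr = med[, 3])
  obs <- ensemble_observables(times, cells)
  structure(list(times = times, cells = cells, medium = medium,
                 observables = obs, spec = spec, params = params,
                 n = n),
            class = "qlmac_ensemble")
}

ensemble_observables <- function(times, cells) {
  n <- dim(cells)[3]
  nt <- length(times)
  total <- cells[, "nfkb_ikb_c", ] + cells[, "nfkb_c", ] + cells[, "nfkb_n", ]
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cell_id = i, time_h = times,
               total = if (n == 1) total else total[, i],
               nuclear = cells[, "nfkb_n", i],
               cytoplasmic = cells[, "nfkb_ikb_c", i] + cells[, "nfkb_c", i],
               mch_mat = cells[, "mch_mat", i],
               tnf_intra = cells[, "tnf_intra", i],
               cum_sec = cells[, "cum_sec", i])
  }))
}

#' @export
print.qlmac_ensemble <- function(x, ...) {
  cat(sprintf("<qlmac_ensemble> %d cells, t in [%g, %g] h, density %s\n",
              x$n, min(x$times), max(x$times), x$spec$density_label))
  invisible(x)
}

#' Per-cell observable snapshot at one time
#'
#' @param ensemble a [simulate_population()] result.
#' @param t time (h) that must be on the simulated output grid (no
#'   extrapolation or interpolation).
#' @return data.frame with one row per cell: `cell_id`, `total`, `nuclear`,
#'   `cytoplasmic`, `mch_mat`, `tnf_intra`, `cum_sec`.
#' @export
snapshot <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "qlmac_ensemble"))
  i <- which(abs(ensemble$times - t) < 1e-9)
  if (length(i) != 1) {
    stop("t = ", t, " is not on the simulated grid [",
         min(ensemble$times), ", ", max(ensemble$times), "]")
  }
  cells <- ensemble$cells
  data.frame(
    cell_id = seq_len(ensemble$n),
    total = cells[i, "nfkb_ikb_c", ] + cells[i, "nfkb_c", ] + cells[i, "nfkb_n", ],
    nuclear = cells[i, "nfkb_n", ],
    cytoplasmic = cells[i, "nfkb_ikb_c", ] + cells[i, "nfkb_c", ],
    mch_mat = cells[i, "mch_mat", ],
    tnf_intra = cells[i, "tnf_intra", ],
    cum_sec = cells[i, "cum_sec", ]
  )
}
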