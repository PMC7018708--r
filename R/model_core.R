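# Single-cell reaction network and deterministic simulation.
#
# Species layout (per cell, all concentrations in a.u., time in h):
#   a_tlr4, a_tnfr, a_il10r : active receptor fractions in [0, 1]
#   ikk                     : active IKK fraction in [0, 1]
#   nfkb_ikb_c              : cytoplasmic NF-kB.IkB complex
#   nfkb_c, nfkb_n          : free cytoplasmic / nuclear NF-kB
#   ikb                     : free IkB
#   rela_mrna               : Rela transcript (FBD target)
#   tnf_mrna, tnf_intra     : Tnf transcript / intracellular TNF protein
#   mch_mrna, mch_imm, mch_mat : mCherry transcript, immature, mature protein
#   sr, dsr                 : stabilizing / destabilizing regulation activities
#   cum_sec                 : cumulative secreted TNF flux (bookkeeping)

SPECIES <- c("a_tlr4", "a_tnfr", "a_il10r", "ikk",
             "nfkb_ikb_c", "nfkb_c", "nfkb_n", "ikb",
             "rela_mrna", "tnf_mrna", "tnf_intra",
             "mch_mrna", "mch_imm", "mch_mat", "sr", "dsr", "cum_sec")
N_SPECIES <- length(SPECIES)
FRACTION_SPECIES <- c("a_tlr4", "a_tnfr", "a_il10r", "ikk", "sr", "dsr")

hill <- function(x, K, h) {
  x <- pmax(x, 0)
  xh <- x^h
  xh / (K^h + xh)
}

#' Construct a cell state vector
#'
#' @param ... name = value overrides for the species listed in `SPECIES`;
#'   unspecified species are 0.
#' @return Named numeric vector of length 17.
#' @export
cell_state <- function(...) {
  s <- setNames(numeric(N_SPECIES), SPECIES)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), SPECIES)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    s[names(over)] <- unlist(over)
  }
  s
}

# Vectorised right-hand side over an N x 17 state matrix. `inputs` supplies
# scalars u_lps, u_pma, u_il10, bfa, tnf_ext (already evaluated at time t) and
# the logical fbd flag. Returns an N x 17 matrix of rates plus the per-cell
# secretion flux as attribute "sec_flux".
cell_rates <- function(S, pl, inputs, k_rela0 = NULL) {
  a_tlr4 <- S[, 1L]; a_tnfr <- S[, 2L]; a_il10r <- S[, 3L]; ikk <- S[, 4L]
  cplx <- S[, 5L]; nfkb_c <- S[, 6L]; nfkb_n <- S[, 7L]; ikb <- S[, 8L]
  rela_m <- S[, 9L]; tnf_m <- S[, 10L]; tnf_p <- S[, 11L]
  mch_m <- S[, 12L]; mch_i <- S[, 13L]; mch_f <- S[, 14L]
  sr <- S[, 15L]; dsr <- S[, 16L]
  if (is.null(k_rela0)) k_rela0 <- pl$k_rela0

  d_tlr4 <- pl$kon_tlr4 * inputs$u_lps * (1 - a_tlr4) - pl$koff_tlr4 * a_tlr4
  d_tnfr <- pl$kon_tnfr * inputs$tnf_ext * (1 - a_tnfr) - pl$koff_tnfr * a_tnfr
  d_il10r <- pl$kon_il10r * inputs$u_il10 * (1 - a_il10r) - pl$koff_il10r * a_il10r

  # slow negative regulation of IKK (A20-like), co-induced with DSR, shuts
  # signalling down late in the response
  ikk_drive <- (pl$m1 * pl$k_ikk_tlr4 * a_tlr4 +
                pl$k_ikk_pkc * inputs$u_pma +
                pl$m5 * pl$k_ikk_tnfr * a_tnfr) *
    pmax(1 - pl$f_adapt * dsr, 0) / (1 + pl$g_il10_ikk * a_il10r)
  d_ikk <- ikk_drive * (1 - ikk) - pl$k_ikk_off * ikk

  release <- pl$k_rel * ikk * cplx
  recapture <- pl$k_nbind * ikb * nfkb_n
  d_cplx <- recapture + pl$k_trl_rela * rela_m - release - pl$d_rela * cplx
  d_nfkb_c <- release - pl$k_imp * nfkb_c - pl$d_rela * nfkb_c
  d_nfkb_n <- pl$k_imp * nfkb_c - recapture - pl$d_rela * nfkb_n
  d_ikb <- pl$k_ikb0 + pl$k_ikb_ind * hill(nfkb_n, pl$K_ikb, pl$h_ikb) -
    recapture - pl$d_ikb * ikb

  fbd_txn <- if (inputs$fbd) pl$m6 * pl$k_fbd * hill(nfkb_n, pl$K_fbd, pl$h_fbd) else 0
  d_rela_m <- k_rela0 + fbd_txn - pl$d_rela_m * rela_m

  txn <- pl$m2 * pl$k_txn * hill(nfkb_n, pl$K_txn, pl$h_txn)
  deg_m <- pl$d_m * (1 + pl$m4 * pl$a_dsr * dsr + pl$a_il10 * a_il10r) /
    (1 + pl$m3 * pl$a_sr * sr)
  d_tnf_m <- txn - deg_m * tnf_m

  trl <- pl$k_trl * (1 + pl$m5 * pl$b_tnfr * a_tnfr) / (1 + pl$b_il10 * a_il10r)
  sec_flux <- pl$k_sec * (1 - inputs$bfa) * tnf_p
  d_tnf_p <- trl * tnf_m - sec_flux - pl$d_tnf * tnf_p

  d_mch_m <- pl$k_mch_scale * txn - pl$d_mch_m * mch_m
  d_mch_i <- pl$k_trl_mch * mch_m - pl$k_mat * mch_i - pl$d_mch * mch_i
  d_mch_f <- pl$k_mat * mch_i - pl$d_mch * mch_f

  d_sr <- pl$k_sr_on * a_tlr4 * (1 - sr) - pl$k_sr_off * sr
  d_dsr <- pl$k_dsr_on * a_tlr4 * (1 - dsr) - pl$k_dsr_off * dsr

  out <- cbind(d_tlr4, d_tnfr, d_il10r, d_ikk, d_cplx, d_nfkb_c, d_nfkb_n,
               d_ikb, d_rela_m, d_tnf_m, d_tnf_p, d_mch_m, d_mch_i, d_mch_f,
               d_sr, d_dsr, sec_flux, deparse.level = 0)
  attr(out, "sec_flux") <- sec_flux
  out
}

#' Single-cell reaction rates
#'
#' Evaluates the right-hand side of the single-cell ODE system at one state,
#' given the instantaneous inputs. Mechanism multipliers scale exactly:
#' m1 x (TLR4 -> IKK), m2 x k_txn, m3 x a_sr, m4 x a_dsr, m5 x (TNFR -> IKK
#' and b_tnfr), m6 x k_fbd. Secretion is `k_sec * tnf_intra * (1 - bfa)`.
#'
#' @param state named species vector (see [cell_state()]).
#' @param params parameter vector ([default_params()]).
#' @param inputs list with `u_lps`, `u_pma`, `u_il10`, `bfa`, `tnf_ext`
#'   (numbers, default 0) and `fbd` (logical, default FALSE).
#' @return Named vector of rates, one per species.
#' @export
#' @examples
#' s <- cell_state(nfkb_ikb_c = 1, ikb = 0.03)
#' derivatives(s, default_params(), list(u_lps = 1, fbd = TRUE))
derivatives <- function(state, params, inputs = list()) {
  if (!all(is.finite(state))) {
    stop("non-finite state value in: ",
         paste(SPECIES[!is.finite(state)], collapse = ", "))
  }
  validate_params(params)
  s <- cell_state()
  s[names(state)] <- state
  defaults <- list(u_lps = 0, u_pma = 0, u_il10 = 0, bfa = 0, tnf_ext = 0,
                   fbd = FALSE)
  inputs <- modifyList(defaults, inputs)
  r <- cell_rates(matrix(s, nrow = 1), as.list(params), inputs)
  setNames(as.numeric(r), SPECIES)
}

# Integrate the (possibly multi-cell) system piecewise between input
# discontinuities. `cells0`: N x 17 matrix; `medium0`: length-3 vector
# (tnf_ext, stnfr_free, tnf_stnfr); `tnf_ext_fun`: NULL for coupled medium, or
# a function of t forcing extracellular TNF (cells then do not feed back).
integrate_system <- function(cells0, medium0, params, sched, times,
                             k_rela0 = NULL, couple = TRUE,
                             density0 = NULL, t_plate = NULL,
                             tnf_ext_fun = NULL,
                             rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  pl <- as.list(params)
  n <- nrow(cells0)
  y0 <- c(as.numeric(cells0), medium0)
  fbd <- sched$fbd
  u_lps <- sched$u_lps; u_pma <- sched$u_pma; u_il10 <- sched$u_il10
  bfa <- sched$bfa
  dens_mult <- sched$density_mult

  rhs <- function(t, y, parms) {
    S <- matrix(y[seq_len(n * N_SPECIES)], nrow = n)
    med <- y[n * N_SPECIES + 1:3]
    tnf_ext <- if (is.null(tnf_ext_fun)) med[1] else tnf_ext_fun(t)
    inp <- list(u_lps = u_lps(t), u_pma = u_pma(t), u_il10 = u_il10(t),
                bfa = bfa(t), tnf_ext = max(tnf_ext, 0), fbd = fbd)
    R <- cell_rates(S, pl, inp, k_rela0)
    if (couple && is.null(tnf_ext_fun)) {
      dens <- dens_mult
      if (!is.null(density0)) {
        dens <- dens_mult * grow_density(1, t - t_plate,
                                         c(rate = pl$growth_rate, cap = pl$growth_cap))
      }
      mean_sec <- mean(attr(R, "sec_flux"))
      bind <- pl$k_stnfr * max(med[1], 0) * max(med[2], 0)
      d_ext <- dens * mean_sec - pl$d_tnf_ext * med[1] -
        bind - pl$k_uptake * dens * med[1]
      dmed <- c(d_ext, -bind, bind)
    } else {
      dmed <- c(0, 0, 0)
    }
    list(c(as.numeric(R), dmed))
  }

  seg_bounds <- sort(unique(c(min(times), sched$event_times, max(times))))
  seg_bounds <- seg_bounds[seg_bounds >= min(times) & seg_bounds <= max(times)]
  out <- NULL
  y <- y0
  for (i in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[i]; t1 <- seg_bounds[i + 1]
    seg_t <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    sol <- deSolve::ode(y = y, times = seg_t, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE solver failed on [", t0, ", ", t1, "] h; istate = ",
           attr(sol, "istate")[1L], ". Consider loosening rtol/atol.")
    }
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% times
    if (!is.null(out)) keep <- keep & !(sol[, 1] %in% out[, 1])
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  neg <- out[, -1, drop = FALSE]
  if (any(neg < -1e-6)) {
    stop("negative species beyond tolerance (min = ", signif(min(neg), 3), ")")
  }
  out[, -1][out[, -1] < 0] <- 0
  out
}

trajectory_from_matrix <- function(sol, n = 1) {
  times <- sol[, 1]
  S <- sol[, 1 + seq_len(n * N_SPECIES), drop = FALSE]
  med <- sol[, 1 + n * N_SPECIES + 1:3, drop = FALSE]
  colnames(med) <- c("tnf_ext", "stnfr_free", "tnf_stnfr")
  list(times = times, states = S, medium = med)
}

#' Simulate one isolated cell
#'
#' Deterministically integrates the single-cell network under a perturbation
#' schedule. The cell is treated in isolation: extracellular TNF is an
#' exogenous input (`tnf_ext_fun`, zero by default), so there is no
#' autocrine/paracrine feedback — use [simulate_population()] for a coupled
#' ensemble. Pretreatments start at negative times; the stimulus steps on at
#' t = 0. Integration is piecewise between input discontinuities with a
#' stiff-capable solver (lsoda, rtol 1e-6, atol 1e-9).
#'
#' @param initial named species vector (e.g. from [basal_state()]).
#' @param params parameter vector.
#' @param spec a [perturbation()] (or a prebuilt [build_schedule()] list).
#' @param t_grid output times (h); default `seq(t_start, 24, by = 0.1)`.
#' @param tnf_ext_fun optional function of t giving extracellular TNF (a.u.).
#' @param solver_opts list; supported entries `rtol`, `atol`, `method`.
#' @return Object of class `qlmac_trajectory`: list with `times`, `states`
#'   (time x species matrix) and `observables` (data.frame with `time_h`,
#'   `total`, `nuclear`, `cytoplasmic`, `mch_mat`, `tnf_intra`, `cum_sec`).
#' @export
#' @examples
#' p <- default_params()
#' s0 <- basal_state(p)
#' tr <- simulate_cell(s0, p, perturbation(lps = 100, stnfr = 1))
#' head(tr$observables)
simulate_cell <- function(initial, params, spec, t_grid = NULL,
                          tnf_ext_fun = NULL, solver_opts = list()) {
  validate_params(params)
  sched <- if (inherits(spec, "perturbation_spec")) build_schedule(spec, params) else spec
  if (is.null(t_grid)) t_grid <- seq(sched$t_start, 24, by = 0.1)
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  s0 <- cell_state()
  s0[names(initial)] <- initial
  opts <- modifyList(list(rtol = 1e-6, atol = 1e-9, method = "lsoda"), solver_opts)
  sol <- integrate_system(matrix(s0, nrow = 1), c(0, sched$stnfr0, 0), params,
                          sched, t_grid, couple = FALSE,
                          tnf_ext_fun = tnf_ext_fun,
                          rtol = opts$rtol, atol = opts$atol, method = opts$method)
  parts <- trajectory_from_matrix(sol, n = 1)
  S <- parts$states
  colnames(S) <- SPECIES
  obs <- data.frame(
    time_h = parts$times,
    total = S[, "nfkb_ikb_c"] + S[, "nfkb_c"] + S[, "nfkb_n"],
    nuclear = S[, "nfkb_n"],
    cytoplasmic = S[, "nfkb_ikb_c"] + S[, "nfkb_c"],
    mch_mat = S[, "mch_mat"],
    tnf_intra = S[, "tnf_intra"],
    cum_sec = S[, "cum_sec"]
  )
  structure(list(times = parts$times, states = S, observables = obs,
                 schedule = sched),
            class = "qlmac_trajectory")
}

#' Resting (pre-stimulus) cell state
#'
#' Equilibrates the unstimulated single-cell system until the relative rate of
#' change of every species is below `tol` per hour. At rest NF-kB is
#' sequestered in the cytoplasmic complex (basal RelA synthesis balances
#' protein turnover), IKK is off, and the Tnf promoter is silent, so
#' `tnf_mrna` and `tnf_intra` are ~0.
#'
#' @param params parameter vector.
#' @param tol relative-change convergence tolerance per hour.
#' @param max_hours cap on equilibration time.
#' @param initial optional starting guess (defaults to an analytic estimate).
#' @return Named species vector at rest.
#' @export
basal_state <- function(params, tol = 1e-6, max_hours = 4000, initial = NULL) {
  validate_params(params)
  pl <- as.list(params)
  if (is.null(initial)) {
    rela_m <- pl$k_rela0 / max(pl$d_rela_m, 1e-12)
    cplx <- if (pl$d_rela > 0) pl$k_trl_rela * rela_m / pl$d_rela else 0
    initial <- cell_state(rela_mrna = rela_m, nfkb_ikb_c = cplx,
                          ikb = pl$k_ikb0 / max(pl$d_ikb, 1e-12))
  }
  sched <- build_schedule(perturbation(), params)
  s <- cell_state(); s[names(initial)] <- initial
  t_span <- 200
  repeat {
    sol <- integrate_system(matrix(s, nrow = 1), c(0, 0, 0), params, sched,
                            times = c(0, t_span), couple = FALSE)
    s_new <- sol[nrow(sol), 1 + seq_len(N_SPECIES)]
    rate <- derivatives(setNames(s_new, SPECIES), params, list())
    rel <- abs(rate) / pmax(abs(s_new), 1e-8)
    if (max(rel) < tol) {
      s <- setNames(as.numeric(s_new), SPECIES)
      s[["cum_sec"]] <- 0
      return(s)
    }
    if (t_span >= max_hours) {
      stop("basal equilibration did not converge; last two iterates differ by ",
           signif(max(abs(s_new - s)), 3), " (max relative rate ",
           signif(max(rel), 3), "/h)")
    }
    s <- setNames(as.numeric(s_new), SPECIES)
    t_span <- t_span * 2
  }
}
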