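# Two-round multi-objective evolutionary calibration of the cell model.

#' Summary statistics of a reporter trajectory
#'
#' Extracts the trajectory features used as calibration targets: peak time and
#' amplitude of the nuclear, cytoplasmic and total NF-kB reporter and of
#' mature mCherry (peak times refined by quadratic interpolation around the
#' grid argmax), the mCherry rise duration (stimulus to peak), the
#' cytoplasm:nucleus peak-amplitude ratio, and 12-hps trapezoid
#' time-integrals. Only times >= 0 (post-stimulus) are considered.
#'
#' @param traj a `qlmac_trajectory`, a `qlmac_ensemble` (its across-cell mean
#'   trajectory is summarised), or a data.frame of observables with `time_h`.
#' @return Named list; `flat` is TRUE if any reporter peaks at the window end
#'   (no interior maximum).
#' @export
summarize_trajectory <- function(traj) {
  obs <- if (inherits(traj, "qlmac_trajectory")) traj$observables
  else if (inherits(traj, "qlmac_ensemble")) mean_observables(traj)
  else traj
  obs <- obs[obs$time_h >= 0, , drop = FALSE]
  if (max(obs$time_h) < 24) stop("trajectory must cover >= 24 h post-stimulus")
  t <- obs$time_h
  pk <- function(v) quad_peak(t, v)
  peaks <- list(total = pk(obs$total), nuclear = pk(obs$nuclear),
                cytoplasmic = pk(obs$cytoplasmic), mch = pk(obs$mch_mat))
  i12 <- t <= 12
  integ <- function(v) trapz(t[i12], v[i12])
  flat <- any(vapply(peaks, function(p) p$flat, logical(1)))
  list(
    peak_time = vapply(peaks, function(p) p$time, numeric(1)),
    peak_amp = vapply(peaks, function(p) p$value, numeric(1)),
    mch_rise = peaks$mch$time,
    cn_ratio = peaks$cytoplasmic$value / peaks$nuclear$value,
    integral_12h = c(total = integ(obs$total), mch = integ(obs$mch_mat),
                     tnf_intra = integ(obs$tnf_intra)),
    flat = flat
  )
}

# quadratic-interpolated argmax on a grid; flags monotone trajectories whose
# maximum sits at the window end
quad_peak <- function(t, v) {
  i <- which.max(v)
  if (i == length(v) || i == 1) {
    return(list(time = t[i], value = v[i], flat = i == length(v)))
  }
  t3 <- t[(i - 1):(i + 1)]; v3 <- v[(i - 1):(i + 1)]
  denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
  a <- (t3[3] * (v3[2] - v3[1]) + t3[2] * (v3[1] - v3[3]) + t3[1] * (v3[3] - v3[2])) / denom
  b <- (t3[3]^2 * (v3[1] - v3[2]) + t3[2]^2 * (v3[3] - v3[1]) + t3[1]^2 * (v3[2] - v3[3])) / denom
  if (a >= 0) return(list(time = t[i], value = v[i], flat = FALSE))
  tp <- -b / (2 * a)
  tp <- min(max(tp, t3[1]), t3[3])
  c0 <- v3[1] - a * t3[1]^2 - b * t3[1]
  list(time = tp, value = a * tp^2 + b * tp + c0, flat = FALSE)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# across-cell mean of ensemble observables on the common grid
mean_observables <- function(ens) {
  obs <- ens$observables
  agg <- aggregate(obs[, c("total", "nuclear", "cytoplasmic", "mch_mat",
                           "tnf_intra", "cum_sec")],
                   by = list(time_h = obs$time_h), FUN = mean)
  agg[order(agg$time_h), ]
}

# ---- fit objectives ---------------------------------------------------------

#' Calibration objectives
#'
#' `fit_objective()` bundles one perturbation condition with target summary
#' values and tolerances (SDs). `round1_objectives()` returns the focused
#' cell-intrinsic objective — the sTNFR + LPS condition (TNFR feedback
#' excluded), scored on the NF-kB reporter peak statistics.
#' `round2_objectives()` spans the full condition panel: sTNFR + LPS, LPS
#' alone, IL-10 pretreatment + LPS, and the unstimulated control (total
#' reporter flatness).
#'
#' Default targets are the reported single-cell trajectory statistics: total
#' reporter peak 14 +/- 4 hps, nuclear 10 +/- 6 hps, cytoplasmic 15 +/- 4
#' hps, cytoplasm:nucleus peak ratio 1.4 +/- 0.4, mCherry peak 18 +/- 5 hps,
#' mCherry rise 16 +/- 2 hps (LPS alone) and 12 +/- 3 hps (IL-10).
#'
#' @param spec a [perturbation()].
#' @param targets named numeric; names among `t_total`, `t_nuclear`, `t_cyto`,
#'   `cn_ratio`, `t_mch`, `mch_rise`, `flat_total`.
#' @param sds named numeric tolerances (same names).
#' @param weights optional named numeric (default 1 each).
#' @param coupled logical; simulate with medium coupling (single mean cell).
#' @return Object of class `qlmac_objective`.
#' @export
fit_objective <- function(spec, targets, sds, weights = NULL, coupled = FALSE) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (is.null(weights)) weights <- setNames(rep(1, length(targets)), names(targets))
  if (all(weights == 0)) stop("weights must not be all zero")
  if (any(weights < 0)) stop("weights must be >= 0")
  stopifnot(identical(sort(names(targets)), sort(names(sds))))
  structure(list(spec = spec, targets = targets, sds = sds,
                 weights = weights[names(targets)], coupled = coupled),
            class = "qlmac_objective")
}

#' @rdname fit_objective
#' @export
round1_objectives <- function() {
  list(fit_objective(
    perturbation(lps = 100, stnfr = 1, density = "high"),
    targets = c(t_total = 14, t_nuclear = 10, t_cyto = 15, cn_ratio = 1.4,
                t_mch = 18),
    sds = c(t_total = 4, t_nuclear = 6, t_cyto = 4, cn_ratio = 0.4, t_mch = 5),
    coupled = FALSE))
}

#' @rdname fit_objective
#' @export
round2_objectives <- function() {
  list(
    round1_objectives()[[1]],
    fit_objective(perturbation(lps = 100, density = "high"),
                  targets = c(mch_rise = 16), sds = c(mch_rise = 2),
                  coupled = TRUE),
    fit_objective(perturbation(lps = 100, il10 = 10, density = "high"),
                  targets = c(mch_rise = 12), sds = c(mch_rise = 3),
                  coupled = TRUE),
    fit_objective(perturbation(lps = 0.1, stnfr = 1, density = "high"),
                  targets = c(flat_total = 1), sds = c(flat_total = 0.05),
                  coupled = FALSE)
  )
}

# simulate one objective's condition for a mean cell and extract its summary
# fields; returns named vector aligned with obj$targets
objective_summaries <- function(params, obj, basal = NULL) {
  if (is.null(basal)) basal <- basal_state(params)
  tr <- if (obj$coupled) {
    simulate_population(basal, params, obj$spec, n = 1)
  } else {
    simulate_cell(basal, params, obj$spec)
  }
  s <- summarize_trajectory(tr)
  obs <- if (obj$coupled) mean_observables(tr) else tr$observables
  flat_ratio <- {
    i0 <- which.min(abs(obs$time_h)); i24 <- which.max(obs$time_h)
    obs$total[i24] / obs$total[i0]
  }
  all_vals <- c(t_total = unname(s$peak_time["total"]),
                t_nuclear = unname(s$peak_time["nuclear"]),
                t_cyto = unname(s$peak_time["cytoplasmic"]),
                cn_ratio = s$cn_ratio,
                t_mch = unname(s$peak_time["mch"]),
                mch_rise = s$mch_rise,
                flat_total = flat_ratio)
  all_vals[names(obj$targets)]
}

# weighted standardized squared residuals for one objective (vector per field)
objective_residuals <- function(params, obj, basal = NULL) {
  v <- try(objective_summaries(params, obj, basal), silent = TRUE)
  if (inherits(v, "try-error") || anyNA(v)) {
    return(setNames(rep(1e3, length(obj$targets)), names(obj$targets)))
  }
  obj$weights * ((v - obj$targets) / obj$sds)^2
}

# ---- parameter families and the evolutionary engine -------------------------

ROUND1_PARAMS <- c("kon_tlr4", "k_ikk_tlr4", "k_ikk_off", "k_rel", "k_imp",
                   "k_nbind", "k_ikb0", "k_ikb_ind", "K_ikb", "d_ikb",
                   "k_fbd", "K_fbd", "d_rela", "d_rela_m",
                   "k_dsr_on", "k_dsr_off")
ROUND2_PARAMS <- c("g_il10_ikk", "d_mch_m", "d_mch", "K_txn", "k_mch_scale",
                   "d_m", "a_sr", "a_dsr", "a_il10", "k_trl", "k_sec")

# fast nondominated sort; returns list of index vectors (fronts)
nds_fronts <- function(F) {
  n <- nrow(F)
  dominates <- function(i, j) all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  dom_count <- integer(n)
  dom_set <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && dominates(i, j)) dom_set[[i]] <- c(dom_set[[i]], j)
    else if (i != j && dominates(j, i)) dom_count[i] <- dom_count[i] + 1
  }
  fronts <- list()
  current <- which(dom_count == 0)
  while (length(current)) {
    fronts[[length(fronts) + 1]] <- current
    nxt <- integer(0)
    for (i in current) for (j in dom_set[[i]]) {
      dom_count[j] <- dom_count[j] - 1
      if (dom_count[j] == 0) nxt <- c(nxt, j)
    }
    current <- nxt
  }
  fronts
}

crowding_distance <- function(F) {
  n <- nrow(F); d <- numeric(n)
  for (k in seq_len(ncol(F))) {
    o <- order(F[, k])
    rng <- F[o[n], k] - F[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], k] - F[o[1:(n - 2)], k]) / rng
    }
  }
  d
}

# NSGA-II-style multi-objective GA on log10-parameter genomes.
# eval_fn(matrix of genomes) -> objective matrix (rows = individuals).
nsga2_engine <- function(eval_fn, lower, upper, pop = 64, generations = 200,
                         seed = 1, x_init = NULL, p_mut = 0.25, mut_sd = 0.15) {
  d <- length(lower)
  withr_seed(seed, {
    X <- matrix(runif(pop * d, rep(lower, each = pop), rep(upper, each = pop)),
                nrow = pop)
    if (!is.null(x_init)) {
      k <- min(nrow(x_init), pop)
      X[seq_len(k), ] <- x_init[seq_len(k), , drop = FALSE]
    }
    F <- eval_fn(X)
    for (gen in seq_len(generations)) {
      fronts <- nds_fronts(F)
      rank <- integer(nrow(F))
      for (fi in seq_along(fronts)) rank[fronts[[fi]]] <- fi
      crowd <- numeric(nrow(F))
      for (fr in fronts) crowd[fr] <- crowding_distance(F[fr, , drop = FALSE])
      tournament <- function() {
        ij <- sample.int(nrow(X), 2)
        i <- ij[1]; j <- ij[2]
        if (rank[i] < rank[j] || (rank[i] == rank[j] && crowd[i] > crowd[j])) i else j
      }
      kids <- matrix(0, pop, d)
      for (k in seq_len(pop)) {
        a <- X[tournament(), ]; b <- X[tournament(), ]
        w <- runif(d, -0.1, 1.1)            # blend crossover with slight expansion
        child <- w * a + (1 - w) * b
        mut <- runif(d) < p_mut
        child[mut] <- child[mut] + rnorm(sum(mut), 0, mut_sd * (upper - lower)[mut])
        kids[k, ] <- pmin(pmax(child, lower), upper)
      }
      Fk <- eval_fn(kids)
      XX <- rbind(X, kids); FF <- rbind(F, Fk)
      fronts <- nds_fronts(FF)
      sel <- integer(0)
      for (fr in fronts) {
        if (length(sel) + length(fr) <= pop) sel <- c(sel, fr)
        else {
          cd <- crowding_distance(FF[fr, , drop = FALSE])
          sel <- c(sel, fr[order(cd, decreasing = TRUE)][seq_len(pop - length(sel))])
          break
        }
      }
      X <- XX[sel, , drop = FALSE]
      F <- FF[sel, , drop = FALSE]
    }
  })
  first <- nds_fronts(F)[[1]]
  list(X = X, F = F, front = first)
}

#' Round-1 calibration: focused cell-intrinsic NF-kB model
#'
#' Fits the round-1 parameter subset (TLR4 signalling; NF-kB activation,
#' nucleocytoplasmic translocation and inactivation; IkB expression; FBD) to
#' the sTNFR + LPS condition, which excludes TNFR intercellular feedback, on
#' a homogeneous mean cell. The search is an NSGA-II-style evolutionary
#' algorithm over log-uniform bounds centred on the sweep values in `base`;
#' each target field's standardized squared residual is one objective
#' component, and the returned family is the final Pareto-nondominated
#' archive.
#'
#' @param objectives list of [fit_objective()]s (default [round1_objectives()]);
#'   round 1 requires the sTNFR + LPS condition only.
#' @param config list: `pop` (default 32), `generations` (default 40),
#'   `span` (log10 half-width of bounds, default 0.5), `min_family` (minimum
#'   family size, padded from the next fronts if needed, default 5).
#' @param seed integer; the run is fully reproducible.
#' @param base parameter vector supplying sweep centres and the fixed
#'   (non-round-1) values.
#' @return Object of class `qlmac_family`: list with `members` (list of full
#'   parameter vectors), `objectives` (matrix), `best` (member with lowest
#'   summed residual), `free` (names of round-1 parameters).
#' @export
fit_round1 <- function(objectives = round1_objectives(), config = list(),
                       seed = 1, base = default_params()) {
  cfg <- modifyList(list(pop = 32, generations = 40, span = 0.5,
                         min_family = 5), config)
  validate_params(base)
  if (any(vapply(objectives, function(o) o$spec$stnfr == 0, logical(1)))) {
    stop("round-1 objectives must use the sTNFR condition (TNFR feedback excluded)")
  }
  free <- ROUND1_PARAMS
  center <- log10(base[free])
  lower <- center - cfg$span
  upper <- center + cfg$span
  eval_fn <- function(X) {
    t(apply(X, 1, function(x) {
      p <- base
      p[free] <- 10^x
      res <- unlist(lapply(objectives, function(o) objective_residuals(p, o)))
      unname(res)
    }))
  }
  fit <- nsga2_engine(eval_fn, lower, upper, pop = cfg$pop,
                      generations = cfg$generations, seed = seed,
                      x_init = matrix(center, nrow = 1))
  sel <- fit$front
  if (length(sel) < cfg$min_family) {
    extra <- order(rowSums(fit$F))
    sel <- unique(c(sel, extra))[seq_len(min(cfg$min_family, nrow(fit$X)))]
  }
  members <- lapply(sel, function(i) {
    p <- base
    p[free] <- 10^fit$X[i, ]
    p
  })
  obj_mat <- fit$F[sel, , drop = FALSE]
  best <- members[[which.min(rowSums(obj_mat))]]
  structure(list(members = members, objectives = obj_mat, best = best,
                 free = free, seed = seed),
            class = "qlmac_family")
}

#' @export
print.qlmac_family <- function(x, ...) {
  cat(sprintf("<qlmac_family> %d Pareto members over %d objective components\n",
              length(x$members), ncol(x$objectives)))
  invisible(x)
}

pareto_archive_df <- function(family) {
  X <- do.call(rbind, lapply(family$members, function(p) p[family$free]))
  cbind(as.data.frame(X),
        as.data.frame(family$objectives) |>
          setNames(paste0("obj_", seq_len(ncol(family$objectives)))))
}

#' Round-2 calibration: full model across all conditions
#'
#' Simultaneous fit to the full condition panel. Round-1 parameters are
#' constrained to members of the round-1 family (one gene selects the
#' member); the round-2 subset (Tnf transcription/stability/translation,
#' mCherry expression, IL-10 effects, secretion) undergoes a free log-uniform
#' search. Objectives are scalarized per condition (one component per
#' condition) and the single best full parameter set is returned.
#'
#' @param objectives list of [fit_objective()]s spanning >= 4 conditions
#'   (default [round2_objectives()]).
#' @param family a `qlmac_family` from [fit_round1()].
#' @param config list: `pop` (default 24), `generations` (default 20),
#'   `span` (default 0.4).
#' @param seed integer.
#' @param base parameter vector for sweep centres of the round-2 subset.
#' @return List with `params` (best full parameter vector), `value` (summed
#'   residual), `residuals` (per-condition), `member` (round-1 family index
#'   used), `trace`.
#' @export
fit_round2 <- function(objectives = round2_objectives(), family,
                       config = list(), seed = 1, base = default_params()) {
  cfg <- modifyList(list(pop = 24, generations = 20, span = 0.4), config)
  stopifnot(inherits(family, "qlmac_family"))
  if (length(family$members) == 0) stop("round-1 family is empty")
  if (length(objectives) < 4) stop("round-2 needs >= 4 perturbation conditions")
  free <- ROUND2_PARAMS
  center <- log10(pmax(base[free], 1e-8))
  lower <- c(0, center - cfg$span)       # gene 1: family member selector
  upper <- c(1, center + cfg$span)
  nm <- length(family$members)
  decode <- function(x) {
    idx <- 1 + min(nm - 1, floor(x[1] * nm))
    p <- family$members[[idx]]
    p[free] <- 10^x[-1]
    list(params = p, member = idx)
  }
  per_condition <- function(p) {
    basal <- basal_state(p)
    vapply(objectives, function(o) sum(objective_residuals(p, o, basal)),
           numeric(1))
  }
  eval_fn <- function(X) {
    t(apply(X, 1, function(x) per_condition(decode(x)$params)))
  }
  fit <- nsga2_engine(eval_fn, lower, upper, pop = cfg$pop,
                      generations = cfg$generations, seed = seed,
                      x_init = matrix(c(0.001, center), nrow = 1))
  tot <- rowSums(fit$F)
  i <- which.min(tot)
  dec <- decode(fit$X[i, ])
  res <- fit$F[i, ]
  names(res) <- vapply(objectives, function(o) {
    paste0(if (o$spec$lps > 0) paste0("lps", o$spec$lps) else "none",
           if (o$spec$stnfr > 0) "_stnfr" else "",
           if (o$spec$il10 > 0) "_il10" else "")
  }, character(1))
  list(params = dec$params, value = tot[i], residuals = res,
       member = dec$member,
       trace = list(front_size = length(fit$front), seed = seed))
}

#' Per-cell trajectory summaries for an ensemble
#'
#' Computes, for every cell of a simulated ensemble, the peak times (h post
#' stimulus, quadratic-interpolated) and amplitudes of the total, nuclear and
#' cytoplasmic reporter and mature mCherry, the cytoplasm:nucleus
#' peak-amplitude ratio and the mCherry rise duration (stimulus to peak).
#'
#' @param ensemble a [simulate_population()] result covering >= 24 hps.
#' @return data.frame with one row per cell.
#' @export
summarize_cells <- function(ensemble) {
  stopifnot(inherits(ensemble, "qlmac_ensemble"))
  obs <- ensemble$observables
  do.call(rbind, lapply(split(obs, obs$cell_id), function(o) {
    o <- o[order(o$time_h), ]
    s <- summarize_trajectory(o)
    data.frame(cell_id = o$cell_id[1],
               t_total = unname(s$peak_time["total"]),
               t_nuclear = unname(s$peak_time["nuclear"]),
               t_cyto = unname(s$peak_time["cytoplasmic"]),
               t_mch = unname(s$peak_time["mch"]),
               mch_rise = s$mch_rise,
               cn_ratio = s$cn_ratio,
               amp_total = unname(s$peak_amp["total"]),
               amp_mch = unname(s$peak_amp["mch"]),
               flat = s$flat)
  }))
}
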