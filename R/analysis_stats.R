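# Quantification and in-silico experiments: bimodality thresholding, CV
# timecourses, permutation-tested correlations, 12 hps readouts, mechanism
# and robustness sweeps, heterogeneous-vs-homogeneous comparisons.

#' Nadir threshold between the two modes of a bimodal distribution
#'
#' Kernel density estimate (Gaussian kernel, Silverman bandwidth) on the log
#' scale; the threshold is the density minimum between the two highest local
#' maxima, and `fraction_high` is the share of samples above it. Because the
#' threshold is defined through ranks of the density between modes, the
#' fraction is invariant to monotone rescaling of the sample axis.
#'
#' @param samples numeric vector (log-scale values), length >= 100.
#' @param n_grid KDE grid size.
#' @return List with `threshold`, `fraction_high`, `modes` (locations of the
#'   two dominant maxima) and `unimodal` (flag; when TRUE, `threshold` and
#'   `fraction_high` are NA).
#' @export
#' @examples
#' x <- c(rnorm(5000, 0, 0.5), rnorm(5000, 4, 0.5))
#' nadir_threshold(x)$threshold  # ~2
nadir_threshold <- function(samples, n_grid = 512) {
  if (length(samples) < 100) stop("need >= 100 samples")
  d <- density(samples, bw = "nrd0", n = n_grid)
  y <- d$y
  # interior local maxima / minima on the KDE grid
  dy <- diff(y)
  s <- sign(dy)
  turns <- which(diff(s) != 0) + 1
  maxima <- turns[s[turns - 1] > 0 & s[turns] < 0]
  unimodal_out <- list(threshold = NA_real_, fraction_high = NA_real_,
                       modes = d$x[maxima], unimodal = TRUE)
  if (length(maxima) < 2) return(unimodal_out)
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  nadir <- between[which.min(y[between])]
  thr <- d$x[nadir]
  # require genuine bimodality: the minor mode must carry real mass and the
  # dip between the modes must be pronounced, else KDE wiggles on a unimodal
  # sample would masquerade as a second mode
  minor <- min(y[top2]); major <- max(y[top2])
  if (minor < 0.05 * major || y[nadir] > 0.9 * minor) return(unimodal_out)
  list(threshold = thr,
       fraction_high = mean(samples > thr),
       modes = d$x[top2],
       unimodal = FALSE)
}

#' Coefficient-of-variation timecourse across cells
#'
#' @param ensemble a [simulate_population()] result.
#' @param observable one of `"total"`, `"nuclear"`, `"cytoplasmic"`,
#'   `"mch_mat"`, `"tnf_intra"`, `"cum_sec"`.
#' @param mean_floor times where the across-cell mean falls below this floor
#'   are flagged with `cv = NA`.
#' @return data.frame with `time_h`, `mean`, `sd`, `cv` (SD/mean across
#'   cells, population SD with denominator n).
#' @export
cv_timecourse <- function(ensemble, observable = "mch_mat", mean_floor = 1e-8) {
  stopifnot(inherits(ensemble, "qlmac_ensemble"))
  if (ensemble$n < 2) stop("CV requires >= 2 cells")
  obs <- ensemble$observables
  if (!observable %in% names(obs)) stop("unknown observable: ", observable)
  sp <- split(obs[[observable]], obs$time_h)
  tt <- as.numeric(names(sp))
  o <- order(tt)
  m <- vapply(sp, mean, numeric(1))[o]
  # population SD (denominator n), the flow-cytometry convention
  s <- vapply(sp, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))[o]
  cv <- ifelse(m < mean_floor, NA_real_, s / m)
  data.frame(time_h = tt[o], mean = m, sd = s, cv = cv)
}

#' Permutation-tested R-squared between two per-cell quantities
#'
#' Least-squares R^2 of `y` on `x`, with a one-tailed permutation p-value:
#' `p = (1 + #permutations with R^2 >= observed) / (B + 1)`. For `n <= 7` the
#' full permutation set is enumerated instead of sampled, making the p-value
#' exact. The add-one correction bounds p below by `1/(B+1)`. A Gaussian-tail
#' approximation of the permutation null (fitted to the Fisher-z transformed
#' correlation) is reported alongside as `p_gauss`; reported p-values far
#' below `1/(B+1)` can only come from such a parametric extrapolation, so the
#' two estimators are kept clearly distinct.
#'
#' @param x,y numeric vectors, equal length >= 3, each with nonzero variance.
#' @param B number of random permutations (ignored when enumerating).
#' @param seed integer seed for the permutation draws.
#' @return List with `r2`, `p` (permutation), `p_gauss` (parametric tail,
#'   labelled approximation), `B_used`, `exhaustive`.
#' @export
r2_permutation <- function(x, y, B = 999, seed = 1) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("x and y must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in x or y")
  if (B < 999) stop("B must be >= 999")
  r_obs <- cor(x, y)
  r2_obs <- r_obs^2
  if (n <= 7) {
    perms <- permutations_all(n)
    r2_perm <- apply(perms, 1, function(idx) cor(x, y[idx])^2)
    # exhaustive: exact p without add-one (the identity is in the set)
    p <- mean(r2_perm >= r2_obs - 1e-12)
    B_used <- nrow(perms)
    exhaustive <- TRUE
    r_perm <- apply(perms, 1, function(idx) cor(x, y[idx]))
  } else {
    r_perm <- withr_seed(seed, {
      vapply(seq_len(B), function(i) cor(x, sample(y)), numeric(1))
    })
    r2_perm <- r_perm^2
    p <- (1 + sum(r2_perm >= r2_obs - 1e-12)) / (B + 1)
    B_used <- B
    exhaustive <- FALSE
  }
  # one-tailed Gaussian tail on Fisher z of the signed correlation
  z_perm <- atanh(pmin(pmax(r_perm, -1 + 1e-12), 1 - 1e-12))
  z_obs <- atanh(sign(r_obs) * min(abs(r_obs), 1 - 1e-12))
  p_gauss <- stats::pnorm(abs(z_obs), mean = mean(z_perm), sd = sd(z_perm),
                          lower.tail = FALSE)
  list(r2 = r2_obs, p = p, p_gauss = p_gauss, B_used = B_used,
       exhaustive = exhaustive)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' 12-hps per-cell readout triple
#'
#' Trapezoid time-integrals over [0, 12] hps of the total NF-kB reporter and
#' mature mCherry, plus the cumulative secreted TNF flux at 12 hps, per cell.
#'
#' @param ensemble a [simulate_population()] result spanning >= 12 hps.
#' @return data.frame: `cell_id`, `integ_total`, `integ_mch`, `cum_tnf`.
#' @export
readouts_12hps <- function(ensemble) {
  stopifnot(inherits(ensemble, "qlmac_ensemble"))
  if (max(ensemble$times) < 12) stop("simulation must span >= 12 hps")
  obs <- ensemble$observables
  obs <- obs[obs$time_h >= 0 & obs$time_h <= 12, ]
  out <- do.call(rbind, lapply(split(obs, obs$cell_id), function(o) {
    o <- o[order(o$time_h), ]
    data.frame(cell_id = o$cell_id[1],
               integ_total = trapz(o$time_h, o$total),
               integ_mch = trapz(o$time_h, o$mch_mat),
               cum_tnf = o$cum_sec[nrow(o)] - o$cum_sec[1])
  }))
  out[order(out$cell_id), ]
}

#' One-at-a-time mechanism-magnitude sweep
#'
#' Varies each mechanism multiplier over a grid (others held at 1x) and
#' records the mean 12-hps readout triple for the given condition. The
#' default grid is log2-spaced over 1/8x..8x and includes the 1x point.
#'
#' @param base parameter vector.
#' @param grid multiplier values (must include 1).
#' @param spec condition; default high density + LPS 100.
#' @param initials,k_rela0 optional population initial conditions (as in
#'   [simulate_population()]); default is a single mean cell.
#' @param mechanisms which of m1..m6 to sweep.
#' @return data.frame: `mechanism`, `multiplier`, `integ_total`, `integ_mch`,
#'   `cum_tnf` (means over cells).
#' @export
mechanism_sweep <- function(base, grid = 2^seq(-3, 3, 1),
                            spec = perturbation(lps = 100, density = "high"),
                            initials = NULL, k_rela0 = NULL,
                            mechanisms = paste0("m", 1:6)) {
  if (!any(abs(grid - 1) < 1e-12)) stop("grid must include the 1x point")
  if (is.null(initials)) initials <- basal_state(base)
  run <- function(p) {
    ens <- simulate_population(initials, p, spec, k_rela0 = k_rela0,
                               t_grid = seq(build_schedule(spec, p)$t_start, 12.5, 0.1))
    colMeans(readouts_12hps(ens)[, c("integ_total", "integ_mch", "cum_tnf")])
  }
  out <- list()
  for (mi in mechanisms) {
    for (g in grid) {
      m <- setNames(rep(1, 6), paste0("m", 1:6)); m[mi] <- g
      r <- run(apply_mechanism_scaling(base, m))
      out[[length(out) + 1]] <- data.frame(mechanism = mi, multiplier = g,
                                           integ_total = r[["integ_total"]],
                                           integ_mch = r[["integ_mch"]],
                                           cum_tnf = r[["cum_tnf"]])
    }
  }
  do.call(rbind, out)
}

#' Robustness of readouts to global parameter variation
#'
#' Draws parameter sets lognormally around the fitted values (median = fitted,
#' log-SD chosen so the linear-scale CV matches the requested value), leaving
#' the mechanism multipliers at 1, and measures the divergence of the mean
#' 12-hps readout triple from the base case as the median absolute relative
#' deviation across draws.
#'
#' @param base parameter vector.
#' @param cv_list coefficients of variation to test (>= 2 values).
#' @param n_samples draws per CV (>= 20).
#' @param seed integer.
#' @param spec condition simulated.
#' @return data.frame: `cv`, `divergence` (median abs relative deviation,
#'   pooled over the three readouts), plus per-readout columns.
#' @export
robustness_cv_sweep <- function(base, cv_list = c(0.05, 0.1, 0.2, 0.4),
                                n_samples = 24, seed = 1,
                                spec = perturbation(lps = 100, density = "high")) {
  if (length(cv_list) < 2) stop("cv_list needs >= 2 values")
  if (n_samples < 20) stop("n_samples must be >= 20")
  validate_params(base)
  s0 <- basal_state(base)
  run <- function(p, s) {
    ens <- simulate_population(s, p, spec,
                               t_grid = seq(build_schedule(spec, p)$t_start, 12.5, 0.1))
    colMeans(readouts_12hps(ens)[, c("integ_total", "integ_mch", "cum_tnf")])
  }
  base_r <- run(base, s0)
  kin <- setdiff(names(base), c(paste0("m", 1:6), "f_adapt"))
  kin <- kin[base[kin] > 0]
  out <- list()
  for (ci in seq_along(cv_list)) {
    cv <- cv_list[ci]
    if (cv == 0) {
      out[[ci]] <- data.frame(cv = 0, divergence = 0, d_total = 0, d_mch = 0,
                              d_tnf = 0)
      next
    }
    sdlog <- sqrt(log(1 + cv^2))
    devs <- withr_seed(seed + ci, {
      t(vapply(seq_len(n_samples), function(i) {
        p <- base
        fac <- rlnorm(length(kin), meanlog = 0, sdlog = sdlog)
        p[kin] <- base[kin] * fac
        r <- try(run(p, basal_state(p)), silent = TRUE)
        if (inherits(r, "try-error")) rep(NA_real_, 3)
        else abs(r / base_r - 1)
      }, numeric(3)))
    })
    md <- apply(devs, 2, median, na.rm = TRUE)
    out[[ci]] <- data.frame(cv = cv, divergence = median(devs, na.rm = TRUE),
                            d_total = md[1], d_mch = md[2], d_tnf = md[3])
  }
  do.call(rbind, out)
}

#' Heterogeneous vs homogeneous population comparison
#'
#' Simulates the four scenarios {high/low density} x {high/low-density initial
#' distribution} for a heterogeneous population (initials sampled from the
#' mixture) and for a hypothetical homogeneous one (every cell assigned the
#' mean of the same distribution, i.e. extrinsic noise removed). Readouts are
#' the mean per-cell 12-hps triple, normalised to 1x at the
#' heterogeneous/low-density/low-initials scenario. Total secreted TNF
#' additionally scales per-cell TNF by relative cell number. The coupling
#' metric compares the fold change of total TNF when density and initials
#' move together (low,low -> high,high) against the product of the two
#' single-factor fold changes.
#'
#' @param mix_high `qlmac_gmm` (or samples) for the high-density initial
#'   distribution.
#' @param mix_low same for low density (typically from
#'   [impute_cross_density()]).
#' @param params parameter vector.
#' @param n cells per population.
#' @param seed integer.
#' @param lps LPS dose.
#' @return List with `readouts` (data.frame over scenarios x population
#'   types, normalised) and `coupling` (list: `fold_coupled`,
#'   `fold_density`, `fold_initials`, `product`, `super_multiplicative`).
#' @export
hetero_vs_homo <- function(mix_high, mix_low, params, n = 30, seed = 1,
                           lps = 100) {
  validate_params(params)
  scen <- expand.grid(density = c("low", "high"), initials = c("low", "high"),
                      stringsAsFactors = FALSE)
  draw <- function(mix, k, sd) sample_initials(mix, k, params, seed = sd)
  res <- list()
  for (i in seq_len(nrow(scen))) {
    mix <- if (scen$initials[i] == "high") mix_high else mix_low
    spec <- perturbation(lps = lps, density = scen$density[i])
    het <- draw(mix, n, seed + i)
    hom <- het
    hom$states[, "nfkb_ikb_c"] <- mean(het$states[, "nfkb_ikb_c"])
    hom$states[, "rela_mrna"] <- mean(het$states[, "rela_mrna"])
    hom$k_rela0 <- rep(mean(het$k_rela0), n)
    for (type in c("heterogeneous", "homogeneous")) {
      ini <- if (type == "heterogeneous") het else hom
      ens <- simulate_population(ini$states, params, spec, k_rela0 = ini$k_rela0,
                                 t_grid = seq(build_schedule(spec, params)$t_start,
                                              12.5, 0.1))
      r <- colMeans(readouts_12hps(ens)[, c("integ_total", "integ_mch", "cum_tnf")])
      res[[length(res) + 1]] <- data.frame(
        density = scen$density[i], initials = scen$initials[i], type = type,
        integ_total = r[["integ_total"]], integ_mch = r[["integ_mch"]],
        cum_tnf = r[["cum_tnf"]],
        total_tnf = r[["cum_tnf"]] *
          unname(DENSITY_LEVELS[scen$density[i]] / DENSITY_LEVELS["low"]))
    }
  }
  tab <- do.call(rbind, res)
  anchor <- tab[tab$density == "low" & tab$initials == "low" &
                  tab$type == "heterogeneous", ]
  for (col in c("integ_total", "integ_mch", "cum_tnf", "total_tnf")) {
    tab[[paste0(col, "_rel")]] <- tab[[col]] / anchor[[col]]
  }
  het <- tab[tab$type == "heterogeneous", ]
  g <- function(d, i) het$total_tnf[het$density == d & het$initials == i]
  fold_coupled <- g("high", "high") / g("low", "low")
  fold_density <- g("high", "low") / g("low", "low")
  fold_initials <- g("low", "high") / g("low", "low")
  list(readouts = tab,
       coupling = list(fold_coupled = fold_coupled,
                       fold_density = fold_density,
                       fold_initials = fold_initials,
                       product = fold_density * fold_initials,
                       super_multiplicative =
                         fold_coupled > fold_density * fold_initials))
}

#' Post-hoc classification of trajectories into high/low activation
#'
#' Splits cells by the nadir threshold on log cumulative mCherry; if the
#' distribution is unimodal (no nadir), falls back to 2-means clustering on
#' the log scale. Labels are invariant to cell order.
#'
#' @param ensemble a [simulate_population()] result (or a data.frame of
#'   observables with `cell_id`, `time_h`, `mch_mat`).
#' @param eps positive offset added before taking logs.
#' @return List with `labels` (factor "low"/"high" per cell), `metric` (log
#'   cumulative mCherry), `method` ("nadir", "kmeans", or "single"), and
#'   `single_group` flag when all cells are indistinguishable.
#' @export
classify_activation <- function(ensemble, eps = 1e-6) {
  obs <- if (inherits(ensemble, "qlmac_ensemble")) ensemble$observables else ensemble
  obs <- obs[obs$time_h >= 0, ]
  cum <- vapply(split(obs, obs$cell_id), function(o) {
    o <- o[order(o$time_h), ]
    trapz(o$time_h, o$mch_mat)
  }, numeric(1))
  ids <- as.integer(names(cum))
  cum <- unname(cum[order(ids)])
  lm_ <- log(cum + eps)
  if (diff(range(lm_)) < 1e-9) {
    return(list(labels = factor(rep("low", length(lm_)), c("low", "high")),
                metric = lm_, method = "single", single_group = TRUE))
  }
  thr <- if (length(lm_) >= 100) nadir_threshold(lm_) else
    list(unimodal = TRUE)
  if (!thr$unimodal) {
    lab <- ifelse(lm_ > thr$threshold, "high", "low")
    method <- "nadir"
  } else {
    km <- withr_seed(7, kmeans(lm_, centers = 2, nstart = 10))
    hi_cl <- which.max(km$centers)
    lab <- ifelse(km$cluster == hi_cl, "high", "low")
    method <- "kmeans"
  }
  list(labels = factor(lab, c("low", "high")), metric = lm_,
       method = method, single_group = FALSE)
}
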