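# coupled populations: medium feedback, density scaling, growth, snapshots

test_that("logistic growth closed forms", {
  expect_equal(grow_density(1e5, c(0, 5, 40), c(rate = 0, cap = 3)),
               rep(1e5, 3))
  # carrying capacity at the starting density is a fixed point
  expect_equal(grow_density(2e5, c(0, 10, 100), c(rate = 0.1, cap = 1)),
               rep(2e5, 3))
  # far from capacity, rate log(2)/12 doubles in ~12 h
  d <- grow_density(1e3, 12, c(rate = log(2) / 12, cap = 1e4))
  expect_gt(d / 1e3, 1.9); expect_lt(d / 1e3, 2.1)
  expect_error(grow_density(1e5, -1), ">= 0")
  expect_error(grow_density(0, 1), "> 0")
})

test_that("decoupled single cell reproduces simulate_cell exactly", {
  p <- test_params(k_sec = 0)
  s0 <- basal_state(p)
  spec <- perturbation(lps = 100, density = "high")
  grid <- seq(0, 12, 0.1)
  ens <- simulate_population(s0, p, spec, t_grid = grid, n = 1)
  tr <- simulate_cell(s0, p, spec, t_grid = grid)
  expect_lt(max(abs(ens$medium$tnf_ext)), 1e-12)
  expect_equal(ens$cells[, , 1], tr$states, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("initial medium accumulation scales linearly with density", {
  # with identical cells and no losses, d(tnf_ext)/dt at t -> 0+ is
  # proportional to the density multiplier: an 8x density ratio gives an 8x
  # accumulation rate
  p <- test_params(d_tnf_ext = 0, k_uptake = 0, kon_tnfr = 0)
  s0 <- basal_state(p)
  s0[["tnf_intra"]] <- 1  # nonzero secretion from t = 0
  grid <- seq(0, 0.05, 0.01)
  rate_at <- function(mult) {
    ens <- simulate_population(s0, p, perturbation(density = unname(
      DENSITY_LEVELS["high"]) * mult), t_grid = grid, n = 1)
    (ens$medium$tnf_ext[2] - ens$medium$tnf_ext[1]) / 0.01
  }
  r1 <- rate_at(1 / 8); r8 <- rate_at(1)
  expect_equal(r8 / r1, 8, tolerance = 0.02)
})

test_that("sTNFR mass is conserved along the trajectory", {
  p <- test_params()
  s0 <- cached_basal(p)
  ini <- matrix(rep(as.numeric(s0), each = 5), nrow = 5)
  ens <- simulate_population(ini, p, perturbation(lps = 100, stnfr = 2,
                                                  density = "high"),
                             t_grid = seq(-1, 12, 0.1))
  tot <- ens$medium$stnfr_free + ens$medium$tnf_stnfr
  expect_equal(tot, rep(2, length(tot)), tolerance = 1e-6)
})

test_that("permuting identical cells leaves the medium unchanged bit-wise", {
  p <- test_params()
  s0 <- cached_basal(p)
  ini <- matrix(rep(as.numeric(s0), each = 4), nrow = 4)
  kr <- rep(p[["k_rela0"]], 4)
  spec <- perturbation(lps = 100, density = "high")
  e1 <- simulate_population(ini, p, spec, k_rela0 = kr, t_grid = seq(0, 6, 0.1))
  e2 <- simulate_population(ini[c(3, 1, 4, 2), ], p, spec,
                            k_rela0 = kr[c(3, 1, 4, 2)],
                            t_grid = seq(0, 6, 0.1))
  expect_identical(e1$medium$tnf_ext, e2$medium$tnf_ext)
})

test_that("sTNFR pretreatment puts high density between high and low no-sTNFR", {
  p <- test_params()
  s0 <- cached_basal(p)
  cum12 <- function(spec) {
    e <- simulate_population(s0, p, spec, n = 1, t_grid = seq(-1, 12.5, 0.1))
    o <- e$observables
    o$cum_sec[o$time_h == 12] + o$tnf_intra[o$time_h == 12]
  }
  hi <- cum12(perturbation(lps = 100, density = "high"))
  hi_s <- cum12(perturbation(lps = 100, stnfr = 1, density = "high"))
  lo <- cum12(perturbation(lps = 100, density = "low"))
  expect_lt(hi_s, hi)
  expect_gt(hi_s, lo)
})

test_that("snapshot returns per-cell rows at grid times only", {
  p <- test_params()
  s0 <- cached_basal(p)
  ini <- matrix(rep(as.numeric(s0), each = 3), nrow = 3)
  ens <- simulate_population(ini, p, perturbation(lps = 100, density = "high"),
                             t_grid = seq(0, 6, 0.5))
  sn <- snapshot(ens, 0)
  expect_equal(nrow(sn), 3)
  expect_equal(sn$cell_id, 1:3)
  expect_equal(sn$total, rep(sum(s0[c("nfkb_ikb_c", "nfkb_c", "nfkb_n")]), 3),
               tolerance = 1e-9)
  expect_error(snapshot(ens, 7.25), "not on the simulated grid")
  # paired BFA comparison at matched seeds: intracellular TNF elementwise >=
  ens_b <- simulate_population(ini, p, perturbation(lps = 100, bfa_at = 1,
                                                    density = "high"),
                               t_grid = seq(0, 6, 0.5))
  expect_true(all(snapshot(ens_b, 6)$tnf_intra >=
                    snapshot(ens, 6)$tnf_intra - 1e-9))
})

test_that("fraction of activated cells is non-decreasing in density", {
  # the licensed fraction of the initial mixture rises with density, and TNF
  # coupling must not reverse the ordering of activated fractions
  p <- test_params()
  cfg <- synthetic_config(seed = 11, n_cells = 150, params = p)
  frac_high <- function(cond) {
    mix <- qlmac:::synth_mixture(cfg, cond)
    ini <- sample_initials(mix, cfg$n_cells, p, seed = cfg$seed)
    dens <- c(high = "high", low = "low", very_low = "very_low")[[cond]]
    ens <- simulate_population(ini$states, p,
                               perturbation(lps = 100, density = dens),
                               k_rela0 = ini$k_rela0,
                               t_grid = seq(0, 12, 0.25))
    cl <- classify_activation(ens)
    mean(cl$labels == "high")
  }
  f <- c(frac_high("very_low"), frac_high("low"), frac_high("high"))
  expect_true(all(diff(f) >= 0))
  expect_gt(f[3], f[1])
})
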