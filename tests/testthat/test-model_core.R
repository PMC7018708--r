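# single-cell network: rate equations, simulation, basal equilibration

test_that("derivatives: frozen system, pure decay, and input validation", {
  p <- test_params()
  # all rate constants zero -> zero rate vector
  p0 <- p; p0[] <- 0; p0[paste0("m", 1:6)] <- 1
  s <- cell_state(nfkb_ikb_c = 1, ikb = 0.5, tnf_intra = 2)
  expect_equal(unname(derivatives(s, p0, list(u_lps = 1, fbd = TRUE))),
               rep(0, length(s)))
  # single species with only first-order decay: derivative = -d * x
  for (x0 in c(1, 10, 0)) {
    pd <- p0; pd[["d_tnf"]] <- 0.7
    sd_ <- cell_state(tnf_intra = x0)
    r <- derivatives(sd_, pd, list())
    expect_equal(unname(r["tnf_intra"]), -0.7 * x0)
    expect_equal(unname(r[setdiff(names(r), "tnf_intra")]),
                 rep(0, length(r) - 1))
  }
  # errors name the offending field
  bad <- cell_state(); bad[["ikk"]] <- NaN
  expect_error(derivatives(bad, p, list()), "ikk")
  pneg <- p; pneg[["k_sec"]] <- -1
  expect_error(derivatives(cell_state(), pneg, list()), "k_sec")
})

test_that("no basal TNF production without stimulus", {
  p <- test_params()
  s0 <- cached_basal(p)
  expect_lt(s0[["tnf_mrna"]], 1e-6)
  expect_lt(s0[["tnf_intra"]], 1e-6)
  r <- derivatives(s0, p, list())  # no LPS, no IL-10, no TNF_ext
  expect_equal(unname(r["tnf_intra"]), 0, tolerance = 1e-9)
})

test_that("mechanism multipliers scale the mapped rates exactly", {
  p <- test_params()
  s <- cell_state(nfkb_ikb_c = 0.8, nfkb_n = 0.5, ikb = 0.1, a_tlr4 = 0.6,
                  a_tnfr = 0.3, ikk = 0.4, tnf_mrna = 0.2, tnf_intra = 0.5,
                  sr = 0.5, dsr = 0.3, rela_mrna = 0.1)
  inp <- list(u_lps = 1, fbd = TRUE, tnf_ext = 0.2)
  r1 <- derivatives(s, p, inp)
  # m = 1 reproduces the unscaled model bit-identically
  r1b <- derivatives(s, apply_mechanism_scaling(p, rep(1, 6)), inp)
  expect_identical(r1, r1b)
  # m2 = 0 is disallowed (> 0 required); m2 tiny kills promoter output
  expect_error(apply_mechanism_scaling(p, c(m2 = 0)), "> 0")
  p2 <- apply_mechanism_scaling(p, c(m2 = 2))
  r2 <- derivatives(s, p2, inp)
  pl <- as.list(p)
  txn1 <- pl$k_txn * (s[["nfkb_n"]]^pl$h_txn /
                        (pl$K_txn^pl$h_txn + s[["nfkb_n"]]^pl$h_txn))
  expect_equal(unname(r2["mch_mrna"] - r1["mch_mrna"]),
               unname(pl$k_mch_scale * txn1), tolerance = 1e-12)
})

test_that("ODE solution matches closed-form exponential decay to 1e-6", {
  p <- test_params()
  p0 <- p; p0[] <- 0; p0[paste0("m", 1:6)] <- 1
  p0[["d_tnf"]] <- log(2)  # half-life 1 h
  tr <- simulate_cell(cell_state(tnf_intra = 1), p0, perturbation(),
                      t_grid = seq(0, 4, 0.1))
  x <- tr$states[, "tnf_intra"]
  expect_equal(unname(x[tr$times == 1]), 0.5, tolerance = 1e-6)
  expect_equal(unname(x[tr$times == 3]), 0.125, tolerance = 1e-6)
})

test_that("trajectories preserve invariants: non-negativity, bounded fractions", {
  p <- test_params()
  s0 <- cached_basal(p)
  tr <- simulate_cell(s0, p, perturbation(lps = 100, stnfr = 1, il10 = 10))
  expect_true(all(tr$states >= -1e-9))
  fr <- tr$states[, c("a_tlr4", "a_tnfr", "a_il10r", "ikk", "sr", "dsr")]
  expect_true(all(fr <= 1 + 1e-9))
  # total reporter identity
  expect_equal(tr$observables$total,
               unname(tr$states[, "nfkb_ikb_c"] + tr$states[, "nfkb_c"] +
                        tr$states[, "nfkb_n"]))
  # cumulative secreted flux non-decreasing
  expect_true(all(diff(tr$states[, "cum_sec"]) >= -1e-9))
})

test_that("BFA blocks secretion exactly and causes intracellular accumulation", {
  p <- test_params()
  s0 <- cached_basal(p)
  grid <- seq(-0.5, 6, 0.1)
  trB <- simulate_cell(s0, p, perturbation(lps = 100, bfa_at = 1), t_grid = grid)
  trN <- simulate_cell(s0, p, perturbation(lps = 100), t_grid = grid)
  # secreted flux after BFA start is exactly zero
  cs <- trB$states[, "cum_sec"]
  after <- trB$times >= 1
  expect_equal(max(cs[after]) - min(cs[after]), 0, tolerance = 1e-12)
  # intracellular TNF >= the no-BFA run at matched times through 3 hps
  win <- trB$times > 1 & trB$times <= 3
  expect_true(all(trB$states[win, "tnf_intra"] >=
                    trN$states[win, "tnf_intra"] - 1e-9))
  expect_gt(trB$states[trB$times == 3, "tnf_intra"],
            trN$states[trN$times == 3, "tnf_intra"])
})

test_that("FBD off leaves total reporter flat; FBD on gives interior peak", {
  p <- test_params()
  s0 <- cached_basal(p)
  tr_off <- simulate_cell(s0, p, perturbation(lps = 0.1, stnfr = 1))  # below dose threshold
  o <- tr_off$observables
  expect_equal(o$total[which.max(o$time_h)], o$total[which.min(abs(o$time_h))],
               tolerance = 0.05)
  tr_on <- simulate_cell(s0, p, perturbation(lps = 100, stnfr = 1))
  s <- summarize_trajectory(tr_on)
  expect_false(s$flat)
  expect_gt(s$peak_amp[["total"]], 1.2)
  expect_lt(s$peak_time[["total"]], 24)
  o2 <- tr_on$observables
  expect_lt(o2$total[which.max(o2$time_h)], s$peak_amp[["total"]])
})

test_that("mature mCherry lags its transcript by about the maturation half-time", {
  # step of mch_mrna with all other dynamics frozen: the immature pool fills
  # and matures; half-rise of mch_mat vs mch_mrna step is ~1 h later
  p <- test_params()
  p0 <- p; p0[] <- 0; p0[paste0("m", 1:6)] <- 1
  p0[["k_trl_mch"]] <- 1; p0[["k_mat"]] <- log(2)
  tr <- simulate_cell(cell_state(mch_mrna = 1), p0, perturbation(),
                      t_grid = seq(0, 12, 0.05))
  mat <- tr$states[, "mch_mat"]
  # with no decay, mch_mat(t) = t - (1 - exp(-k t))/k; compare half-rise lag
  # against the pure-translation ramp t
  ramp <- tr$times
  lag <- sapply(c(4, 8, 12), function(tt) {
    i <- which(tr$times == tt)
    ramp[i] - mat[i]  # asymptotic offset = 1/k_mat
  })
  expect_equal(unname(lag), rep(1 / log(2), 3), tolerance = 0.2 * 1 / log(2))
})

test_that("basal equilibration converges from different starting guesses", {
  p <- test_params()
  s1 <- basal_state(p)
  guess <- cell_state(nfkb_ikb_c = 5, ikb = 1, rela_mrna = 1)
  s2 <- basal_state(p, initial = guess)
  rel <- abs(s1 - s2) / pmax(abs(s1), 1e-4)
  expect_lt(max(rel), 1e-4)
  # zero basal synthesis -> all inducible species zero
  pz <- p; pz[["k_rela0"]] <- 0; pz[["k_ikb0"]] <- 0
  sz <- basal_state(pz)
  expect_equal(max(sz), 0, tolerance = 1e-6)
  # resting sequestration: complex positive, nucleus nearly empty
  expect_gt(s1[["nfkb_ikb_c"]], 0.1)
  expect_lt(s1[["nfkb_n"]], 0.05 * s1[["nfkb_ikb_c"]])
})
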