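# bimodality thresholding, CV timecourses, permutation tests, readouts,
# sweeps and the heterogeneity comparison

test_that("nadir threshold recovers the antimode of planted mixtures", {
  set.seed(31)
  x <- c(rnorm(5000, 0, 0.5), rnorm(5000, 4, 0.5))
  nt <- nadir_threshold(x)
  expect_false(nt$unimodal)
  expect_equal(nt$threshold, 2, tolerance = 0.2)
  expect_equal(nt$fraction_high, 0.5, tolerance = 0.02)
  # weight (0.2, 0.8)
  y <- c(rnorm(2000, 0, 0.5), rnorm(8000, 4, 0.5))
  expect_lt(abs(nadir_threshold(y)$fraction_high - 0.8), 0.03)
  # single Gaussian flags unimodal
  z <- rnorm(5000, 1, 0.7)
  expect_true(nadir_threshold(z)$unimodal)
  expect_error(nadir_threshold(rnorm(50)), ">= 100")
})

test_that("fraction_high is invariant to monotone rescaling", {
  set.seed(32)
  x <- c(rnorm(3000, 0, 0.4), rnorm(3000, 3, 0.5))
  f1 <- nadir_threshold(x)$fraction_high
  f2 <- nadir_threshold(2 * x + 7)$fraction_high
  expect_equal(f1, f2, tolerance = 0.01)
})

test_that("CV timecourse matches closed forms", {
  p <- test_params()
  s0 <- cached_basal(p)
  # identical cells -> CV identically 0
  ini <- matrix(rep(as.numeric(s0), each = 4), nrow = 4)
  ens <- simulate_population(ini, p, perturbation(lps = 100, density = "high"),
                             t_grid = seq(0, 4, 0.5))
  cv <- cv_timecourse(ens, "total")
  expect_equal(cv$cv, rep(0, nrow(cv)), tolerance = 1e-9)
  # hand arithmetic: cells at (1, 3) -> population SD 1, mean 2, CV 0.5
  fake <- ens
  fake$observables <- data.frame(cell_id = rep(1:2, each = 2),
                                 time_h = rep(c(0, 1), 2),
                                 total = c(1, 1, 3, 3))
  cv2 <- cv_timecourse(fake, "total")
  expect_equal(cv2$cv, c(0.5, 0.5))
  # multiplicative lognormal population: CV constant = sqrt(exp(s^2)-1)
  set.seed(33)
  lat <- rlnorm(10000, 0, 0.4)
  tt <- c(0, 1, 2)
  fake2 <- ens
  fake2$observables <- data.frame(cell_id = rep(seq_along(lat), each = 3),
                                  time_h = rep(tt, length(lat)),
                                  total = rep(c(2, 5, 9), length(lat)) *
                                    rep(lat, each = 3))
  cv3 <- cv_timecourse(fake2, "total")
  expect_equal(cv3$cv, rep(sqrt(exp(0.4^2) - 1), 3), tolerance = 0.05)
})

test_that("permutation R2: perfect fit, exhaustive oracle, p floor", {
  r <- r2_permutation(1:10, 2 * (1:10), B = 999, seed = 2)
  expect_equal(r$r2, 1)
  expect_equal(r$p, 1 / 1000)
  # n = 5: Monte-Carlo agrees with the 120-permutation enumeration
  x <- c(1.2, 3.1, 2.2, 5.3, 4.1); y <- c(2.0, 1.1, 4.2, 3.3, 5.4)
  ex <- r2_permutation(x, y)          # exhaustive path (n <= 7)
  expect_true(ex$exhaustive)
  expect_equal(ex$B_used, 120)
  # Monte-Carlo estimate of the same p via manual resampling
  set.seed(11)
  r2o <- cor(x, y)^2
  mc <- mean(replicate(1e5, cor(x, sample(y))^2) >= r2o - 1e-12)
  expect_equal(ex$p, mc, tolerance = 0.01)
  # p respects the add-one floor
  expect_gte(r2_permutation(1:20, (1:20)^2, B = 999)$p, 1 / 1000)
  expect_error(r2_permutation(rep(1, 5), 1:5), "zero variance")
})

test_that("permutation p-values are calibrated under independence", {
  set.seed(35)
  reps <- 400
  pv <- replicate(reps, {
    x <- rnorm(30); y <- rnorm(30)
    r2_permutation(x, y, B = 999, seed = sample.int(1e6, 1))$p
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.025)
})

test_that("12-hps readouts: constants, clamps and ramps", {
  p <- test_params()
  s0 <- cached_basal(p)
  ini <- matrix(rep(as.numeric(s0), each = 2), nrow = 2)
  ens <- simulate_population(ini, p, perturbation(lps = 100, bfa_at = 1,
                                                  density = "high"),
                             t_grid = seq(0, 12.5, 0.1))
  rd <- readouts_12hps(ens)
  expect_equal(nrow(rd), 2)
  expect_true(all(rd$integ_total >= 0 & rd$integ_mch >= 0 & rd$cum_tnf >= 0))
  # with BFA at 1 hps, cumulative secreted TNF equals the 0-1 hps part only
  o <- ens$observables[ens$observables$cell_id == 1, ]
  expect_equal(rd$cum_tnf[1], o$cum_sec[o$time_h == 1] - o$cum_sec[o$time_h == 0],
               tolerance = 1e-9)
})

test_that("mechanism sweep: 1x point reproduces base, m2 monotone for mCherry", {
  p <- test_params()
  s0 <- cached_basal(p)
  sw <- mechanism_sweep(p, grid = c(0.25, 1, 4), initials = s0,
                        mechanisms = c("m2", "m6"))
  base_row <- sw[sw$mechanism == "m2" & sw$multiplier == 1, ]
  base_row2 <- sw[sw$mechanism == "m6" & sw$multiplier == 1, ]
  expect_equal(base_row$integ_total, base_row2$integ_total, tolerance = 1e-12)
  m2 <- sw[sw$mechanism == "m2", ]
  expect_true(all(diff(m2$integ_mch[order(m2$multiplier)]) > 0))
  expect_error(mechanism_sweep(p, grid = c(0.5, 2)), "1x")
})

test_that("robustness sweep: zero CV exact, divergence grows, reproducible", {
  p <- test_params()
  rb <- robustness_cv_sweep(p, cv_list = c(0, 0.2), n_samples = 20, seed = 4)
  expect_equal(rb$divergence[rb$cv == 0], 0)
  expect_gt(rb$divergence[rb$cv == 0.2], 0)
  rb2 <- robustness_cv_sweep(p, cv_list = c(0, 0.2), n_samples = 20, seed = 4)
  expect_identical(rb, rb2)
})

test_that("homogeneous beats heterogeneous for concave readout maps", {
  # Jensen logic on a constructed concave map: readout(latent) = sqrt(latent)
  set.seed(36)
  lat <- rlnorm(200, 0, 0.6)
  het <- mean(sqrt(lat))
  hom <- sqrt(mean(lat))
  expect_gt(hom, het)
  # degenerate mixture: heterogeneous == homogeneous within solver tolerance
  p <- test_params()
  mix0 <- structure(list(weights = c(w_low = 0, w_high = 1),
                         means = c(mu_low = 0, mu_high = 1),
                         sds = c(sd_low = 1e-12, sd_high = 1e-12),
                         loglik = NA, degenerate = TRUE),
                    class = "qlmac_gmm")
  hh <- hetero_vs_homo(mix0, mix0, p, n = 4, seed = 2)
  tab <- hh$readouts
  for (sc in split(tab, interaction(tab$density, tab$initials))) {
    expect_equal(sc$integ_mch[sc$type == "heterogeneous"],
                 sc$integ_mch[sc$type == "homogeneous"], tolerance = 1e-6)
  }
})

test_that("activation classification recovers planted groups, order-invariant", {
  p <- test_params()
  mix <- structure(list(weights = c(w_low = 0.4, w_high = 0.6),
                        means = c(mu_low = -1.5, mu_high = 2.5),
                        sds = c(sd_low = 0.25, sd_high = 0.25),
                        loglik = NA, degenerate = FALSE),
                   class = "qlmac_gmm")
  ini <- sample_initials(mix, 24, p, seed = 14)
  ens <- simulate_population(ini$states, p,
                             perturbation(lps = 100, density = "high"),
                             k_rela0 = ini$k_rela0, t_grid = seq(0, 12, 0.25))
  cl <- classify_activation(ens)
  planted <- ini$latent > 0.5
  expect_equal(as.vector(cl$labels == "high"), as.vector(planted))
  # invariance to cell order: relabelling cells permutes labels accordingly
  perm <- sample(24)
  obs <- ens$observables
  obs$cell_id <- perm[obs$cell_id]
  cl2 <- classify_activation(obs)
  expect_identical(as.character(cl2$labels[perm]), as.character(cl$labels))
  # all-identical cells -> single group flag
  ini0 <- matrix(rep(as.numeric(cached_basal(p)), each = 3), nrow = 3)
  ens0 <- simulate_population(ini0, p, perturbation(lps = 100, density = "high"),
                              t_grid = seq(0, 12, 0.5))
  expect_true(classify_activation(ens0)$single_group)
})
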