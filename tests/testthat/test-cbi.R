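test_that("Jensen-Shannon divergence: closed values and bounds", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.3112781, tolerance = 1e-6)
  set.seed(2)
  for (n in c(2, 5, 10)) {
    w1 <- rgamma(n, 1); w1 <- w1 / sum(w1)
    w2 <- rgamma(n, 1); w2 <- w2 / sum(w2)
    d <- jsd(w1, w2)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, jsd(w2, w1), tolerance = 1e-12)
  }
  expect_error(jsd(c(0.5, 0.5), c(0.5, 0.4)), "simplex")
})

test_that("a one-member ensemble pins the weight and centers lambda", {
  inst <- tiny_instance(seed = 51)
  one <- subset_library(inst$library, 1)
  d <- sample_posterior(inst$curve, one, config = mcmc_config(seed = 6))
  expect_true(all(d$w_draws == 1))
  lam_hat <- saxs_scale_factor(inst$curve, one, 1)
  expect_lt(abs(mean(d$lambda_draws) - lam_hat), 4 * sd(d$lambda_draws))
})

test_that("with a flat likelihood the posterior reverts to the prior mean", {
  lib <- make_profile_library(4, q = seq(0.02, 0.3, length.out = 30),
                              seed = 52)
  ib <- as.vector(rep(0.25, 4) %*% lib$profiles)
  flat <- saxs_curve(lib$q, ib, 1e4 * ib)  # errors drown the signal
  d <- sample_posterior(flat, lib, config = mcmc_config(n_iter = 4000,
                                                        seed = 7))
  g <- glance(d)
  means <- g$mean[1:4]
  se <- g$sd[1:4] / sqrt(g$ess[1:4])
  expect_true(all(abs(means - 0.25) < 3 * se + 0.01))
  expect_simplex(colMeans(d$w_draws), tol = 1e-6)
})

test_that("with a flat likelihood the energy prior pulls weights to Boltzmann", {
  U <- c(-135.2, -140.0, -126.7, -125.5, -124.0)
  es <- energy_prior(U, kT = 15)
  lib <- make_profile_library(5, q = seq(0.02, 0.3, length.out = 30),
                              seed = 53)
  ib <- as.vector(rep(0.2, 5) %*% lib$profiles)
  flat <- saxs_curve(lib$q, ib, 1e4 * ib)
  d <- sample_posterior(flat, lib, energy_spec = es,
                        config = mcmc_config(n_iter = 6000, seed = 8),
                        u_ref_range = es$u_ref + c(-1e-6, 1e-6))
  bw <- boltzmann_weights(U, 15)
  g <- glance(d)
  se <- g$sd[1:5] / sqrt(g$ess[1:5])
  expect_true(all(abs(g$mean[1:5] - bw) < 3 * se + 0.015))
})

test_that("posterior draws stay on the simplex and chains are labelled", {
  inst <- tiny_instance(seed = 54)
  d <- sample_posterior(inst$curve, inst$library,
                        config = mcmc_config(n_iter = 600, seed = 9))
  expect_true(all(abs(rowSums(d$w_draws) - 1) < 1e-9))
  expect_equal(sort(unique(d$chain_ids)), 1:4)
  expect_s3_class(glance(d), "tbl_df")
  expect_equal(nrow(tidy(d)),
               nrow(d$w_draws) * (ncol(d$w_draws) + 1L))
})

test_that("ensemble uncertainty is zero when degenerate, larger when vague", {
  w <- c(0.2, 0.3, 0.5)
  dd <- posterior_draws(w_draws = rbind(w, w, w, w),
                        lambda_draws = rep(1, 4), chain_ids = c(1, 1, 2, 2))
  expect_equal(ensemble_uncertainty(dd, w), 0)

  # identified posterior vs prior-like posterior (paired information check)
  b <- synthetic_benchmark("recovery100", seed = 2)
  sub <- subset_library(b$library, b$truth$ids)
  d_id <- sample_posterior(b$curve, sub, config = mcmc_config(seed = 10),
                           init = list(weights = b$truth$weights))
  sig_id <- ensemble_uncertainty(d_id)
  flat <- saxs_curve(b$curve$q, b$curve$intensity,
                     1e4 * abs(b$curve$intensity) + 1)
  d_fl <- sample_posterior(flat, sub, config = mcmc_config(seed = 11))
  sig_fl <- ensemble_uncertainty(d_fl)
  expect_lt(sig_id, 0.2)   # well-identified regime
  expect_gt(sig_fl, 2 * sig_id)
})

test_that("posterior predictive checks calibrate on self-generated data", {
  b <- synthetic_benchmark("recovery100", seed = 3)
  sub <- subset_library(b$library, b$truth$ids)
  d <- sample_posterior(b$curve, sub, config = mcmc_config(seed = 12),
                        init = list(weights = b$truth$weights))
  ppc <- posterior_predictive(d, sub, b$curve, n_rep = 400, seed = 13)
  n <- nrow(b$curve)
  binom_se <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(ppc$coverage - 0.95), 5 * binom_se + 0.02)

  # deliberately heavy-tailed generation degrades the Gaussian envelope
  set.seed(14)
  m_cauchy <- as.vector(b$truth$weights %*% sub$profiles) +
    b$curve$error * rcauchy(n)
  cv_c <- saxs_curve(b$curve$q, m_cauchy, b$curve$error)
  ppc_c <- posterior_predictive(d, sub, cv_c, n_rep = 400, seed = 15)
  expect_lt(ppc_c$coverage, ppc$coverage - 0.03)

  # zero replicates: empty envelope, no error
  p0 <- posterior_predictive(d, sub, b$curve, n_rep = 0)
  expect_equal(nrow(p0$envelope), 0L)
})

test_that("posterior means agree with the variational point estimates", {
  b <- synthetic_benchmark("recovery100", seed = 4)
  sub <- subset_library(b$library, b$truth$ids)
  m <- select_ensemble(b$curve, sub, config = selection_config(seed = 16))
  d <- sample_posterior(b$curve, sub, config = mcmc_config(seed = 17),
                        init = list(weights = m$weights,
                                    lambda = m$lambda_hat))
  vbi_w <- m$weights[match(colnames(d$w_draws), m$member_ids)]
  expect_lt(max(abs(colMeans(d$w_draws) - vbi_w)), 0.05)
})

test_that("posterior-mean weights recover the truth across replicate data sets", {
  errs <- vapply(1:20, function(s) {
    lib <- make_profile_library(5, q = seq(0.01, 0.6, length.out = 200),
                                seed = 60 + s)
    w_true <- c(0.1, 0.15, 0.2, 0.25, 0.3)
    sim <- simulate_measurement(lib, 1:5, w_true,
                                noise_spec(sigma_scale = 1, seed = 80 + s))
    d <- sample_posterior(sim$curve, lib,
                          config = mcmc_config(n_iter = 1200, n_chains = 2,
                                               seed = 90 + s),
                          init = list(weights = w_true))
    max(abs(colMeans(d$w_draws) - w_true))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
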