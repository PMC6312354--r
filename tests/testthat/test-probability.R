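test_that("Boltzmann weights: symmetry, direct ratios, shift invariance", {
  expect_equal(boltzmann_weights(rep(-5, 7)), rep(1 / 7, 7))
  expect_equal(boltzmann_weights(c(0, -log(2)), kT = 1), c(1 / 3, 2 / 3))
  U <- c(-135.2, -140.0, -126.7, -125.5, -124.0)
  for (kT in c(0.5, 1, 15)) {
    w1 <- boltzmann_weights(U, kT)
    w2 <- boltzmann_weights(U + 57.3, kT)
    expect_equal(w1, w2, tolerance = 1e-12)
    expect_simplex(w1)
  }
  expect_error(boltzmann_weights(c(0, 1), kT = 0), "positive")
})

test_that("Jeffreys prior density matches its closed form", {
  expect_equal(exp(jeffreys_log_prior(c(0.5, 0.5))), 2 / pi,
               tolerance = 1e-12)
  expect_equal(jeffreys_log_prior(c(0.3, 0.7)),
               jeffreys_log_prior(c(0.7, 0.3)))
  expect_error(jeffreys_log_prior(c(1, 0)), "simplex")
})

test_that("energy prior: flat case, mean identity, u_ref sharpness control", {
  # beta = 1 for all members -> flat Dirichlet, log density = log Gamma(n)
  es_flat <- energy_prior(rep(0, 4), kT = 1, u_ref = 0)
  expect_equal(es_flat$beta, rep(1, 4))
  set.seed(1)
  w <- rgamma(4, 1); w <- w / sum(w)
  expect_equal(energy_log_prior(w, es_flat), lgamma(4), tolerance = 1e-12)

  U <- c(-135.2, -140.0, -126.7, -125.5, -124.0)
  es <- energy_prior(U, kT = 15)
  expect_equal(es$beta / sum(es$beta), boltzmann_weights(U, 15),
               tolerance = 1e-12)

  # lowering u_ref by kT ln 10 multiplies beta by 10: same mean, less spread
  es10 <- energy_prior(U, kT = 15, u_ref = es$u_ref - 15 * log(10))
  expect_equal(es10$beta, 10 * es$beta, tolerance = 1e-9)
  var_dir <- function(b) b * (sum(b) - b) / (sum(b)^2 * (sum(b) + 1))
  expect_true(all(var_dir(es10$beta) < var_dir(es$beta)))
  expect_error(energy_prior(c(-3000, 0), kT = 1, u_ref = 0), "u_ref")
})

test_that("Dirichlet energy prior reproduces Boltzmann means by sampling", {
  U <- c(-10, -12, -9.5)
  es <- energy_prior(U, kT = 2)
  set.seed(42)
  n <- 1e5
  draws <- matrix(rgamma(n * 3, shape = rep(es$beta, each = n)), nrow = n)
  draws <- draws / rowSums(draws)
  mc_mean <- colMeans(draws)
  mc_se <- apply(draws, 2, sd) / sqrt(n)
  expect_true(all(abs(mc_mean - boltzmann_weights(U, 2)) < 3 * mc_se))
})

test_that("scale factor is the weighted least-squares optimum", {
  inst <- tiny_instance(seed = 7)
  # exact proportionality
  one <- subset_library(inst$library, 1)
  cv <- saxs_curve(inst$curve$q, 2 * one$profiles[1, ],
                   inst$curve$error)
  expect_equal(saxs_scale_factor(cv, one, 1), 2, tolerance = 1e-12)

  # optimality against an independent golden-section search
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    lib <- make_profile_library(n, q = seq(0.02, 0.3, length.out = 25),
                                seed = rep)
    w <- rgamma(n, 1); w <- w / sum(w)
    m <- as.vector(w %*% lib$profiles) * runif(1, 0.5, 2) +
      rnorm(25, 0, 0.01)
    cv <- saxs_curve(lib$q, m, rep(0.01, 25))
    lam <- saxs_scale_factor(cv, lib, w)
    ssr <- function(l) {
      ib <- as.vector(w %*% lib$profiles)
      sum(((m - l * ib) / cv$error)^2)
    }
    lam_gs <- golden_section(ssr, 0, 5, tol = 1e-12)
    expect_equal(lam, lam_gs, tolerance = 1e-8)
    # perturbing lambda strictly increases the weighted misfit
    expect_gt(ssr(lam * 1.01), ssr(lam))
    expect_gt(ssr(lam * 0.99), ssr(lam))
  }

  # orthogonal data under the error metric gives lambda = 0
  lib1 <- subset_library(inst$library, 1)
  m_orth <- rep(c(1, -1), length.out = length(lib1$q)) /
    lib1$profiles[1, ]  # makes sum(e2 * m * I) = 0 for constant errors
  cv0 <- saxs_curve(lib1$q, m_orth * lib1$profiles[1, ]^0, rep(1, length(lib1$q)))
  # construct directly: m alternating so the inner product vanishes
  m2 <- rep(c(1, -1), length.out = length(lib1$q)) * mean(lib1$profiles[1, ]) /
    lib1$profiles[1, ] * lib1$profiles[1, ]
  num <- sum(m2 * lib1$profiles[1, ])
  m2 <- m2 - num / sum(lib1$profiles[1, ]^2) * lib1$profiles[1, ]
  cv2 <- saxs_curve(lib1$q, m2, rep(1, length(lib1$q)))
  expect_equal(saxs_scale_factor(cv2, lib1, 1), 0, tolerance = 1e-10)
})

test_that("Gaussian SAXS log-likelihood has the right normalization", {
  inst <- tiny_instance(seed = 9)
  lib <- inst$library
  w <- c(0.2, 0.3, 0.5)
  ib <- as.vector(w %*% lib$profiles)
  # perfect fit: only the normalization constant remains
  cv <- saxs_curve(lib$q, ib, rep(0.05, length(lib$q)))
  expect_equal(saxs_loglik(cv, lib, w, lambda = 1),
               -0.5 * sum(log(2 * pi * cv$error^2)), tolerance = 1e-10)
  # standard normal at residual 1
  cv1 <- saxs_curve(c(0.1, 0.2), c(1, 1), c(1, 1))
  lib1 <- structural_library("a", cv1$q, matrix(c(1e-12, 1e-12), 1))
  ll <- dnorm(1, 0, 1, log = TRUE)
  expect_equal(saxs_loglik(cv1, lib1, 1, lambda = 1), 2 * ll,
               tolerance = 1e-6)
  expect_equal(ll, -0.5 * log(2 * pi) - 0.5)
  # doubling errors at zero residual costs N log 2
  cv2 <- saxs_curve(lib$q, ib, rep(0.1, length(lib$q)))
  expect_equal(saxs_loglik(cv2, lib, w, lambda = 1) -
                 saxs_loglik(cv, lib, w, lambda = 1),
               -length(lib$q) * log(2), tolerance = 1e-9)
})

test_that("chemical-shift likelihood adds variances, never rescales", {
  cs <- chemical_shift_data("r1_HN", 8.0, errors = 4)
  pred <- matrix(8.0 + 5, 1, 1)  # residual 5
  ll <- cs_loglik(cs, pred, cs_pred_err = 3, w = 1)
  expect_equal(ll, dnorm(5, 0, sqrt(3^2 + 4^2), log = TRUE),
               tolerance = 1e-12)  # combined variance 25, not (3+4)^2
  expect_error(cs_loglik(chemical_shift_data("a", 1, 0), matrix(1, 1, 1),
                         0, 1), "degenerate")
  # permutation of identical prediction rows is invisible
  cs2 <- chemical_shift_data(c("a", "b"), c(8, 7.5), 0.1)
  pred2 <- rbind(c(8.1, 7.4), c(8.1, 7.4))
  expect_equal(cs_loglik(cs2, pred2, 0.2, c(0.3, 0.7)),
               cs_loglik(cs2, pred2, 0.2, c(0.7, 0.3)))
})

test_that("combined likelihood is the sum of its parts", {
  inst <- tiny_instance(seed = 11)
  lib <- inst$library
  cs <- simulate_cs(3, 10, 1:3, c(0.2, 0.3, 0.5), seed = 2)
  lib$cs_pred <- cs$cs_pred
  lib$cs_pred_err <- cs$cs_pred_err
  w <- c(0.25, 0.35, 0.4)
  expect_equal(combined_loglik(inst$curve, lib, w, lambda = 1),
               saxs_loglik(inst$curve, lib$profiles, w, 1))
  both <- combined_loglik(inst$curve, lib, w, lambda = 1,
                          cs_data = cs$cs_data)
  expect_equal(both,
               saxs_loglik(inst$curve, lib$profiles, w, 1) +
                 cs_loglik(cs$cs_data, lib$cs_pred, lib$cs_pred_err, w),
               tolerance = 1e-12)
})
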