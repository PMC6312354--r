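test_that("profiles are normalized to unity at zero angle", {
  q <- c(1e-6, seq(0.01, 0.4, length.out = 30))
  lib <- make_profile_library(5, q = q, seed = 61)
  expect_equal(unname(lib$profiles[, 1]), rep(1, 5), tolerance = 1e-6)
  expect_true(all(lib$profiles > 0))
})

test_that("a single sphere has the Guinier radius sqrt(3/5) R", {
  R <- 20
  q <- seq(0.005, 0.04, length.out = 40)  # Guinier region: q Rg < 0.7
  lib <- make_profile_library(1, q = q, r1_range = c(R, R),
                              r2_range = c(0, 0), n_satellites = 0,
                              fine_structure = 0, seed = 62)
  # Guinier fit: ln I = -Rg^2 q^2 / 3
  fit <- stats::lm(log(lib$profiles[1, ]) ~ I(q^2))
  rg_fit <- sqrt(-3 * coef(fit)[[2]])
  rg_exact <- sqrt(3 / 5) * R
  expect_lt(abs(rg_fit - rg_exact) / rg_exact, 0.01)
  expect_equal(attr(lib, "geometry")$rg, rg_exact, tolerance = 1e-9)
})

test_that("the radius of gyration grows with domain separation", {
  lib <- make_profile_library(25, r1_range = c(16, 16), r2_range = c(12, 12),
                              n_satellites = 0, fine_structure = 0,
                              seed = 63)
  g <- attr(lib, "geometry")
  expect_equal(order(g$d), order(g$rg))  # parallel-axis monotonicity
})

test_that("noise-free simulation returns the exact weighted average", {
  lib <- make_profile_library(4, seed = 64)
  w <- c(0.1, 0.2, 0.3, 0.4)
  sim <- simulate_measurement(lib, 1:4, w, noise_spec(sigma_scale = 0))
  expect_equal(sim$curve$intensity, as.vector(w %*% lib$profiles),
               tolerance = 1e-12)
  expect_true(all(sim$curve$error > 0))  # floor keeps the curve valid
  expect_equal(sim$truth$ids, lib$ids)
  expect_equal(sim$truth$weights, w)
})

test_that("added noise is calibrated to the reported error column", {
  lib <- make_profile_library(3, q = seq(0.01, 0.5, length.out = 120),
                              seed = 65)
  w <- c(0.2, 0.3, 0.5)
  truth <- as.vector(w %*% lib$profiles)
  z <- unlist(lapply(1:90, function(r) {
    sim <- simulate_measurement(lib, 1:3, w,
                                noise_spec(sigma_scale = 1, seed = 1000 + r))
    (sim$curve$intensity - truth) / sim$curve$error
  }))
  n <- length(z)  # > 1e4 standardized residuals
  expect_gt(n, 1e4)
  se_sd <- 1 / sqrt(2 * n)
  expect_lt(abs(sd(z) - 1), 3 * se_sd + 0.005)
  expect_lt(abs(mean(z)), 3 / sqrt(n) + 0.005)
})

test_that("chemical-shift simulation reduces to the weighted prediction", {
  sim <- simulate_cs(6, 15, c(2, 4), c(0.4, 0.6), eps_cs = 0, eps_pre = 0,
                     seed = 66)
  pred <- as.vector(c(0.4, 0.6) %*% sim$cs_pred[c(2, 4), ])
  expect_equal(sim$cs_data$shift, pred, tolerance = 1e-12)
  expect_equal(sim$cs_data$label, sim$labels)
})

test_that("energy assignment favors the generating subset", {
  lib <- make_profile_library(20, seed = 67)
  U <- assign_energies(lib, c(3, 7, 9, 12, 18), gap = 8, seed = 68)
  expect_equal(sort(U[c(3, 7, 9, 12, 18)]),
               sort(c(-135.2, -140.0, -126.7, -125.5, -124.0)))
  expect_gte(min(U[-c(3, 7, 9, 12, 18)]) - max(U[c(3, 7, 9, 12, 18)]), 8)
  # gap = 0 with spread 0 carries no information
  U0 <- assign_energies(lib, 1:5, gap = 0, spread = 0, seed = 69,
                        truth_energies = rep(-100, 5))
  expect_equal(boltzmann_weights(U0 * 0), rep(1 / 20, 20))
})

test_that("the refined-conformer preset carries the deep-energy duplicate", {
  b <- synthetic_benchmark("refined101", seed = 70)
  expect_equal(length(b$library$ids), 101L)
  expect_equal(min(b$energies), -178.9)
  expect_equal(b$library$ids[which.min(b$energies)], "conf_refined")
})

test_that("weight rmsd penalizes missing and spurious members", {
  truth <- c(a = 0.4, b = 0.6)
  expect_equal(weight_rmsd(truth, truth), 0)
  inferred <- c(c = 0.5, d = 0.5)
  # union {a,b,c,d}: errors (0.4, 0.6, 0.5, 0.5)
  expect_equal(weight_rmsd(inferred, truth),
               sqrt((0.4^2 + 0.6^2 + 0.5^2 + 0.5^2) / 4))
  expect_equal(weight_rmsd(inferred, truth), weight_rmsd(truth, inferred))
})

test_that("benchmark presets carry their ground truth", {
  b <- synthetic_benchmark("recovery100", seed = 71)
  expect_equal(length(b$library$ids), 100L)
  expect_equal(sort(b$truth$weights), c(0.1, 0.15, 0.2, 0.25, 0.3))
  expect_true(all(b$truth$ids %in% b$library$ids))
  be <- synthetic_benchmark("energy100", seed = 72)
  expect_equal(sort(unname(be$energies[match(be$truth$ids, be$library$ids)])),
               sort(c(-135.2, -140.0, -126.7, -125.5, -124.0)))
  expect_equal(be$kT, 15)
})
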