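test_that("weights_from_alpha normalizes and is scale invariant", {
  expect_equal(weights_from_alpha(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_equal(weights_from_alpha(c(2, 2, 4)),
               weights_from_alpha(c(2, 2, 4) * 17.3))
  expect_equal(weights_from_alpha(5), 1)
  expect_error(weights_from_alpha(c(1, 0)), "positive")
})

test_that("Dirichlet covariance factor matches the closed form", {
  cv <- dirichlet_cov(c(1, 1))
  expect_equal(cv[1, 1], 1 / 12, tolerance = 1e-12)
  expect_equal(cv[1, 2], -1 / 12, tolerance = 1e-12)
  # rows sum to zero (weights sum to a constant)
  cv3 <- dirichlet_cov(c(0.7, 2.1, 4))
  expect_equal(rowSums(cv3), rep(0, 3), tolerance = 1e-14)
})

test_that("at the Jeffreys prior the KL blocks vanish and L is data-only", {
  inst <- tiny_instance(seed = 21)
  n <- 3
  alpha <- rep(0.5, n)
  L <- negative_elbo(alpha, inst$curve, inst$library)
  lam <- attr(L, "lambda")
  w <- rep(1 / n, n)
  ib <- as.vector(w %*% inst$library$profiles)
  e2 <- 1 / inst$curve$error^2
  misfit <- 0.5 * sum(e2 * (inst$curve$intensity - lam * ib)^2)
  G <- inst$library$profiles %*% (t(inst$library$profiles) * e2)
  covterm <- 0.5 * lam^2 * sum(G * dirichlet_cov(alpha))
  const <- 0.5 * sum(log(2 * pi * inst$curve$error^2))
  expect_equal(as.numeric(L), const + misfit + covterm, tolerance = 1e-9)
})

test_that("misfit + covariance terms equal the Dirichlet expectation (MC oracle)", {
  inst <- tiny_instance(seed = 22)
  lib <- inst$library
  alpha <- c(1.3, 0.6, 2.2)
  L <- negative_elbo(alpha, inst$curve, lib)
  lam <- attr(L, "lambda")
  e2 <- 1 / inst$curve$error^2
  set.seed(99)
  K <- 1e5
  W <- matrix(rgamma(K * 3, shape = rep(alpha, each = K)), nrow = K)
  W <- W / rowSums(W)
  R <- sweep(lam * (W %*% lib$profiles), 2, inst$curve$intensity)
  vals <- 0.5 * as.vector((R * R) %*% e2)
  mc_se <- sd(vals) / sqrt(K)
  w_bar <- alpha / sum(alpha)
  ib <- as.vector(w_bar %*% lib$profiles)
  misfit <- 0.5 * sum(e2 * (inst$curve$intensity - lam * ib)^2)
  G <- lib$profiles %*% (t(lib$profiles) * e2)
  covterm <- 0.5 * lam^2 * sum(G * dirichlet_cov(alpha))
  expect_lt(abs(mean(vals) - (misfit + covterm)), 3 * mc_se)
})

test_that("the analytic objective gradient matches finite differences", {
  inst <- tiny_instance(seed = 23, n = 4)
  cs <- simulate_cs(4, 12, 1:4, rep(0.25, 4), seed = 3)
  lib <- inst$library
  lib$cs_pred <- cs$cs_pred
  lib$cs_pred_err <- cs$cs_pred_err
  for (use_cs in c(FALSE, TRUE)) {
    obj <- make_elbo_objective(inst$curve, lib,
                               cs_data = if (use_cs) cs$cs_data)
    gr <- attr(obj, "gradient")
    set.seed(5)
    al <- runif(4, 0.3, 2.5)
    ga <- gr(al)
    gn <- vapply(1:4, function(i) {
      h <- 1e-6 * al[i]
      ap <- al; am <- al
      ap[i] <- al[i] + h; am[i] <- al[i] - h
      (as.numeric(obj(ap)) - as.numeric(obj(am))) / (2 * h)
    }, numeric(1))
    expect_equal(unname(ga), gn, tolerance = 1e-4)
  }
})

test_that("L is invariant under permutation of library members", {
  inst <- tiny_instance(seed = 24, n = 4)
  alpha <- c(0.4, 1.2, 0.9, 2.0)
  L1 <- as.numeric(negative_elbo(alpha, inst$curve, inst$library))
  perm <- c(3, 1, 4, 2)
  lib_p <- subset_library(inst$library, perm)
  L2 <- as.numeric(negative_elbo(alpha[perm], inst$curve, lib_p))
  expect_equal(L1, L2, tolerance = 1e-10)
})

test_that("annealing recovers the optimum of a convex surrogate", {
  cvec <- c(1.5, 0.7, 2.3)
  f <- function(a, extra = NULL) sum((a - cvec)^2)
  res <- anneal_optimize(rep(1, 3), f,
                         anneal_schedule(t_start = 1, t_end = 1e-7,
                                         n_steps = 20000, step_scale = 0.15,
                                         seed = 11))
  expect_lt(max(abs(res$par - cvec)), 1e-2)
})

test_that("annealing is deterministic given a seed and greedy at T -> 0", {
  inst <- tiny_instance(seed = 25)
  obj <- make_elbo_objective(inst$curve, inst$library)
  f <- function(a, extra = NULL) as.numeric(obj(a))
  sch <- anneal_schedule(t_start = 2, t_end = 1e-3, n_steps = 500, seed = 7)
  r1 <- anneal_optimize(rep(0.5, 3), f, sch)
  r2 <- anneal_optimize(rep(0.5, 3), f, sch)
  expect_identical(r1, r2)
  # zero-temperature limit: pure descent, final value never above start
  sch0 <- anneal_schedule(t_start = 1e-8, t_end = 1e-9, n_steps = 300,
                          seed = 8)
  r0 <- anneal_optimize(rep(0.5, 3), f, sch0)
  expect_lte(r0$value, f(rep(0.5, 3)))
})

test_that("selection on the exact generating library recovers the weights", {
  b <- synthetic_benchmark("lownoise100", seed = 3)
  lib5 <- subset_library(b$library, b$truth$ids)
  m <- select_ensemble(b$curve, lib5,
                       config = selection_config(seed = 31, n_steps = 2000))
  expect_setequal(m$member_ids, b$truth$ids)
  w <- tidy(m)$weight[match(b$truth$ids, tidy(m)$member_id)]
  expect_lt(max(abs(w - b$truth$weights)), 0.02)
  expect_simplex(m$weights)
})

test_that("a single-member library yields that conformer with weight 1", {
  inst <- tiny_instance(seed = 26)
  one <- subset_library(inst$library, 2)
  m <- select_ensemble(inst$curve, one,
                       config = selection_config(seed = 5, n_steps = 300,
                                                 patience = 2))
  expect_equal(m$member_ids, one$ids)
  expect_equal(m$weights, 1.0)
})

test_that("the candidate set never grows during selection", {
  b <- synthetic_benchmark("recovery100", seed = 4)
  m <- select_ensemble(b$curve, b$library,
                       config = selection_config(seed = 32, patience = 3))
  h <- m$history
  for (p in unique(h$pass)) {
    sizes <- h$n_members[h$pass == p]
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("selected member sets are stable across seeds", {
  b <- synthetic_benchmark("recovery100", seed = 5)
  sets <- lapply(1:3, function(s)
    select_ensemble(b$curve, b$library,
                    config = selection_config(seed = 40 + s,
                                              patience = 3))$member_ids)
  # pairwise overlap of at least 4 members among the generating five
  ov <- vapply(sets, function(s) sum(b$truth$ids %in% s), numeric(1))
  expect_true(sum(ov >= 4) >= 2)
})
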