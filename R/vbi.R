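#' Population weights from Dirichlet concentration parameters
#'
#' The variational point estimate \eqn{w_i = \alpha_i / \sum_i \alpha_i};
#' invariant under positive rescaling of `alpha`.
#'
#' @param alpha Positive concentration vector.
#' @return Simplex weight vector (names preserved).
#' @export
weights_from_alpha <- function(alpha) {
  if (any(alpha <= 0)) abort("alpha must be strictly positive")
  alpha / sum(alpha)
}

#' Build the variational objective L for a data set
#'
#' Returns a closure `f(alpha, u_ref = NULL)` evaluating the negative
#' evidence lower bound L to be *minimized* over the Dirichlet
#' concentration parameters. All data-dependent quantities (error-weighted
#' Gram matrices, cross terms) are precomputed, so a single evaluation
#' costs O(n^2) regardless of the number of data points.
#'
#' L consists of: the KL-type divergence between the Dirichlet
#' approximation and the prior (Jeffreys parameters 1/2, or Boltzmann
#' factors \eqn{\beta_i(U_{ref})} when an energy prior is used); the data
#' misfit evaluated at the Dirichlet-mean weights, with the SAXS scale
#' factor profiled analytically at every evaluation; and the Gram-weighted
#' Dirichlet covariance correction with matrix factor
#' \eqn{[\alpha_i(\alpha_0-\alpha_i)\delta_{ij} -
#' \alpha_i\alpha_j(1-\delta_{ij})] / (\alpha_0^2(\alpha_0+1))}. The
#' covariance term carries the squared scale factor so that the misfit and
#' covariance terms together equal the exact Dirichlet expectation of the
#' quadratic data misfit at fixed scale. Gaussian normalization constants
#' are included, making -L a true lower bound on the log model evidence.
#' When chemical-shift data are supplied, analogous misfit and covariance
#' terms with combined variances are added (no scale factor: shifts live
#' on an absolute ppm scale).
#'
#' @param curve A [saxs_curve()].
#' @param library A [structural_library()] (the current candidate set).
#' @param cs_data Optional experimental [chemical_shift_data()].
#' @param energy_spec Optional [energy_prior()] over the library members;
#'   when present the closure's `u_ref` argument moves the prior sharpness.
#' @return Function `f(alpha, u_ref = NULL) -> L`.
#' @export
make_elbo_objective <- function(curve, library, cs_data = NULL,
                                energy_spec = NULL) {
  P <- library$profiles
  n <- nrow(P)
  m <- curve$intensity
  e2 <- 1 / curve$error^2
  a_vec <- as.vector(P %*% (m * e2))
  G <- P %*% (t(P) * e2)
  gdiag <- diag(G)
  S_mm <- sum(e2 * m^2)
  const_saxs <- 0.5 * sum(log(2 * pi * curve$error^2))

  has_cs <- !is.null(cs_data)
  if (has_cs) {
    if (is.null(library$cs_pred))
      abort("cs_data supplied but the library has no predicted shifts")
    C <- as.matrix(library$cs_pred)
    err <- library$cs_pred_err %||% 0
    if (length(err) == 1L) err <- rep(err, ncol(C))
    v <- err^2 + cs_data$error^2
    if (any(v <= 0)) abort("degenerate chemical-shift variance")
    mc <- cs_data$shift
    b_vec <- as.vector(C %*% (mc / v))
    H <- C %*% (t(C) / v)
    hdiag <- diag(H)
    S_cc <- sum(mc^2 / v)
    const_cs <- 0.5 * sum(log(2 * pi * v))
  }

  energy_case <- !is.null(energy_spec)
  if (!energy_case) {
    p <- rep(0.5, n)
    p0 <- n / 2
    sum_lgamma_p <- n * lgamma(0.5)
  }

  fn <- function(alpha, u_ref = NULL) {
    if (any(alpha <= 0) || any(!is.finite(alpha)))
      abort("alpha must be finite and strictly positive")
    if (energy_case) {
      p <- prior_beta(energy_spec, u_ref)
      p0 <- sum(p)
      sum_lgamma_p <- sum(lgamma(p))
    }
    a0 <- sum(alpha)
    kl <- lgamma(a0) - lgamma(p0) + sum_lgamma_p - sum(lgamma(alpha)) +
      sum((alpha - p) * (digamma(alpha) - digamma(a0)))

    Ga <- as.vector(G %*% alpha)
    g_q <- sum(alpha * Ga)
    t_q <- sum(alpha * a_vec)
    if (g_q <= 0) abort("degenerate profile Gram form")
    lambda <- a0 * t_q / g_q
    misfit <- 0.5 * (S_mm - t_q^2 / g_q)
    covden <- a0^2 * (a0 + 1)
    cov_saxs <- 0.5 * lambda^2 * (a0 * sum(gdiag * alpha) - g_q) / covden

    L <- kl + const_saxs + misfit + cov_saxs
    if (has_cs) {
      Ha <- as.vector(H %*% alpha)
      h_q <- sum(alpha * Ha)
      misfit_cs <- 0.5 * (S_cc - 2 * sum(alpha * b_vec) / a0 + h_q / a0^2)
      cov_cs <- 0.5 * (a0 * sum(hdiag * alpha) - h_q) / covden
      L <- L + const_cs + misfit_cs + cov_cs
    }
    if (!is.finite(L)) abort("non-finite variational objective")
    attr(L, "lambda") <- lambda
    L
  }
  # analytic gradient dL/d(alpha); same precomputed pieces
  gr <- function(alpha, u_ref = NULL) {
    if (energy_case) {
      p <- prior_beta(energy_spec, u_ref)
      p0 <- sum(p)
    }
    a0 <- sum(alpha)
    g_kl <- (alpha - p) * trigamma(alpha) - (a0 - p0) * trigamma(a0)

    Ga <- as.vector(G %*% alpha)
    g_q <- sum(alpha * Ga)
    t_q <- sum(alpha * a_vec)
    lambda <- a0 * t_q / g_q
    g_mis <- -(t_q / g_q) * a_vec + (t_q^2 / g_q^2) * Ga

    s_q <- sum(gdiag * alpha)
    covden <- a0^2 * (a0 + 1)
    C0 <- (a0 * s_q - g_q) / covden
    dlam <- t_q / g_q + (a0 / g_q) * a_vec - (2 * a0 * t_q / g_q^2) * Ga
    dC0 <- ((s_q + a0 * gdiag - 2 * Ga) * covden -
              (a0 * s_q - g_q) * (2 * a0 * (a0 + 1) + a0^2)) / covden^2
    g_cov <- lambda * C0 * dlam + 0.5 * lambda^2 * dC0

    out <- g_kl + g_mis + g_cov
    if (has_cs) {
      Ha <- as.vector(H %*% alpha)
      h_q <- sum(alpha * Ha)
      tb <- sum(alpha * b_vec)
      g_mis_cs <- -b_vec / a0 + tb / a0^2 + Ha / a0^2 - h_q / a0^3
      sh <- sum(hdiag * alpha)
      dC0h <- ((sh + a0 * hdiag - 2 * Ha) * covden -
                 (a0 * sh - h_q) * (2 * a0 * (a0 + 1) + a0^2)) / covden^2
      out <- out + g_mis_cs + 0.5 * dC0h
    }
    out
  }
  attr(fn, "gradient") <- gr
  fn
}

#' Evaluate the variational objective L once
#'
#' Convenience wrapper around [make_elbo_objective()]; L is the quantity
#' minimized during model selection and -L is the evidence lower bound.
#'
#' @inheritParams make_elbo_objective
#' @param alpha Positive Dirichlet concentration vector over the library
#'   members.
#' @param u_ref Optional reference-energy shift (energy prior only).
#' @return L (numeric scalar, attribute `lambda` holds the profiled SAXS
#'   scale).
#' @export
negative_elbo <- function(alpha, curve, library, cs_data = NULL,
                          energy_spec = NULL, u_ref = NULL) {
  if (length(alpha) != length(library$ids))
    abort("alpha length must match the library size")
  make_elbo_objective(curve, library, cs_data, energy_spec)(alpha, u_ref)
}

#' Dirichlet covariance factor matrix
#'
#' \eqn{Cov(w_i, w_j)} of a Dirichlet(\eqn{\alpha}):
#' \eqn{[\alpha_i(\alpha_0-\alpha_i)\delta_{ij} -
#' \alpha_i\alpha_j(1-\delta_{ij})]/(\alpha_0^2(\alpha_0+1))}.
#' Exposed for oracle tests of the covariance correction term.
#'
#' @param alpha Positive concentration vector.
#' @return The n x n covariance matrix.
#' @export
dirichlet_cov <- function(alpha) {
  a0 <- sum(alpha)
  (diag(alpha * a0, nrow = length(alpha)) - outer(alpha, alpha)) /
    (a0^2 * (a0 + 1))
}

#' Simulated-annealing schedule
#'
#' Geometric cooling from `t_start` to `t_end` over `n_steps` proposals.
#'
#' @param t_start,t_end Start/end temperatures in objective units;
#'   `t_start > t_end > 0`.
#' @param n_steps Number of proposals (>= 1).
#' @param step_scale Standard deviation of the Gaussian perturbation of a
#'   single log-concentration per proposal.
#' @param seed Optional RNG seed for a reproducible trajectory.
#' @return List of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_start = 1, t_end = 1e-3, n_steps = 5000,
                            step_scale = 0.3, seed = NULL) {
  if (!(t_start > t_end && t_end > 0)) abort("need t_start > t_end > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  structure(list(t_start = t_start, t_end = t_end, n_steps = as.integer(n_steps),
                 step_scale = step_scale, seed = seed),
            class = "anneal_schedule")
}

#' Minimize an objective over positive parameters by simulated annealing
#'
#' Proposals perturb one randomly chosen log-parameter by a Gaussian step
#' (so parameters stay positive); a worse value \eqn{\Delta L > 0} is
#' accepted with probability \eqn{\exp(-\Delta L / T)} under geometric
#' cooling. The best-ever state is returned. When `extra_range` is given,
#' an additional scalar (e.g. the energy-prior reference shift) is
#' co-optimized with uniform proposals on that interval.
#'
#' @param par Positive start vector.
#' @param fn Objective `fn(par, extra)`; must return a finite value.
#' @param schedule An [anneal_schedule()].
#' @param extra Optional starting value of the co-optimized scalar.
#' @param extra_range Optional length-2 interval for `extra` proposals.
#' @return List with `par`, `extra`, `value`, `accept_rate`.
#' @export
anneal_optimize <- function(par, fn, schedule = anneal_schedule(),
                            extra = NULL, extra_range = NULL) {
  if (any(par <= 0)) abort("start point must be strictly positive")
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  n <- length(par)
  lp <- log(par)
  cur_extra <- extra
  cur <- fn(exp(lp), cur_extra)
  if (!is.finite(cur))
    abort(paste0("objective not finite at start; par = ",
                 paste(signif(par, 4), collapse = ", ")))
  best <- cur; best_lp <- lp; best_extra <- cur_extra
  ns <- schedule$n_steps
  temps <- if (ns == 1L) schedule$t_start else
    schedule$t_start * (schedule$t_end / schedule$t_start)^((seq_len(ns) - 1) / (ns - 1))
  move_extra_p <- if (!is.null(extra_range)) 1 / (n + 1) else 0
  n_acc <- 0L
  for (k in seq_len(ns)) {
    if (move_extra_p > 0 && runif(1) < move_extra_p) {
      prop_extra <- runif(1, extra_range[[1]], extra_range[[2]])
      val <- fn(exp(lp), prop_extra)
      if (is.nan(val))
        abort(paste0("objective returned NaN at step ", k, "; u_ref = ",
                     signif(prop_extra, 6), "; alpha = ",
                     paste(signif(exp(lp), 4), collapse = ", ")))
      d <- val - cur
      if (d <= 0 || runif(1) < exp(-d / temps[[k]])) {
        cur <- val; cur_extra <- prop_extra; n_acc <- n_acc + 1L
      }
    } else {
      i <- sample.int(n, 1L)
      old <- lp[[i]]
      lp[[i]] <- min(30, max(-30, old + rnorm(1, 0, schedule$step_scale)))
      val <- fn(exp(lp), cur_extra)
      if (is.nan(val))
        abort(paste0("objective returned NaN at step ", k, "; alpha = ",
                     paste(signif(exp(lp), 4), collapse = ", ")))
      d <- val - cur
      if (d <= 0 || runif(1) < exp(-d / temps[[k]])) {
        cur <- val; n_acc <- n_acc + 1L
      } else {
        lp[[i]] <- old
      }
    }
    if (cur < best) { best <- cur; best_lp <- lp; best_extra <- cur_extra }
  }
  list(par = exp(best_lp), extra = best_extra, value = as.numeric(best),
       accept_rate = n_acc / ns)
}

#' Model-selection configuration
#'
#' @param w_cut Pruning threshold: conformers whose variational weight
#'   falls strictly below it are culled (default 0.01, well below the
#'   smallest population a small-ensemble experiment resolves).
#' @param patience Iterations without improvement of L before the inner
#'   loop stops (default 10).
#' @param max_restarts Maximum number of re-optimization passes started
#'   from the surviving set (SAXS-only / SAXS+CS runs; a single pass
#'   suffices with energy priors).
#' @param use_energies Use the library energies as a Boltzmann-biased
#'   prior; default: whenever the library carries energies.
#' @param kT Thermal scale of the energy prior.
#' @param u_ref_range Interval for the co-optimized reference shift;
#'   default `-min(U) + c(-5, 5) * kT * log(10)` (prior total
#'   concentration swept over ten orders of magnitude).
#' @param n_steps,step_scale Annealing proposals per optimization and
#'   log-step width.
#' @param t_start_factor,t_end_factor Start/end temperature as multiples
#'   of the local objective variability (median |change in L| over probe
#'   proposals around the start point; geometric cooling between them).
#' @param polish Quasi-Newton refinement of the annealed optimum
#'   (recommended; the annealer locates the basin, the polish sharpens
#'   the point estimate).
#' @param max_cull_frac At most `floor(n * max_cull_frac)` members culled
#'   per iteration, guarding against premature pruning of small-weight
#'   members.
#' @param improve_tol Minimum decrease of L that counts as improvement.
#' @param seed RNG seed for the whole selection run.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(w_cut = 0.01, patience = 10, max_restarts = 3,
                             use_energies = NULL, kT = 1,
                             u_ref_range = NULL, n_steps = 5000,
                             step_scale = 0.3, t_start_factor = 10,
                             t_end_factor = 1e-3, polish = TRUE,
                             max_cull_frac = 0.5, improve_tol = 1e-6,
                             seed = NULL) {
  if (!(w_cut > 0 && w_cut < 1)) abort("w_cut must be in (0, 1)")
  if (patience < 1) abort("patience must be >= 1")
  structure(list(w_cut = w_cut, patience = as.integer(patience),
                 max_restarts = as.integer(max_restarts),
                 use_energies = use_energies, kT = kT,
                 u_ref_range = u_ref_range, n_steps = as.integer(n_steps),
                 step_scale = step_scale, t_start_factor = t_start_factor,
                 t_end_factor = t_end_factor, polish = polish,
                 max_cull_frac = max_cull_frac, improve_tol = improve_tol,
                 seed = seed),
            class = "selection_config")
}

# deterministic seed substream
seed_stream <- function(seed) {
  k <- 0L
  function() {
    if (is.null(seed)) return(NULL)
    k <<- k + 1L
    (as.integer(seed) + k * 1009L) %% 2147483646L + 1L
  }
}

# one ELBO optimization on a fixed candidate set
fit_alpha <- function(curve, sublib, cs_data, energy_spec, config,
                      u_ref_init, seed, alpha_init = NULL) {
  obj <- make_elbo_objective(curve, sublib, cs_data, energy_spec)
  n <- length(sublib$ids)
  alpha0 <- alpha_init %||%
    (if (is.null(energy_spec)) rep(0.5, n) else
      pmax(prior_beta(energy_spec, u_ref_init), 1e-8))
  # set the temperature scale from the objective's local variability:
  # probe single-coordinate steps around the start point
  if (!is.null(seed)) set.seed(seed)
  L0 <- as.numeric(obj(alpha0, u_ref_init))
  probe <- replicate(40, {
    a <- alpha0
    i <- sample.int(n, 1L)
    a[[i]] <- a[[i]] * exp(rnorm(1, 0, config$step_scale))
    as.numeric(obj(a, u_ref_init)) - L0
  })
  sc <- max(stats::median(abs(probe)), 1e-3)
  sched <- anneal_schedule(t_start = config$t_start_factor * sc,
                           t_end = config$t_end_factor * sc,
                           n_steps = config$n_steps,
                           step_scale = config$step_scale, seed = seed)
  res <- anneal_optimize(alpha0, obj, sched, extra = u_ref_init,
                         extra_range = if (!is.null(energy_spec))
                           config$u_ref_range)
  anneal_par <- res$par  # stochastic (pre-polish) optimum
  if (isTRUE(config$polish)) {
    grf <- attr(obj, "gradient")
    polish_once <- function(lp0, uref) {
      try(optim(lp0,
                fn = function(lp) obj(exp(pmin(pmax(lp, -30), 30)), uref),
                gr = function(lp) {
                  a <- exp(pmin(pmax(lp, -30), 30))
                  grf(a, uref) * a  # chain rule to log-alpha
                },
                method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14)),
          silent = TRUE)
    }
    for (round in 1:4) {
      pol <- polish_once(log(res$par), res$extra)
      improved <- FALSE
      if (!inherits(pol, "try-error") && is.finite(pol$value) &&
          pol$value < res$value - 1e-10) {
        res$par <- exp(pmin(pmax(pol$par, -30), 30))
        improved <- pol$value < res$value - 1e-6 * max(1, abs(res$value))
        res$value <- pol$value
      }
      if (!is.null(energy_spec)) {
        opt_u <- optimize(function(u) obj(res$par, u),
                          interval = config$u_ref_range)
        if (opt_u$objective < res$value - 1e-10) {
          improved <- TRUE
          res$extra <- opt_u$minimum
          res$value <- opt_u$objective
        }
      }
      if (!improved) break
    }
  }
  L <- obj(res$par, res$extra)
  list(alpha = res$par, u_ref = res$extra, L = as.numeric(L),
       lambda = attr(L, "lambda"), anneal_alpha = anneal_par)
}

#' Variational model selection of a conformational ensemble
#'
#' Iterative prune-and-refit loop: the variational objective L is
#' minimized over the Dirichlet concentration parameters on the current
#' candidate set (simulated annealing plus optional quasi-Newton polish),
#' point-estimate weights \eqn{w_i = \alpha_i/\alpha_0} are computed, and
#' members with \eqn{w_i < w_{cut}} are culled (at most half the set per
#' iteration; ties at the threshold are retained). The loop stops once no
#' member is culled and L has not improved for `patience` iterations.
#' Without an energy prior the whole pass is restarted from the surviving
#' set until L no longer improves across passes; with an energy prior a
#' single pass is run and the reference shift `U_ref` is co-optimized
#' with the concentrations.
#'
#' @param curve A [saxs_curve()].
#' @param library A [structural_library()] (>= 1 member).
#' @param cs_data Optional experimental [chemical_shift_data()].
#' @param config A [selection_config()].
#' @return An [ensemble_model()] with the selected subset, weights, final
#'   L, scale factor, optimized `u_ref` (energy runs), the per-iteration
#'   `history` tibble, and the fitted curve in `$fit`.
#' @export
select_ensemble <- function(curve, library, cs_data = NULL,
                            config = selection_config()) {
  n_lib <- length(library$ids)
  if (n_lib < 1L) abort("library must contain at least one conformer")
  use_energies <- config$use_energies %||% !is.null(library$energies)
  if (use_energies && is.null(library$energies))
    abort("use_energies = TRUE but the library has no energies")
  kT <- config$kT
  if (use_energies && is.null(config$u_ref_range))
    config$u_ref_range <- -min(library$energies) + c(-5, 5) * kT * log(10)
  next_seed <- seed_stream(config$seed)

  current_ids <- library$ids
  history <- list()
  global_best <- NULL
  pass_bests <- numeric(0)
  n_restarts <- if (use_energies) 1L else max(1L, config$max_restarts)

  for (pass in seq_len(n_restarts)) {
    best_L <- Inf
    no_improve <- 0L
    iter <- 0L
    alpha_cur <- NULL  # warm start: carried across pruning iterations
    u_ref_cur <- if (use_energies)
      -min(library$energies[match(current_ids, library$ids)])
    repeat {
      iter <- iter + 1L
      sublib <- subset_library(library, current_ids)
      espec <- if (use_energies)
        energy_prior(sublib$energies, kT = kT, u_ref = u_ref_cur)
      fit <- fit_alpha(curve, sublib, cs_data, espec, config,
                       u_ref_cur, next_seed(), alpha_init = alpha_cur)
      if (use_energies) u_ref_cur <- fit$u_ref
      alpha_cur <- fit$alpha
      w <- weights_from_alpha(fit$alpha)
      improved <- fit$L < best_L - config$improve_tol
      if (fit$L < best_L) best_L <- fit$L
      no_improve <- if (improved) 0L else no_improve + 1L

      below <- which(w < config$w_cut)  # strict: ties at w_cut retained
      if (length(below) == 0L && no_improve >= 1L && length(w) > 1L) {
        # Stagnant with every refined weight above the cut. First consult
        # the stochastic annealed weights (near-redundant members
        # fluctuate below the cut on flat stretches of L); failing that,
        # probe the next smaller model by trially removing the
        # lowest-weight member(s). The loop's own stopping rule arbitrates:
        # if the smaller models do not improve L, patience runs out and
        # the best state seen -- tracked globally -- is returned, so a
        # detrimental trial cull never corrupts the result.
        w_sto <- weights_from_alpha(fit$anneal_alpha)
        below <- which(w_sto < config$w_cut)
        if (length(below) > 0L) {
          w[below] <- w_sto[below]
        } else {
          n_trial <- max(1L, length(w) %/% 20L)
          below <- order(w)[seq_len(n_trial)]
        }
      }
      n_keep_min <- 1L
      max_cull <- floor(length(w) * config$max_cull_frac)
      cull <- integer(0)
      if (length(below) > 0L && max_cull > 0L) {
        cull <- below[order(w[below])][seq_len(min(length(below), max_cull))]
        if (length(w) - length(cull) < n_keep_min)
          cull <- cull[seq_len(length(w) - n_keep_min)]
      }
      if (length(below) == length(w) && length(w) - length(cull) <= 1L)
        warn("all members fell below w_cut; retaining the highest-weight conformer")
      history[[length(history) + 1L]] <- tibble(
        pass = pass, iteration = iter, L = fit$L,
        n_members = length(current_ids),
        culled = list(current_ids[cull]))
      if (is.null(global_best) || fit$L < global_best$L) {
        global_best <- c(fit, list(ids = current_ids))
      }
      if (no_improve >= config$patience) break
      if (length(cull) > 0L) {
        current_ids <- current_ids[-cull]
        alpha_cur <- alpha_cur[-cull]
        next
      }
    }
    # restart from the surviving set until L no longer improves across passes
    pass_bests <- c(pass_bests, best_L)
    if (pass > 1L &&
        best_L >= min(pass_bests[seq_len(pass - 1L)]) - config$improve_tol)
      break
  }

  sublib <- subset_library(library, global_best$ids)
  w <- weights_from_alpha(global_best$alpha)
  ibar <- as.vector(w %*% sublib$profiles)
  fitted <- global_best$lambda * ibar
  ensemble_model(
    member_ids = global_best$ids, weights = unname(w),
    L_value = global_best$L, lambda_hat = global_best$lambda,
    u_ref = if (use_energies) global_best$u_ref,
    alpha = unname(global_best$alpha),
    history = bind_rows(history),
    fit = tibble(q = curve$q, intensity = curve$intensity,
                 error = curve$error, fitted = fitted),
    use_energies = use_energies)
}
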