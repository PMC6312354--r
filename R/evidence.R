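#' Log model evidence by Monte Carlo integration
#'
#' Estimates \eqn{\log f(m|S) = \log \int f(m|w,S) f(w|S) dw} as the
#' log-mean of the likelihood over weight vectors sampled from the prior
#' Dirichlet (Jeffreys 1/2's, or Boltzmann-factor concentrations for an
#' energy prior). The SAXS scale factor is profiled analytically per draw,
#' mirroring its treatment in the variational stage. Accumulation is a
#' stabilized log-mean-exp; the standard error is a batch jackknife on the
#' log scale.
#'
#' @param curve A [saxs_curve()].
#' @param library A [structural_library()] restricted to the candidate
#'   subset under evaluation.
#' @param n_draws Number of prior draws (>= 1000).
#' @param cs_data Optional experimental [chemical_shift_data()].
#' @param energy_spec Optional [energy_prior()] over the subset members
#'   (Jeffreys prior when NULL).
#' @param seed Optional RNG seed.
#' @param n_batches Batches for the jackknife standard error.
#' @return List with `log_evidence`, `stderr`, `n_draws`.
#' @export
log_evidence_mc <- function(curve, library, n_draws = 1e5, cs_data = NULL,
                            energy_spec = NULL, seed = NULL,
                            n_batches = 20) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 1000L) abort("n_draws must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  n <- length(library$ids)
  conc <- if (is.null(energy_spec)) rep(0.5, n) else energy_spec$beta
  P <- library$profiles
  m <- curve$intensity
  e2 <- 1 / curve$error^2
  const_saxs <- -0.5 * sum(log(2 * pi * curve$error^2))
  S_mm <- sum(e2 * m^2)
  # per-draw likelihoods reduce to quadratic forms in the error-weighted
  # Gram matrix, so the per-draw cost is O(n^2) regardless of curve length
  a_vec <- as.vector(P %*% (m * e2))
  G <- P %*% (t(P) * e2)
  has_cs <- !is.null(cs_data)
  if (has_cs) {
    C <- as.matrix(library$cs_pred)
    err <- library$cs_pred_err %||% 0
    if (length(err) == 1L) err <- rep(err, ncol(C))
    v <- err^2 + cs_data$error^2
    mc <- cs_data$shift
    const_cs <- -0.5 * sum(log(2 * pi * v))
    b_vec <- as.vector(C %*% (mc / v))
    H <- C %*% (t(C) / v)
    S_cc <- sum(mc^2 / v)
  }

  ll <- numeric(n_draws)
  chunk <- 20000L
  done <- 0L
  while (done < n_draws) {
    k <- min(chunk, n_draws - done)
    W <- matrix(rgamma(k * n, shape = rep(conc, each = k)), nrow = k)
    W <- W / rowSums(W)
    num <- as.vector(W %*% a_vec)           # per-draw lambda numerator
    den <- rowSums((W %*% G) * W)           # w' G w
    ll_chunk <- const_saxs - 0.5 * (S_mm - num^2 / den)  # lambda profiled
    if (has_cs) {
      ll_chunk <- ll_chunk + const_cs -
        0.5 * (S_cc - 2 * as.vector(W %*% b_vec) + rowSums((W %*% H) * W))
    }
    ll[done + seq_len(k)] <- ll_chunk
    done <- done + k
  }

  mx <- max(ll)
  if (!is.finite(mx)) {
    warn("all likelihood draws underflowed; increase n_draws or temper")
    return(list(log_evidence = -Inf, stderr = NA_real_, n_draws = n_draws))
  }
  e <- exp(ll - mx)
  log_ev <- mx + log(mean(e))
  # batch jackknife on the log scale
  bidx <- rep(seq_len(n_batches), length.out = n_draws)
  bs <- vapply(seq_len(n_batches), function(b) sum(e[bidx == b]), numeric(1))
  bn <- tabulate(bidx, n_batches)
  tot <- sum(e)
  loo <- mx + log((tot - bs) / (n_draws - bn))
  se <- sqrt((n_batches - 1) / n_batches * sum((loo - mean(loo))^2))
  list(log_evidence = log_ev, stderr = se, n_draws = n_draws)
}

#' Log Bayes factor between two candidate subsets
#'
#' Difference of log evidences; equal prior model probabilities are
#' assumed, so this is the full model-comparison statistic.
#'
#' @param curve A [saxs_curve()].
#' @param library The full [structural_library()].
#' @param subset1,subset2 Conformer ids (or indices) of the two competing
#'   subsets.
#' @param ... Passed to [log_evidence_mc()] (`n_draws`, `cs_data`,
#'   `energy_spec`, `seed`, ...).
#' @return Log Bayes factor (positive favors `subset1`).
#' @export
log_bayes_factor <- function(curve, library, subset1, subset2, ...) {
  e1 <- log_evidence_mc(curve, subset_library(library, subset1), ...)
  e2 <- log_evidence_mc(curve, subset_library(library, subset2), ...)
  e1$log_evidence - e2$log_evidence
}

#' Exhaustive model-evidence scan over ensemble sizes
#'
#' Enumerates every subset of each requested size, estimates its log
#' evidence by [log_evidence_mc()], and reports the best subset per size
#' plus the globally selected size. Each subset gets its own deterministic
#' seed substream derived from `seed`, so subset evidences are independent
#' and reproducible.
#'
#' @param curve A [saxs_curve()].
#' @param library A [structural_library()].
#' @param sizes Integer ensemble sizes to scan.
#' @param n_draws Prior draws per subset.
#' @param seed Root seed.
#' @param cs_data,energy_spec Passed through to the evidence estimator
#'   (for an energy prior, the prior is rebuilt per subset from the
#'   library energies at the supplied `kT` and `u_ref`).
#' @param max_subsets Refuse to enumerate more than this many subsets
#'   unless `force = TRUE`.
#' @param force Override the combinatorial guard.
#' @return A tibble (class `evidence_scan`) with one row per size:
#'   `size`, `best_subset` (list-column of ids), `log_evidence`,
#'   `stderr`, `n_subsets`; attribute `selected_size` holds the size of
#'   the global evidence maximum.
#' @export
scan_ensemble_sizes <- function(curve, library, sizes, n_draws = 1e5,
                                seed = NULL, cs_data = NULL,
                                energy_spec = NULL, max_subsets = 1e6,
                                force = FALSE) {
  n <- length(library$ids)
  counts <- vapply(sizes, function(k) choose(n, k), numeric(1))
  if (sum(counts) > max_subsets && !force)
    abort(paste0("refusing to enumerate ", format(sum(counts), big.mark = ","),
                 " subsets (sum over k of C(", n, ", k)); use force = TRUE"))
  next_seed <- seed_stream(seed)
  rows <- lapply(seq_along(sizes), function(si) {
    k <- sizes[[si]]
    combos <- combn(n, k)
    best <- NULL
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      sub <- subset_library(library, idx)
      es <- if (!is.null(energy_spec))
        energy_prior(sub$energies, kT = energy_spec$kT,
                     u_ref = energy_spec$u_ref)
      ev <- log_evidence_mc(curve, sub, n_draws = n_draws, cs_data = cs_data,
                            energy_spec = es, seed = next_seed())
      if (is.null(best) || ev$log_evidence > best$log_evidence)
        best <- c(ev, list(ids = library$ids[idx], es = list(es)))
    }
    # the within-size maximum of noisy estimates is biased upward (more so
    # for sizes with more subsets); re-estimate the winner on fresh draws
    ev2 <- log_evidence_mc(curve, subset_library(library, best$ids),
                           n_draws = n_draws, cs_data = cs_data,
                           energy_spec = best$es[[1]], seed = next_seed())
    tibble(size = k, best_subset = list(best$ids),
           log_evidence = ev2$log_evidence, stderr = ev2$stderr,
           n_subsets = ncol(combos))
  })
  out <- bind_rows(rows)
  attr(out, "selected_size") <- out$size[[which.max(out$log_evidence)]]
  class(out) <- c("evidence_scan", class(out))
  out
}

#' Number of candidate ensembles of given sizes
#'
#' Exact \eqn{\sum_k \binom{n}{k}} computed in double precision binomial
#' arithmetic; used by the combinatorial guard and handy for reporting
#' how large an exhaustive scan would be.
#'
#' @param n Library size.
#' @param sizes Ensemble sizes.
#' @return The exact count (numeric; exact while below 2^53).
#' @export
count_ensembles <- function(n, sizes) sum(choose(n, sizes))
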