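#' Reduced chi-square of a model curve
#'
#' \eqn{\chi^2_\nu = \sum_j (m_j - \hat I_j)^2 / \varepsilon_j^2 / (N -
#' n_{free})}. The model intensity is the already-scaled ensemble curve
#' (e.g. `model$fit$fitted` from [select_ensemble()]).
#'
#' @param curve A [saxs_curve()].
#' @param model_intensity Model intensities on the curve's q-grid.
#' @param n_free Number of fitted parameters subtracted from the degrees
#'   of freedom; a common convention for an ensemble of k members plus a
#'   scale factor is `k - 1 + 1`.
#' @return Scalar reduced chi-square.
#' @export
reduced_chi2 <- function(curve, model_intensity, n_free = 0) {
  N <- nrow(curve)
  dof <- N - n_free
  if (dof < 1) abort("non-positive degrees of freedom")
  sum(((curve$intensity - model_intensity) / curve$error)^2) / dof
}

#' Error-weighted residuals
#'
#' Per-point \eqn{(m_j - \hat I_j)/\varepsilon_j}, the standard
#' difference-plot quantity for assessing SAXS model fits across the
#' measured q-range.
#'
#' @inheritParams reduced_chi2
#' @return Tibble with columns `q`, `residual`.
#' @export
weighted_residuals <- function(curve, model_intensity) {
  tibble(q = curve$q,
         residual = (curve$intensity - model_intensity) / curve$error)
}

# P(longest run >= C) in N fair Bernoulli trials, exact.
# Strings with max run <= r decompose as a sign choice times a composition
# of N into parts <= r; the DP runs on the probability scale (parts of
# length j weighted 2^-j) so large N never overflows.
longest_run_pvalue <- function(N, C) {
  if (C <= 1) return(1)
  r <- C - 1L
  p <- numeric(N + 1L)
  p[1L] <- 1  # p[n+1] = (# compositions of n into parts <= r) / 2^n
  w <- 2^-(seq_len(r))
  for (n in seq_len(N)) {
    j <- seq_len(min(r, n))
    p[n + 1L] <- sum(p[n + 1L - j] * w[j])
  }
  max(0, min(1, 1 - 2 * p[N + 1L]))
}

#' Correlation-map longest-run test
#'
#' Identifies the longest stretch of residuals lying on one side of the
#' model curve and the probability of observing a run at least that long
#' among N fair coin flips. The null distribution is computed exactly by
#' dynamic programming over run-length-bounded sign sequences, not by an
#' asymptotic approximation. Zero residuals break runs on both sides.
#'
#' @param residuals Numeric residuals (any scale; only signs are used) or
#'   a sign vector.
#' @return List with `C` (longest run), `p_value`, and `n`.
#' @examples
#' cormap_pvalue(c(1, 1, 1))  # C = 3, P = 0.25
#' @export
cormap_pvalue <- function(residuals) {
  n <- length(residuals)
  if (n < 2L) abort("need at least 2 residuals")
  s <- sign(residuals)
  runs <- rle(s)
  C <- max(runs$lengths[runs$values != 0], 0L)
  if (C == 0L)  # all residuals exactly zero
    return(list(C = 0L, p_value = 1, n = n))
  list(C = as.integer(C), p_value = longest_run_pvalue(n, C), n = n)
}

#' Goodness-of-fit report for an ensemble model
#'
#' Bundles reduced chi-square (raw and dof-corrected), error-weighted
#' residual summary and the correlation-map test for a fitted ensemble.
#'
#' @param model An [ensemble_model()] carrying its `fit` tibble.
#' @param n_free Degrees-of-freedom correction; default
#'   `length(weights) - 1 + 1` (independent weights plus the scale
#'   factor).
#' @return One-row tibble with `chi2_raw`, `chi2_reduced`, `n_free`,
#'   `cormap_C`, `cormap_p`.
#' @export
fit_quality <- function(model, n_free = NULL) {
  if (is.null(model$fit)) abort("model carries no fitted curve")
  n_free <- n_free %||% length(model$weights)  # (k - 1) weights + lambda
  curve <- saxs_curve(model$fit$q, model$fit$intensity, model$fit$error)
  res <- weighted_residuals(curve, model$fit$fitted)
  cm <- cormap_pvalue(res$residual)
  tibble(chi2_raw = reduced_chi2(curve, model$fit$fitted, 0),
         chi2_reduced = reduced_chi2(curve, model$fit$fitted, n_free),
         n_free = n_free, cormap_C = cm$C, cormap_p = cm$p_value)
}
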