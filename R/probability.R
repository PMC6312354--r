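#' Boltzmann population weights from conformer energies
#'
#' Maps per-conformer energies to equilibrium populations
#' \eqn{w_i \propto \exp(-U_i / kT)}. Computed with min-energy subtraction
#' so arbitrarily shifted energy scales (e.g. force-field scores near
#' -140) never overflow; the populations are invariant under any additive
#' shift of all energies.
#'
#' @param energies Numeric vector of energies (lower = more favorable).
#' @param kT Thermal energy in the same units as `energies`; must be > 0.
#' @return Simplex weight vector.
#' @examples
#' boltzmann_weights(c(0, -log(2)), kT = 1)  # (1/3, 2/3)
#' @export
boltzmann_weights <- function(energies, kT = 1) {
  if (!is.numeric(kT) || length(kT) != 1L || kT <= 0)
    abort("kT must be a single positive number")
  if (any(!is.finite(energies))) abort("energies must be finite")
  z <- exp(-(energies - min(energies)) / kT)
  z / sum(z)
}

#' Energy-biased Dirichlet prior specification
#'
#' Defines the Dirichlet prior over population weights whose concentration
#' parameters are Boltzmann factors \eqn{\beta_i = \exp(-(U_{ref}+U_i)/kT)}.
#' Its mean equals [boltzmann_weights()] exactly for any `u_ref`; `u_ref`
#' only rescales the total concentration \eqn{\beta_0}, i.e. the sharpness
#' of the prior (smaller `u_ref` means larger \eqn{\beta_i}, a tighter
#' prior around the Boltzmann populations).
#'
#' @param energies Per-conformer energies.
#' @param kT Thermal energy scale, same units; default 1 (energies in
#'   native force-field units).
#' @param u_ref Reference energy shift. Default `-min(energies)`, which
#'   puts the largest \eqn{\beta_i} at 1.
#' @return Object of class `energy_prior` with fields `energies`, `kT`,
#'   `u_ref`, `log_beta`, `beta`.
#' @export
energy_prior <- function(energies, kT = 1, u_ref = NULL) {
  if (kT <= 0) abort("kT must be positive")
  if (any(!is.finite(energies))) abort("energies must be finite")
  u_ref <- u_ref %||% -min(energies)
  log_beta <- -(u_ref + energies) / kT
  if (any(log_beta > 700))
    abort("beta overflow: raise u_ref (it tunes the prior sharpness)")
  beta <- exp(log_beta)
  if (any(beta <= 0) || any(!is.finite(beta)))
    abort("degenerate beta; adjust u_ref")
  structure(list(energies = as.numeric(energies), kT = kT, u_ref = u_ref,
                 log_beta = log_beta, beta = beta),
            class = "energy_prior")
}

# beta vector for an energy prior at a (possibly different) u_ref
prior_beta <- function(spec, u_ref = NULL) {
  if (is.null(u_ref) || identical(u_ref, spec$u_ref)) return(spec$beta)
  lb <- -(u_ref + spec$energies) / spec$kT
  if (any(lb > 700))
    abort("beta overflow: raise u_ref (it tunes the prior sharpness)")
  exp(lb)
}

check_simplex_interior <- function(w) {
  if (any(w <= 0))
    abort("weights must be strictly inside the simplex (all > 0)")
  if (abs(sum(w) - 1) > 1e-6)
    abort("weights must sum to 1")
  invisible(w)
}

#' Jeffreys log prior density over population weights
#'
#' The non-informative Dirichlet(1/2, ..., 1/2) density,
#' \eqn{\Gamma(n/2)\,\Gamma(1/2)^{-n} \prod_i w_i^{-1/2}}. Undefined on the
#' simplex boundary.
#'
#' @param w Weight vector strictly inside the simplex.
#' @return Log density.
#' @export
jeffreys_log_prior <- function(w) {
  check_simplex_interior(w)
  n <- length(w)
  lgamma(n / 2) - n * lgamma(0.5) - 0.5 * sum(log(w))
}

#' Energy-biased Dirichlet log prior density
#'
#' Dirichlet density with Boltzmann-factor concentration parameters, see
#' [energy_prior()].
#'
#' @param w Weight vector strictly inside the simplex.
#' @param spec An [energy_prior()].
#' @return Log density.
#' @export
energy_log_prior <- function(w, spec) {
  check_simplex_interior(w)
  b <- spec$beta
  if (length(b) != length(w)) abort("prior dimension does not match weights")
  lgamma(sum(b)) - sum(lgamma(b)) + sum((b - 1) * log(w))
}

#' Optimal SAXS scale factor
#'
#' The least-squares scale between the measured curve and the
#' ensemble-averaged profile under the error metric:
#' \deqn{\lambda = \frac{\sum_j \varepsilon_j^{-2} m_j \bar I_j}
#'                     {\sum_j \varepsilon_j^{-2} \bar I_j^2}}
#' where \eqn{\bar I_j = \sum_i w_i I_{ij}} (weights may be passed as
#' Dirichlet concentrations; they are normalized internally).
#'
#' @param curve A [saxs_curve()].
#' @param profiles Matrix of per-conformer profiles (rows) on the curve's
#'   q-grid, or a [structural_library()].
#' @param weights Simplex weights or unnormalized concentrations.
#' @return The scalar scale factor.
#' @export
saxs_scale_factor <- function(curve, profiles, weights) {
  if (inherits(profiles, "structural_library")) profiles <- profiles$profiles
  w <- weights / sum(weights)
  ibar <- as.vector(w %*% profiles)
  e2 <- 1 / curve$error^2
  den <- sum(e2 * ibar^2)
  if (den <= 0) abort("degenerate profile: ensemble average is identically zero")
  sum(e2 * curve$intensity * ibar) / den
}

#' Gaussian SAXS log-likelihood
#'
#' Independent Gaussian errors per point:
#' \eqn{\sum_j \log N(m_j \mid \lambda \sum_i w_i I_{ij}, \varepsilon_j)}.
#'
#' @param curve A [saxs_curve()].
#' @param profiles Per-conformer profile matrix or [structural_library()].
#' @param w Simplex weights.
#' @param lambda Scale factor; default the optimal [saxs_scale_factor()].
#' @return Log-likelihood.
#' @export
saxs_loglik <- function(curve, profiles, w, lambda = NULL) {
  if (inherits(profiles, "structural_library")) profiles <- profiles$profiles
  lambda <- lambda %||% saxs_scale_factor(curve, profiles, w)
  ibar <- as.vector((w / sum(w)) %*% profiles)
  sum(dnorm(curve$intensity, mean = lambda * ibar, sd = curve$error,
            log = TRUE))
}

#' Gaussian chemical-shift log-likelihood
#'
#' Per-shift Gaussian with combined variance
#' \eqn{\varepsilon_{CS}^2 + \varepsilon_{pre}^2} (prediction uncertainty
#' plus experimental error). Chemical shifts are on an absolute ppm scale,
#' so no scale factor is applied.
#'
#' @param cs_data Experimental [chemical_shift_data()].
#' @param cs_pred Predicted-shift matrix (conformers x shifts).
#' @param cs_pred_err Per-shift prediction uncertainty (scalar broadcast
#'   allowed).
#' @param w Simplex weights.
#' @return Log-likelihood.
#' @export
cs_loglik <- function(cs_data, cs_pred, cs_pred_err, w) {
  cs_pred <- as.matrix(cs_pred)
  k <- ncol(cs_pred)
  if (length(cs_pred_err) == 1L) cs_pred_err <- rep(cs_pred_err, k)
  v <- cs_pred_err^2 + cs_data$error^2
  if (any(v <= 0))
    abort("degenerate variance: both error terms are zero for some shift")
  pred <- as.vector((w / sum(w)) %*% cs_pred)
  sum(dnorm(cs_data$shift, mean = pred, sd = sqrt(v), log = TRUE))
}

#' Combined log-likelihood over all data sources
#'
#' Product of the SAXS and (if supplied) chemical-shift likelihoods, i.e.
#' the sum of [saxs_loglik()] and [cs_loglik()].
#'
#' @param curve A [saxs_curve()].
#' @param library A [structural_library()] (its `cs_pred`/`cs_pred_err`
#'   are used when `cs_data` is supplied).
#' @param w Simplex weights.
#' @param lambda SAXS scale factor; default optimal.
#' @param cs_data Optional experimental [chemical_shift_data()].
#' @return Log-likelihood.
#' @export
combined_loglik <- function(curve, library, w, lambda = NULL,
                            cs_data = NULL) {
  ll <- saxs_loglik(curve, library$profiles, w, lambda)
  if (!is.null(cs_data)) {
    if (is.null(library$cs_pred))
      abort("cs_data supplied but the library has no predicted shifts")
    ll <- ll + cs_loglik(cs_data, library$cs_pred, library$cs_pred_err, w)
  }
  ll
}
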