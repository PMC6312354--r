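#' Tidy an ensemble model
#'
#' @param x An [ensemble_model()].
#' @param ... Unused.
#' @return Tibble with one row per retained conformer: `member_id`,
#'   `weight`, `alpha`.
#' @export
tidy.ensemble_model <- function(x, ...) {
  tibble(member_id = x$member_ids, weight = x$weights,
         alpha = x$alpha %||% rep(NA_real_, length(x$weights)))
}

#' One-row summary of an ensemble model
#'
#' @param x An [ensemble_model()].
#' @param ... Unused.
#' @return Tibble with `n_members`, `L_value`, `lambda_hat`, `u_ref`.
#' @export
glance.ensemble_model <- function(x, ...) {
  tibble(n_members = length(x$member_ids), L_value = x$L_value,
         lambda_hat = x$lambda_hat, u_ref = x$u_ref %||% NA_real_)
}

#' Tidy posterior draws into long format
#'
#' @param x A [posterior_draws()] object.
#' @param ... Unused.
#' @return Long tibble: `.chain`, `.draw`, `parameter`, `value` (weights
#'   per member id, `lambda`, and `u_ref` when sampled).
#' @export
tidy.posterior_draws <- function(x, ...) {
  n <- nrow(x$w_draws)
  base <- as_tibble(x$w_draws)
  names(base) <- paste0("w[", colnames(x$w_draws), "]")
  base$lambda <- x$lambda_draws
  if (!is.null(x$uref_draws)) base$u_ref <- x$uref_draws
  base$.chain <- x$chain_ids
  base$.draw <- seq_len(n)
  tidyr::pivot_longer(base, cols = -c(".chain", ".draw"),
                      names_to = "parameter", values_to = "value")
}

#' Posterior summary with convergence diagnostics
#'
#' @param x A [posterior_draws()] object.
#' @param ... Unused.
#' @return Tibble per parameter: posterior `mean`, `sd`, central 95%
#'   interval, split-Rhat and effective sample size.
#' @export
glance.posterior_draws <- function(x, ...) {
  vals <- cbind(x$w_draws, lambda = x$lambda_draws,
                if (!is.null(x$uref_draws)) u_ref = x$uref_draws)
  colnames(vals) <- x$diagnostics$parameter
  tibble(parameter = x$diagnostics$parameter,
         mean = colMeans(vals),
         sd = apply(vals, 2, sd),
         q2.5 = apply(vals, 2, quantile, 0.025),
         q97.5 = apply(vals, 2, quantile, 0.975),
         rhat = x$diagnostics$rhat,
         ess = x$diagnostics$ess)
}

#' Plot a SAXS curve
#'
#' @param object A [saxs_curve()].
#' @param ... Unused.
#' @return A ggplot (log-intensity vs q with error bars).
#' @export
autoplot.saxs_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$q, y = .data$intensity)) +
    geom_point(size = 0.7) +
    ggplot2::geom_errorbar(aes(ymin = .data$intensity - .data$error,
                               ymax = .data$intensity + .data$error),
                           linewidth = 0.2, alpha = 0.5) +
    scale_y_log10() +
    labs(x = "q (1/Å)", y = "I(q)") +
    theme_bw()
}

#' Plot an ensemble-model fit with error-weighted residuals
#'
#' @param object An [ensemble_model()] carrying its `fit` tibble.
#' @param ... Unused.
#' @return A ggplot: data and model curve (log scale) over q.
#' @export
autoplot.ensemble_model <- function(object, ...) {
  if (is.null(object$fit)) abort("model carries no fitted curve")
  ggplot(object$fit, aes(x = .data$q)) +
    geom_point(aes(y = .data$intensity), size = 0.7, alpha = 0.6) +
    geom_line(aes(y = .data$fitted), color = "#d55e00") +
    scale_y_log10() +
    labs(x = "q (1/Å)", y = "I(q)",
         title = sprintf("%d-member ensemble fit", length(object$weights))) +
    theme_bw()
}

#' Plot posterior weight distributions
#'
#' @param object A [posterior_draws()] object.
#' @param ... Unused.
#' @return A ggplot of per-member weight densities.
#' @export
autoplot.posterior_draws <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, startsWith(.data$parameter, "w["))
  ggplot(df, aes(x = .data$value)) +
    ggplot2::geom_density(fill = "#56b4e9", alpha = 0.5) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "population weight", y = "posterior density") +
    theme_bw()
}

#' Plot a posterior predictive envelope
#'
#' @param object A `posterior_predictive` result.
#' @param ... Unused.
#' @return A ggplot with the 95% predictive band and the data.
#' @export
autoplot.posterior_predictive <- function(object, ...) {
  ggplot(object$envelope, aes(x = .data$q)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "#56b4e9",
                alpha = 0.4) +
    geom_line(aes(y = .data$mid), color = "#0072b2") +
    geom_point(aes(y = .data$intensity), size = 0.6) +
    scale_y_log10() +
    labs(x = "q (1/Å)", y = "I(q)",
         title = sprintf("posterior predictive check (coverage %.2f)",
                         object$coverage)) +
    theme_bw()
}

#' @importFrom rlang .data
NULL
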