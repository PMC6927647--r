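#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

label_parameters <- function(fit, parameters) {
  lab <- parameters
  for (j in seq_along(fit$terms)) {
    lab[lab == sprintf("beta[%d]", j)] <- fit$terms[j]
  }
  zyears <- if (inherits(fit, "pop_fit")) fit$years else fit$years
  for (t in seq_along(zyears)) {
    lab[lab == sprintf("zeta[%d]", t)] <- sprintf("zeta_%d", zyears[t])
  }
  lab
}

#' Tidy posterior summaries of a fitted model
#'
#' One row per parameter with the posterior median and HPD interval at
#' `conf.level`, following the broom convention. Coefficients are labelled by
#' their design-term names, year effects by calendar year.
#'
#' @param x A `pop_fit` or `ratio_fit`.
#' @param parameters Regular expression selecting monitored scalars.
#' @param conf.level HPD interval mass.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `conf.low`, `conf.high`, `rhat`,
#'   `ess`.
#' @method tidy pop_fit
#' @export
tidy.pop_fit <- function(x, parameters = "^(phi_a|alpha|beta|sigma|zeta)",
                         conf.level = 0.9, ...) {
  s <- posterior_summary(x, parameters, mass = conf.level, mass50 = FALSE)
  conv <- convergence_report(x, parameters)
  tibble::tibble(term = label_parameters(x, s$parameter),
                 estimate = s$median, conf.low = s$lower, conf.high = s$upper,
                 rhat = conv$rhat[match(s$parameter, conv$parameter)],
                 ess = conv$ess[match(s$parameter, conv$parameter)])
}

#' @rdname tidy.pop_fit
#' @method tidy ratio_fit
#' @export
tidy.ratio_fit <- tidy.pop_fit

#' One-row fit summary
#'
#' @param x A `pop_fit` or `ratio_fit`.
#' @param ... Unused.
#' @return A tibble with chain bookkeeping, the worst split R-hat and smallest
#'   ESS over hyperparameters, and the runtime.
#' @method glance pop_fit
#' @export
glance.pop_fit <- function(x, ...) {
  conv <- convergence_report(x, "^(phi_a|alpha|beta|sigma)")
  tibble::tibble(chains = x$protocol$chains,
                 kept_per_chain = x$protocol$kept_per_chain,
                 total_kept = x$protocol$total_kept,
                 max_rhat = max(conv$rhat, na.rm = TRUE),
                 min_ess = min(conv$ess),
                 runtime = x$runtime)
}

#' @rdname glance.pop_fit
#' @method glance ratio_fit
#' @export
glance.ratio_fit <- function(x, ...) {
  conv <- convergence_report(x, "^(alpha|beta|sigma)")
  tibble::tibble(chains = x$protocol$chains,
                 kept_per_chain = x$protocol$kept_per_chain,
                 total_kept = x$protocol$total_kept,
                 max_rhat = max(conv$rhat, na.rm = TRUE),
                 min_ess = min(conv$ess),
                 runtime = x$runtime)
}

#' Coefficient forest plot
#'
#' Posterior medians with 50% (heavy) and 90% (light) HPD intervals for every
#' covariate coefficient, the display used to compare evidence for recruitment
#' drivers between the two models.
#'
#' @param object A `pop_fit` or `ratio_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pop_fit
#' @export
autoplot.pop_fit <- function(object, ...) {
  s <- posterior_summary(object, "^beta\\[", mass = 0.9, mass50 = TRUE)
  s$term <- factor(label_parameters(object, s$parameter),
                   levels = rev(label_parameters(object, s$parameter)))
  ggplot2::ggplot(s, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       yend = .data$term), linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower50, xend = .data$upper50,
                                       yend = .data$term), linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median), size = 2) +
    ggplot2::labs(x = "standardized coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pop_fit
#' @method autoplot ratio_fit
#' @export
autoplot.ratio_fit <- autoplot.pop_fit

#' Posterior predictive discrepancy plot
#'
#' Replicated-vs-observed discrepancies; points above the identity line drive
#' the Bayesian p-value toward 1.
#'
#' @param object A `ppc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppc_result
#' @export
autoplot.ppc_result <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$d_obs, y = .data$d_rep)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed discrepancy", y = "replicated discrepancy",
                  subtitle = sprintf("%s: Bayesian p = %.2f", object$discrepancy,
                                     object$bayesian_p)) +
    ggplot2::theme_minimal()
}

#' Detection-fraction plot of a power experiment
#'
#' @param object A `power_report`.
#' @param terms Terms to display (default: those with nonzero true effects,
#'   or all if none).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_report
#' @export
autoplot.power_report <- function(object, terms = NULL, ...) {
  if (is.null(terms)) {
    nz <- names(object$effects)[object$effects != 0]
    terms <- if (length(nz) > 0) nz else names(object$effects)
  }
  d <- dplyr::filter(object$results, .data$term %in% terms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$fraction,
                                  colour = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = sprintf("%d%% HPD excludes zero", round(100 * object$mass)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Latent abundance trajectory plot
#'
#' Posterior median and HPD ribbon of total latent abundance for one district,
#' with the observed survey totals overlaid.
#'
#' @param fit A `pop_fit` with latent monitors.
#' @param district District identifier.
#' @param mass HPD mass for the ribbon.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(fit, district, mass = 0.9) {
  traj <- latent_trajectory(fit, district, mass)
  obs <- dplyr::filter(fit$surveys, .data$district == !!district,
                       !is.na(.data$total_count))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$total_count),
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "total abundance", title = district) +
    ggplot2::theme_minimal()
}
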