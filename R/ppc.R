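#' Discrepancy measures for posterior predictive checks
#'
#' `discrepancy_ssq` is the omnibus sum of squared residuals
#' `sum((y - E)^2)`; `discrepancy_freeman_tukey` is the Freeman-Tukey
#' statistic `sum((sqrt(y) - sqrt(E))^2)`, the variance-stabilized residual for
#' counts; `discrepancy_calf_variance` is the sample variance (n - 1
#' denominator) of the classified calf counts, targeting the model's ability
#' to reproduce the large year-to-year spread in observed calves.
#'
#' @param values Observed or replicated values.
#' @param expected Expected values given the parameters, same length.
#' @return The scalar discrepancy.
#' @export
discrepancy_ssq <- function(values, expected) {
  if (length(values) != length(expected)) stop("length mismatch", call. = FALSE)
  sum((values - expected)^2)
}

#' @rdname discrepancy_ssq
#' @export
discrepancy_freeman_tukey <- function(values, expected) {
  if (length(values) != length(expected)) stop("length mismatch", call. = FALSE)
  if (any(values < 0)) stop("negative counts", call. = FALSE)
  sum((sqrt(values) - sqrt(expected))^2)
}

#' @rdname discrepancy_ssq
#' @param calf_counts Classified calf counts (at least two district-years).
#' @export
discrepancy_calf_variance <- function(calf_counts) {
  if (length(calf_counts) < 2) stop("need at least two classified district-years", call. = FALSE)
  stats::var(calf_counts)
}

bayes_p <- function(d_rep, d_obs) {
  mean(d_rep > d_obs) + 0.5 * mean(d_rep == d_obs)
}

#' Posterior predictive check
#'
#' For a thinned subset of posterior draws, one replicated dataset is
#' simulated from the fitted model's own observation process and the chosen
#' discrepancy is computed for the replicated and the observed data; the
#' one-sided Bayesian p-value is the fraction of draws where the replicated
#' discrepancy exceeds the observed one (ties counted half). Values near 0.5
#' indicate adequate fit; values near 0 or 1 flag misfit.
#'
#' For the population model the replicated totals are Poisson draws around
#' `N_total * exp(gamma)`; by default `gamma` is regenerated per replicate
#' (a new-survey prediction), since reusing the fitted observation effects
#' makes the total-count checks trivially well calibrated. Classified counts
#' are multinomial draws at the observed classification sizes. The age-ratio
#' model replicates ratios from its Gaussian likelihood and supports only the
#' sum-of-squares discrepancy.
#'
#' @param fit A `pop_fit` (with latent and gamma monitors) or `ratio_fit`.
#' @param discrepancy One of `"ssq"`, `"freeman_tukey"`, `"calf_variance"`.
#' @param ndraws Number of posterior draws used (thinned evenly).
#' @param gamma_mode `"new"` regenerates the observation effects per
#'   replicate; `"fitted"` reuses the posterior draws of `gamma`.
#' @param seed Optional seed for the replication RNG.
#' @param data Optional survey tibble to use as the observed data in place of
#'   the one the model was fitted to; it must cover the same district-years.
#'   Useful for misfit injection: corrupting the observed data and rechecking
#'   the fitted model pushes the p-value toward 0 or 1.
#' @return A `ppc_result`: tibble of per-draw discrepancies plus the Bayesian
#'   p-value.
#' @export
posterior_predictive_check <- function(fit,
                                       discrepancy = c("freeman_tukey", "ssq",
                                                       "calf_variance"),
                                       ndraws = 1000, gamma_mode = c("new", "fitted"),
                                       seed = NULL, data = NULL) {
  discrepancy <- match.arg(discrepancy)
  gamma_mode <- match.arg(gamma_mode)
  if (inherits(fit, "ratio_fit") && discrepancy != "ssq") {
    stop("the age-ratio model supports only the ssq discrepancy", call. = FALSE)
  }
  if (!is.null(data)) {
    if (!inherits(fit, "pop_fit")) stop("data replacement needs a pop_fit", call. = FALSE)
    data <- validate_surveys(data)
    same <- nrow(data) == nrow(fit$surveys) &&
      all(dplyr::arrange(data[c("district", "year")], district, year) ==
            dplyr::arrange(fit$surveys[c("district", "year")], district, year))
    if (!same) stop("replacement data must cover the fitted district-years", call. = FALSE)
    fit$surveys <- data
  }
  runner <- function() {
    if (inherits(fit, "pop_fit")) ppc_population(fit, discrepancy, ndraws, gamma_mode)
    else if (inherits(fit, "ratio_fit")) ppc_ageratio(fit, ndraws)
    else stop("unsupported fit object", call. = FALSE)
  }
  tab <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  structure(list(discrepancy = discrepancy, draws = tab,
                 bayesian_p = bayes_p(tab$d_rep, tab$d_obs)),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("<ppc_result> ", x$discrepancy, ": Bayesian p = ",
      signif(x$bayesian_p, 3), " over ", nrow(x$draws), " draws\n", sep = "")
  invisible(x)
}

thin_index <- function(total, ndraws) {
  unique(round(seq(1, total, length.out = min(ndraws, total))))
}

ppc_population <- function(fit, discrepancy, ndraws, gamma_mode) {
  if (is.null(fit$obs_index)) stop("fit has no attached observations", call. = FALSE)
  m <- draws_matrix(fit)
  rows <- thin_index(nrow(m), ndraws)
  obs <- dplyr::filter(fit$surveys, !is.na(.data$total_count))
  tobs <- match(obs$year, fit$years)
  uobs <- match(obs$district, fit$districts)
  lat_cols <- function(stem) sprintf("%s[%d,%d]", stem, tobs, uobs)
  need <- c(lat_cols("Nc"), lat_cols("Naf"), lat_cols("Nam"))
  if (!all(need %in% colnames(m))) {
    stop("latent abundances were not monitored; refit with monitor = \"latent\"",
         call. = FALSE)
  }
  nc <- m[rows, lat_cols("Nc"), drop = FALSE]
  naf <- m[rows, lat_cols("Naf"), drop = FALSE]
  nam <- m[rows, lat_cols("Nam"), drop = FALSE]
  ntot <- nc + naf + nam
  sig <- m[rows, "sigma_count"]
  is_cls <- !is.na(obs$classified_total) & obs$classified_total > 0
  if (discrepancy == "calf_variance" && sum(is_cls) < 2) {
    stop("need at least two classified district-years", call. = FALSE)
  }
  if (gamma_mode == "fitted") {
    gcols <- sprintf("gam[%d]", seq_len(nrow(obs)))
    if (!all(gcols %in% colnames(m))) {
      stop("observation effects were not monitored; refit with monitor = \"gamma\"",
           call. = FALSE)
    }
    gmat <- m[rows, gcols, drop = FALSE]
  }
  n_i <- nrow(obs)
  out <- purrr::map_dfr(seq_along(rows), function(s) {
    g <- if (gamma_mode == "new") stats::rnorm(n_i, 0, sig[s]) else gmat[s, ]
    mu_rep <- ntot[s, ] * exp(g)
    expected <- if (gamma_mode == "new") ntot[s, ] * exp(sig[s]^2 / 2) else mu_rep
    y_rep <- stats::rpois(n_i, mu_rep)
    if (discrepancy == "ssq") {
      tibble::tibble(d_obs = discrepancy_ssq(obs$total_count, expected),
                     d_rep = discrepancy_ssq(y_rep, expected))
    } else if (discrepancy == "freeman_tukey") {
      tibble::tibble(d_obs = discrepancy_freeman_tukey(obs$total_count, expected),
                     d_rep = discrepancy_freeman_tukey(y_rep, expected))
    } else {
      shares <- rbind(nc[s, ], naf[s, ], nam[s, ])
      calves_rep <- vapply(which(is_cls), function(i) {
        pr <- shares[, i] / sum(shares[, i])
        stats::rmultinom(1, obs$classified_total[i], pr)[1, 1]
      }, numeric(1))
      tibble::tibble(d_obs = discrepancy_calf_variance(obs$calves[is_cls]),
                     d_rep = discrepancy_calf_variance(calves_rep))
    }
  })
  out
}

ppc_ageratio <- function(fit, ndraws) {
  m <- draws_matrix(fit)
  rows <- thin_index(nrow(m), ndraws)
  data <- fit$data
  x <- as.matrix(data[, fit$terms, drop = FALSE])
  ti <- match(data$year, fit$years)
  bcols <- sprintf("beta[%d]", seq_along(fit$terms))
  zcols <- sprintf("zeta[%d]", seq_along(fit$years))
  purrr::map_dfr(rows, function(s) {
    mu <- m[s, "alpha"] + m[s, zcols][ti] + drop(x %*% m[s, bcols])
    y_rep <- stats::rnorm(nrow(data), mu, m[s, "sigma_ratio"])
    tibble::tibble(d_obs = discrepancy_ssq(data$age_ratio, mu),
                   d_rep = discrepancy_ssq(y_rep, mu))
  })
}
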