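#' Per capita recruitment rate on the probability scale
#'
#' Recruitment of ~10-month-old calves per adult female alive the previous
#' spring, linked to covariates through a logit link:
#' `tau = plogis(alpha + zeta_t + x . beta)`. The logit link constrains the
#' population-level offspring production rate to (0, 1).
#'
#' @param alpha Logit-scale intercept (mean recruitment in an average year at
#'   average covariate values).
#' @param zeta_t Year random effect (0 for an average year).
#' @param x_row Standardized covariate/design row.
#' @param beta Regression coefficients, same length as `x_row`.
#' @return Recruitment rate in (0, 1).
#' @export
recruitment_rate <- function(alpha, zeta_t = 0, x_row = numeric(0), beta = numeric(0)) {
  if (length(x_row) != length(beta)) {
    stop("x_row and beta lengths differ (", length(x_row), " vs ", length(beta), ")",
         call. = FALSE)
  }
  stats::plogis(alpha + zeta_t + sum(x_row * beta))
}

#' Expected stage-structured transition
#'
#' The expected numbers of calves, adult females and adult males next spring,
#' given this spring's abundances, the intervening harvest (treated as removed
#' immediately after the survey), apparent adult survival `phi_a`, the female
#' fraction of calves `delta`, and recruitment `tau`:
#' `(tau * N_af - h_c, phi_a * (delta * N_c + N_af - h_af),
#'   phi_a * ((1 - delta) * N_c + N_am - h_am))`.
#' Values are returned unguarded; the process density applies the positivity
#' guard.
#'
#' @param n_calves,n_adult_females,n_adult_males Current abundances.
#' @param h_calves,h_adult_females,h_adult_males Harvest subtracted this cycle.
#' @param phi_a Apparent adult survival in (0, 1).
#' @param delta Female fraction of calves (0.5 by assumption).
#' @param tau Per capita recruitment rate.
#' @return A named numeric vector `(calves, adult_females, adult_males)`.
#' @export
expected_transition <- function(n_calves, n_adult_females, n_adult_males,
                                h_calves, h_adult_females, h_adult_males,
                                phi_a, tau, delta = 0.5) {
  c(calves = tau * n_adult_females - h_calves,
    adult_females = phi_a * (delta * n_calves + n_adult_females - h_adult_females),
    adult_males = phi_a * ((1 - delta) * n_calves + n_adult_males - h_adult_males))
}

pois_guard <- function(mu, eps = 1e-3) {
  out <- pmax(mu, eps)
  names(out) <- names(mu)
  out
}

latent_lookup <- function(latents) {
  stats::setNames(seq_len(nrow(latents)), paste0(latents$district, ":", latents$year))
}

#' Log density of the latent population process
#'
#' Sums, over districts, the initial-state log prior (continuous uniform on
#' `[h_{2}, upper]` per age/sex class, left-truncated at the class's harvest in
#' the following year) and the Poisson transition terms for later years, whose
#' means are the expected transitions guarded below by `eps` (the expected calf
#' count can otherwise go non-positive under heavy calf harvest).
#'
#' @param latents Tibble `district`, `year`, `n_calves`, `n_adult_females`,
#'   `n_adult_males` covering every year of the window contiguously.
#' @param harvest Harvest tibble for the same district-years.
#' @param params List with `alpha`, `beta`, `zeta` (named by year), `phi_a`,
#'   `delta`.
#' @param design Design-matrix tibble from [build_design_matrix()] for years
#'   after the first.
#' @param upper Upper bound of the initial-state prior.
#' @param eps Positivity guard on Poisson means.
#' @return Log density (may be `-Inf` when a truncation bound is violated).
#' @export
log_process_density <- function(latents, harvest, params, design,
                                upper = 10000, eps = 1e-3) {
  hkey <- stats::setNames(seq_len(nrow(harvest)), paste0(harvest$district, ":", harvest$year))
  dkey <- stats::setNames(seq_len(nrow(design)), paste0(design$district, ":", design$year))
  terms <- setdiff(names(design), c("district", "year"))
  beta <- params$beta
  if (length(terms) != length(beta)) stop("beta length does not match design", call. = FALSE)
  total <- 0
  for (d in unique(latents$district)) {
    lat <- dplyr::arrange(dplyr::filter(latents, .data$district == d), .data$year)
    yrs <- lat$year
    if (any(diff(yrs) != 1)) stop("latent years must be contiguous for district ", d, call. = FALSE)
    h2 <- harvest[hkey[[paste0(d, ":", yrs[2])]], ]
    n1 <- c(lat$n_calves[1], lat$n_adult_females[1], lat$n_adult_males[1])
    lo <- c(h2$h_calves, h2$h_adult_females, h2$h_adult_males)
    if (any(n1 < lo) || any(n1 > upper)) return(-Inf)
    total <- total + sum(-log(upper - lo))
    for (i in 2:length(yrs)) {
      hrow <- harvest[hkey[[paste0(d, ":", yrs[i])]], ]
      xrow <- as.numeric(design[dkey[[paste0(d, ":", yrs[i])]], terms])
      tau <- recruitment_rate(params$alpha, params$zeta[[as.character(yrs[i])]], xrow, beta)
      mu <- expected_transition(
        lat$n_calves[i - 1], lat$n_adult_females[i - 1], lat$n_adult_males[i - 1],
        hrow$h_calves, hrow$h_adult_females, hrow$h_adult_males,
        phi_a = params$phi_a, tau = tau, delta = params$delta)
      mu <- pois_guard(mu, eps)
      total <- total +
        stats::dpois(lat$n_calves[i], mu[["calves"]], log = TRUE) +
        stats::dpois(lat$n_adult_females[i], mu[["adult_females"]], log = TRUE) +
        stats::dpois(lat$n_adult_males[i], mu[["adult_males"]], log = TRUE)
    }
  }
  total
}

#' Log density of the two-layer observation process
#'
#' For every surveyed district-year: a Poisson term for the total count with
#' mean `N_total * exp(gamma)` (log-normal observation-level random effect
#' `gamma ~ Normal(0, sigma_count^2)` absorbing overdispersion), plus, when a
#' classification was recorded, a multinomial term connecting the classified
#' calves/adult females/adult males to their shares of the latent population.
#' Classification-missing years contribute only the Poisson and gamma terms.
#'
#' @param surveys Survey tibble (validated).
#' @param latents Latent-abundance tibble as in [log_process_density()].
#' @param params List with `gamma` (named `"district:year"`), `sigma_count`.
#' @return Log density.
#' @export
log_observation_density <- function(surveys, latents, params) {
  lkey <- latent_lookup(latents)
  total <- 0
  for (i in seq_len(nrow(surveys))) {
    row <- surveys[i, ]
    if (is.na(row$total_count)) next
    key <- paste0(row$district, ":", row$year)
    lat <- latents[lkey[[key]], ]
    ntot <- lat$n_calves + lat$n_adult_females + lat$n_adult_males
    g <- params$gamma[[key]]
    total <- total +
      stats::dpois(row$total_count, ntot * exp(g), log = TRUE) +
      stats::dnorm(g, 0, params$sigma_count, log = TRUE)
    if (!is.na(row$classified_total) && row$classified_total > 0) {
      pr <- c(lat$n_calves, lat$n_adult_females, lat$n_adult_males) / ntot
      total <- total + stats::dmultinom(
        c(row$calves, row$adult_females, row$adult_males), prob = pr, log = TRUE)
    }
  }
  total
}

#' Log prior of the population-model parameters
#'
#' Beta(1, 1) on apparent adult survival; Normal(0, 1) on the logit-scale
#' intercept; a common hierarchical shrinkage prior Normal(0, sigma_beta^2) on
#' all regression coefficients; Normal(0, sigma_zeta^2) on the year effects;
#' and Uniform(0, 10) on each standard deviation (`sigma_zeta`, `sigma_beta`,
#' `sigma_count`).
#'
#' @param params Parameter list (`alpha`, `beta`, `zeta`, `phi_a`,
#'   `sigma_zeta`, `sigma_beta`, `sigma_count`).
#' @param sigma_upper Upper bound of the uniform priors on standard deviations.
#' @return Log prior density (`-Inf` out of support).
#' @export
log_prior <- function(params, sigma_upper = 10) {
  if (params$phi_a <= 0 || params$phi_a >= 1) return(-Inf)
  sig <- c(params$sigma_zeta, params$sigma_beta, params$sigma_count)
  if (any(sig <= 0) || any(sig >= sigma_upper)) return(-Inf)
  stats::dbeta(params$phi_a, 1, 1, log = TRUE) +
    stats::dnorm(params$alpha, 0, 1, log = TRUE) +
    sum(stats::dnorm(params$beta, 0, params$sigma_beta, log = TRUE)) +
    sum(stats::dnorm(params$zeta, 0, params$sigma_zeta, log = TRUE)) +
    3 * stats::dunif(sig[1], 0, sigma_upper, log = TRUE)
}

#' Joint log density of the state-space model
#'
#' `log_prior + log_process_density + log_observation_density`; the target of
#' posterior sampling.
#'
#' @inheritParams log_process_density
#' @inheritParams log_observation_density
#' @return Log joint density.
#' @export
joint_log_density <- function(surveys, latents, harvest, params, design,
                              upper = 10000, eps = 1e-3, sigma_upper = 10) {
  log_prior(params, sigma_upper = sigma_upper) +
    log_process_density(latents, harvest, params, design, upper = upper, eps = eps) +
    log_observation_density(surveys, latents, params)
}

# ---- age-ratio comparator --------------------------------------------------

#' Expected calves:100-females ratio
#'
#' The comparator linear model's mean: identity link with the same covariate
#' structure as the recruitment model plus an adult-female-harvest term,
#' `mu = alpha + zeta_t + x . beta + beta_harvest * h_af` with `h_af`
#' standardized like every other covariate.
#'
#' @param alpha Identity-scale intercept.
#' @param zeta_t Year random effect.
#' @param x_row,beta Standardized covariates and coefficients.
#' @param beta_harvest Coefficient of standardized adult-female harvest.
#' @param h_af Standardized adult-female harvest.
#' @return Expected ratio (unconstrained; may be negative).
#' @export
expected_ratio <- function(alpha, zeta_t = 0, x_row = numeric(0), beta = numeric(0),
                           beta_harvest = 0, h_af = 0) {
  if (length(x_row) != length(beta)) {
    stop("x_row and beta lengths differ (", length(x_row), " vs ", length(beta), ")",
         call. = FALSE)
  }
  alpha + zeta_t + sum(x_row * beta) + beta_harvest * h_af
}

#' Log density (likelihood + priors) of the age-ratio model
#'
#' Gaussian likelihood of the observed ratios around [expected_ratio()] with
#' residual variance `sigma_ageratio^2`, plus priors: a diffuse Normal(0,
#' 100^2) on the intercept, the common shrinkage prior Normal(0, sigma_beta^2)
#' on all coefficients including the harvest term, Normal(0, sigma_zeta^2) on
#' year effects, Uniform(0, 10) on `sigma_zeta` and `sigma_beta`, and
#' Uniform(0, 20) on `sigma_ageratio`.
#'
#' @param data Tibble with columns `age_ratio`, `year`, the design-term
#'   columns, and `h_af` (standardized adult-female harvest).
#' @param params List with `alpha`, `beta`, `beta_harvest`, `zeta` (named by
#'   year), `sigma_zeta`, `sigma_beta`, `sigma_ageratio`.
#' @param terms Character vector naming the design columns in `data`.
#' @param alpha_sd Prior standard deviation of the intercept.
#' @param sigma_upper,sigma_ageratio_upper Uniform prior bounds.
#' @return Log density (`-Inf` out of support).
#' @export
log_density_ageratio <- function(data, params, terms,
                                 alpha_sd = 100, sigma_upper = 10,
                                 sigma_ageratio_upper = 20) {
  if (params$sigma_zeta <= 0 || params$sigma_zeta >= sigma_upper ||
      params$sigma_beta <= 0 || params$sigma_beta >= sigma_upper ||
      params$sigma_ageratio <= 0 || params$sigma_ageratio >= sigma_ageratio_upper) {
    return(-Inf)
  }
  x <- as.matrix(data[, terms, drop = FALSE])
  mu <- params$alpha + params$zeta[as.character(data$year)] +
    drop(x %*% params$beta) + params$beta_harvest * data$h_af
  sum(stats::dnorm(data$age_ratio, mu, params$sigma_ageratio, log = TRUE)) +
    stats::dnorm(params$alpha, 0, alpha_sd, log = TRUE) +
    sum(stats::dnorm(c(params$beta, params$beta_harvest), 0, params$sigma_beta, log = TRUE)) +
    sum(stats::dnorm(params$zeta, 0, params$sigma_zeta, log = TRUE)) +
    stats::dunif(params$sigma_zeta, 0, sigma_upper, log = TRUE) +
    stats::dunif(params$sigma_beta, 0, sigma_upper, log = TRUE) +
    stats::dunif(params$sigma_ageratio, 0, sigma_ageratio_upper, log = TRUE)
}
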