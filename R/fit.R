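#' MCMC protocol
#'
#' Chain-length bookkeeping for the samplers. The kept draw count per chain is
#' `(iterations - burnin) / thin`; the reference protocols are 100,000
#' iterations, 20,000 burn-in, thin 5, 4 chains for the population model
#' (16,000 kept per chain, 64,000 total) and 20,000 iterations, 5,000 burn-in,
#' thin 1, 4 chains for the age-ratio model (60,000 total). Reduced protocols
#' are passed for simulation experiments.
#'
#' @param iterations Total MCMC iterations per chain (after adaptation).
#' @param burnin Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th sample.
#' @param chains Number of chains.
#' @param adapt Extra sampler-adaptation iterations before the run.
#' @return A list of class `mcmc_protocol` with `kept_per_chain` and
#'   `total_kept`.
#' @export
mcmc_protocol <- function(iterations = 100000, burnin = 20000, thin = 5,
                          chains = 4, adapt = 500) {
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1, chains >= 1)
  if ((iterations - burnin) %% thin != 0) {
    stop("(iterations - burnin) must be divisible by thin", call. = FALSE)
  }
  kept <- (iterations - burnin) %/% thin
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 chains = chains, adapt = adapt,
                 kept_per_chain = kept, total_kept = kept * chains),
            class = "mcmc_protocol")
}

#' @rdname mcmc_protocol
#' @export
ageratio_protocol <- function(iterations = 20000, burnin = 5000, thin = 1,
                              chains = 4, adapt = 500) {
  mcmc_protocol(iterations, burnin, thin, chains, adapt)
}

#' @export
print.mcmc_protocol <- function(x, ...) {
  cat("<mcmc_protocol> ", x$chains, " chains x ", x$iterations, " iterations (",
      x$burnin, " burn-in, thin ", x$thin, ") -> ", x$kept_per_chain,
      " kept per chain, ", x$total_kept, " total\n", sep = "")
  invisible(x)
}

population_model_string <- function(has_obs, has_cls) {
  paste0("
model {
  phi_a ~ dbeta(1, 1)
  alpha ~ dnorm(0, 1)
  sigma_zeta ~ dunif(0, sigma_upper)
  tau_zeta <- pow(sigma_zeta, -2)
  sigma_beta ~ dunif(0, sigma_upper)
  tau_beta <- pow(sigma_beta, -2)
  sigma_count ~ dunif(0, sigma_upper)
  tau_count <- pow(sigma_count, -2)
  for (j in 1:J) { beta[j] ~ dnorm(0, tau_beta) }
  for (t in 2:T) { zeta[t] ~ dnorm(0, tau_zeta) }
  for (u in 1:U) {
    Nc[1, u] ~ dunif(hc[2, u], upper)
    Naf[1, u] ~ dunif(haf[2, u], upper)
    Nam[1, u] ~ dunif(ham[2, u], upper)
    for (t in 2:T) {
      logit(tau_rec[t, u]) <- alpha + zeta[t] + inprod(x[t, u, ], beta)
      mu_c[t, u] <- max(eps, tau_rec[t, u] * Naf[t - 1, u] - hc[t, u])
      mu_af[t, u] <- max(eps, phi_a * (delta * Nc[t - 1, u] + Naf[t - 1, u] - haf[t, u]))
      mu_am[t, u] <- max(eps, phi_a * ((1 - delta) * Nc[t - 1, u] + Nam[t - 1, u] - ham[t, u]))
      Nc[t, u] ~ dpois(mu_c[t, u])
      Naf[t, u] ~ dpois(mu_af[t, u])
      Nam[t, u] ~ dpois(mu_am[t, u])
    }
  }
", if (has_obs) "
  for (i in 1:Nobs) {
    gam[i] ~ dnorm(0, tau_count)
    Ntot[i] <- Nc[tobs[i], uobs[i]] + Naf[tobs[i], uobs[i]] + Nam[tobs[i], uobs[i]]
    y_total[i] ~ dpois(Ntot[i] * exp(gam[i]))
  }
" else "", if (has_cls) "
  for (k in 1:Ncls) {
    NtotC[k] <- Nc[tcls[k], ucls[k]] + Naf[tcls[k], ucls[k]] + Nam[tcls[k], ucls[k]]
    p_cls[k, 1] <- Nc[tcls[k], ucls[k]] / NtotC[k]
    p_cls[k, 2] <- Naf[tcls[k], ucls[k]] / NtotC[k]
    p_cls[k, 3] <- Nam[tcls[k], ucls[k]] / NtotC[k]
    y_cls[k, 1:3] ~ dmulti(p_cls[k, 1:3], n_cls[k])
  }
" else "", "
}
")
}

# crude latent-trajectory starting values: observed totals apportioned by
# observed class shares, linearly interpolated through unobserved years
latent_inits <- function(surveys, districts, years, harvest, upper) {
  U <- length(districts); T <- length(years)
  shares_pool <- c(calves = 0.2, adult_females = 0.55, adult_males = 0.25)
  mk <- function() matrix(NA_real_, T, U, dimnames = list(years, districts))
  Nc <- mk(); Naf <- mk(); Nam <- mk()
  for (u in seq_along(districts)) {
    sub <- dplyr::filter(surveys, .data$district == districts[u], !is.na(.data$total_count))
    ti <- match(sub$year, years)
    est <- matrix(NA_real_, T, 3)
    if (nrow(sub) > 0) {
      for (r in seq_len(nrow(sub))) {
        tot <- sub$total_count[r]
        if (!is.na(sub$classified_total[r]) && sub$classified_total[r] > 0) {
          sh <- c(sub$calves[r], sub$adult_females[r], sub$adult_males[r]) /
            sub$classified_total[r]
        } else {
          sh <- shares_pool
        }
        est[ti[r], ] <- tot * sh
      }
    } else {
      est[1, ] <- 1000 * shares_pool
    }
    for (k in 1:3) {
      known <- which(!is.na(est[, k]))
      est[, k] <- if (length(known) < 2) {
        rep(est[known[1], k], T)
      } else {
        stats::approx(known, est[known, k], xout = seq_len(T), rule = 2)$y
      }
    }
    Nc[, u] <- est[, 1]; Naf[, u] <- est[, 2]; Nam[, u] <- est[, 3]
  }
  clamp <- function(m, lower_row1) {
    m <- pmin(pmax(round(m), 1), upper - 1)
    # year-1 nodes are continuous uniforms truncated at next year's harvest
    m[1, ] <- pmax(m[1, ], lower_row1 + 1)
    m
  }
  hw <- function(col) {
    vapply(districts, function(d) {
      harvest[[col]][harvest$district == d & harvest$year == years[2]]
    }, numeric(1))
  }
  list(Nc = clamp(Nc, hw("h_calves")),
       Naf = clamp(Naf, hw("h_adult_females")),
       Nam = clamp(Nam, hw("h_adult_males")))
}

#' Fit the state-space population model
#'
#' Posterior sampling of the joint density over latent stage-structured
#' abundances, vital-rate parameters and observation parameters, given spring
#' survey counts (with optional classification), the continuous harvest
#' series, and standardized covariates entering recruitment through a logit
#' link. Sampling is Gibbs over the discrete latent states via JAGS; the model
#' statement mirrors [joint_log_density()] exactly.
#'
#' Latent dynamics run through every calendar year of the harvest series;
#' observation terms attach only to surveyed district-years, and
#' classification-missing surveys contribute only their total-count term.
#'
#' @param surveys Survey tibble (may have zero rows: the posterior is then the
#'   prior-process distribution).
#' @param harvest Harvest tibble covering every district-year.
#' @param covariates Covariate tibble (standardized internally if raw).
#' @param design Design terms (character) or a [design_spec()].
#' @param protocol An [mcmc_protocol()].
#' @param seed Integer seed; chains receive distinct substreams.
#' @param monitor Node groups to record: hyperparameters and coefficients are
#'   always kept; add `"latent"` for abundances and `"gamma"` for the
#'   observation effects (both needed for posterior-predictive checks and
#'   growth rates).
#' @param eps Positivity guard on Poisson means.
#' @param upper Upper bound of the initial-abundance prior.
#' @param sigma_upper Upper bound of the uniform priors on standard deviations.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `pop_fit` with the coda draws, index maps and
#'   inputs. Methods: [tidy()][tidy.pop_fit], [glance()][glance.pop_fit],
#'   [autoplot()][autoplot.pop_fit], [derive_lambda()],
#'   [predict_recruitment()], [posterior_predictive_check()],
#'   [convergence_report()].
#' @export
fit_population <- function(surveys, harvest, covariates,
                           design = design_terms_population(),
                           protocol = mcmc_protocol(), seed = 1,
                           monitor = c("latent", "gamma"),
                           eps = 1e-3, upper = 10000, sigma_upper = 10,
                           quiet = TRUE) {
  harvest <- validate_harvest(harvest)
  if (nrow(surveys) > 0) surveys <- validate_surveys(surveys)
  districts <- sort(unique(harvest$district))
  years <- sort(unique(harvest$year))
  T <- length(years); U <- length(districts)
  if (nrow(surveys) > 0) {
    bad <- dplyr::anti_join(surveys[c("district", "year")], harvest[c("district", "year")],
                            by = c("district", "year"))
    if (nrow(bad) > 0) {
      stop("survey district-years outside the harvest window: ",
           paste(paste0(bad$district, ":", bad$year), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(attr(covariates, "scaling"))) covariates <- standardize_covariates(covariates)
  xmat <- build_design_matrix(covariates, design, years = years[-1])
  terms <- setdiff(names(xmat), c("district", "year"))
  J <- length(terms)
  x <- array(0, dim = c(T, U, J))
  ti <- match(xmat$year, years); ui <- match(xmat$district, districts)
  for (j in seq_len(J)) x[cbind(ti, ui, j)] <- xmat[[terms[j]]]

  shape_h <- function(col) {
    m <- matrix(0, T, U)
    m[cbind(match(harvest$year, years), match(harvest$district, districts))] <- harvest[[col]]
    m
  }
  dat <- list(U = U, T = T, J = J, x = x,
              hc = shape_h("h_calves"), haf = shape_h("h_adult_females"),
              ham = shape_h("h_adult_males"),
              eps = eps, delta = 0.5, upper = upper, sigma_upper = sigma_upper)

  obs <- if (nrow(surveys) > 0) dplyr::filter(surveys, !is.na(.data$total_count)) else surveys
  has_obs <- nrow(obs) > 0
  if (has_obs) {
    dat$Nobs <- nrow(obs)
    dat$tobs <- match(obs$year, years)
    dat$uobs <- match(obs$district, districts)
    dat$y_total <- obs$total_count
  }
  cls <- if (has_obs) {
    dplyr::filter(obs, !is.na(.data$classified_total), .data$classified_total > 0)
  } else {
    obs
  }
  has_cls <- has_obs && nrow(cls) > 0
  if (has_cls) {
    dat$Ncls <- nrow(cls)
    dat$tcls <- match(cls$year, years)
    dat$ucls <- match(cls$district, districts)
    dat$y_cls <- cbind(cls$calves, cls$adult_females, cls$adult_males)
    dat$n_cls <- cls$classified_total
  }

  lat0 <- latent_inits(if (has_obs) obs else obs[0, ], districts, years, harvest, upper)
  alpha0 <- if (has_cls) {
    stats::qlogis(min(0.6, max(0.05, sum(cls$calves) / max(1, sum(cls$adult_females)))))
  } else {
    0
  }
  inits <- lapply(seq_len(protocol$chains), function(chain) {
    list(Nc = lat0$Nc, Naf = lat0$Naf, Nam = lat0$Nam,
         phi_a = 0.8, alpha = alpha0 + 0.05 * (chain - 1),
         sigma_zeta = 0.5, sigma_beta = 0.5, sigma_count = 0.2,
         beta = rep(0, J),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 1000L + chain)
  })

  monitors <- c("phi_a", "alpha", "beta", "zeta",
                "sigma_zeta", "sigma_beta", "sigma_count")
  if (has_obs && "gamma" %in% monitor) monitors <- c(monitors, "gam")
  if ("latent" %in% monitor) monitors <- c(monitors, "Nc", "Naf", "Nam")

  t0 <- Sys.time()
  model <- rjags::jags.model(
    textConnection(population_model_string(has_obs, has_cls)),
    data = dat, inits = inits, n.chains = protocol$chains,
    n.adapt = protocol$adapt, quiet = quiet)
  if (protocol$burnin > 0) {
    update(model, protocol$burnin, progress.bar = if (quiet) "none" else "text")
  }
  draws <- rjags::coda.samples(model, variable.names = monitors,
                               n.iter = protocol$iterations - protocol$burnin,
                               thin = protocol$thin,
                               progress.bar = if (quiet) "none" else "text")
  structure(list(
    draws = draws, districts = districts, years = years, terms = terms,
    obs_index = if (has_obs) obs[c("district", "year")] else NULL,
    cls_index = if (has_cls) cls[c("district", "year")] else NULL,
    surveys = surveys, harvest = harvest, covariates = covariates,
    protocol = protocol, seed = seed, eps = eps, upper = upper,
    sigma_upper = sigma_upper,
    runtime = as.numeric(Sys.time() - t0, units = "secs")
  ), class = "pop_fit")
}

#' @export
print.pop_fit <- function(x, ...) {
  cat("<pop_fit> ", length(x$districts), " districts x ", length(x$years),
      " years, ", if (is.null(x$obs_index)) 0 else nrow(x$obs_index),
      " surveyed district-years\n", sep = "")
  print(x$protocol)
  cat("  sampled in ", round(x$runtime, 1), " s\n", sep = "")
  invisible(x)
}

ageratio_model_string <- "
model {
  alpha ~ dnorm(0, pow(alpha_sd, -2))
  sigma_zeta ~ dunif(0, sigma_upper)
  tau_zeta <- pow(sigma_zeta, -2)
  sigma_beta ~ dunif(0, sigma_upper)
  tau_beta <- pow(sigma_beta, -2)
  sigma_ratio ~ dunif(0, sigma_ratio_upper)
  tau_ratio <- pow(sigma_ratio, -2)
  for (j in 1:J) { beta[j] ~ dnorm(0, tau_beta) }
  for (t in 1:T) { zeta[t] ~ dnorm(0, tau_zeta) }
  for (i in 1:N) {
    mu[i] <- alpha + zeta[tobs[i]] + inprod(x[i, ], beta)
    y[i] ~ dnorm(mu[i], tau_ratio)
  }
}
"

#' Fit the Gaussian age-ratio comparator model
#'
#' The traditional analysis: observed calves:100-females ratios regressed on
#' the same standardized covariates (plus standardized adult-female harvest)
#' with year random effects, an identity link, and the common shrinkage prior
#' on all coefficients. District-years without a classification are dropped
#' (with a message), as are first-window years whose lagged covariates do not
#' exist.
#'
#' @inheritParams fit_population
#' @param design Design terms including the `af_harvest` term.
#' @param alpha_sd Prior standard deviation of the (identity-scale) intercept.
#' @param sigma_ratio_upper Upper bound of the uniform prior on the residual
#'   standard deviation.
#' @return An object of class `ratio_fit`.
#' @export
fit_age_ratio <- function(surveys, harvest, covariates,
                          design = design_terms_ageratio(),
                          protocol = ageratio_protocol(), seed = 1,
                          alpha_sd = 100, sigma_upper = 10,
                          sigma_ratio_upper = 20, quiet = TRUE) {
  surveys <- validate_surveys(surveys)
  harvest <- validate_harvest(harvest)
  years <- sort(unique(harvest$year))
  covariates <- if (is.null(attr(covariates, "scaling"))) covariates else
    unstandardize_covariates(covariates)
  aug <- dplyr::left_join(
    covariates,
    dplyr::select(harvest, dplyr::all_of(c("district", "year", "h_adult_females"))),
    by = c("district", "year")) |>
    dplyr::rename(af_harvest = "h_adult_females")
  aug <- standardize_covariates(aug)
  xmat <- build_design_matrix(aug, design, years = years[-1])
  terms <- setdiff(names(xmat), c("district", "year"))
  data <- age_ratio_table(surveys)
  n_first <- sum(data$year == years[1])
  if (n_first > 0) {
    message("dropping ", n_first, " first-year ratio record(s) without lagged covariates")
  }
  n_nocls <- sum(is.na(surveys$classified_total) | is.na(observed_age_ratio(
    surveys$calves, surveys$adult_females)))
  if (n_nocls > 0) message("dropping ", n_nocls, " record(s) without a usable classification")
  data <- dplyr::inner_join(data, xmat, by = c("district", "year"))
  if (nrow(data) == 0) stop("no usable age-ratio records", call. = FALSE)
  yrs_used <- sort(unique(data$year))
  dat <- list(N = nrow(data), J = length(terms), T = length(yrs_used),
              y = data$age_ratio, tobs = match(data$year, yrs_used),
              x = as.matrix(data[, terms, drop = FALSE]),
              alpha_sd = alpha_sd, sigma_upper = sigma_upper,
              sigma_ratio_upper = sigma_ratio_upper)
  inits <- lapply(seq_len(protocol$chains), function(chain) {
    list(alpha = mean(data$age_ratio) + 2 * (chain - 1), beta = rep(0, length(terms)),
         sigma_zeta = 1, sigma_beta = 1, sigma_ratio = stats::sd(data$age_ratio),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 1000L + chain)
  })
  t0 <- Sys.time()
  model <- rjags::jags.model(textConnection(ageratio_model_string), data = dat,
                             inits = inits, n.chains = protocol$chains,
                             n.adapt = protocol$adapt, quiet = quiet)
  if (protocol$burnin > 0) {
    update(model, protocol$burnin, progress.bar = if (quiet) "none" else "text")
  }
  draws <- rjags::coda.samples(
    model, variable.names = c("alpha", "beta", "zeta", "sigma_zeta", "sigma_beta",
                              "sigma_ratio"),
    n.iter = protocol$iterations - protocol$burnin, thin = protocol$thin,
    progress.bar = if (quiet) "none" else "text")
  structure(list(
    draws = draws, terms = terms, years = yrs_used, data = data,
    protocol = protocol, seed = seed,
    runtime = as.numeric(Sys.time() - t0, units = "secs")
  ), class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat("<ratio_fit> ", nrow(x$data), " age-ratio records, ",
      length(x$terms), " covariate terms\n", sep = "")
  print(x$protocol)
  invisible(x)
}
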