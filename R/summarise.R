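#' Highest-posterior-density interval
#'
#' The shortest contiguous interval over the sorted samples that contains
#' `ceiling(mass * n)` of them; among tied shortest windows the one with the
#' lowest start is returned. For unimodal marginals this is the usual HPD
#' summary.
#'
#' @param samples Numeric vector, at least 10 values.
#' @param mass Interval mass in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.9) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  s <- sort(samples)
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1)
  widths <- s[starts + k - 1] - s[starts]
  i <- which.min(widths)  # which.min takes the first of ties = lowest start
  c(lower = s[i], upper = s[i + k - 1])
}

# draws helpers ---------------------------------------------------------------

draws_matrix <- function(fit) {
  m <- as.matrix(fit$draws)
  m
}

draws_of <- function(fit, name) {
  m <- draws_matrix(fit)
  if (!name %in% colnames(m)) stop("parameter not monitored: ", name, call. = FALSE)
  m[, name]
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the usual between/within variance ratio is
#' computed over the resulting 2m sequences; values near 1 indicate the chains
#' agree.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return The split R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2
  pieces <- cbind(x[seq_len(half), , drop = FALSE],
                  x[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(pieces); nn <- nrow(pieces)
  mu <- colMeans(pieces)
  s2 <- apply(pieces, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence report
#'
#' Split R-hat and effective sample size for every monitored scalar. With a
#' single chain R-hat is unavailable (a warning is raised) and only ESS is
#' reported.
#'
#' @param fit A `pop_fit` or `ratio_fit`.
#' @param parameters Optional regular expression selecting parameters
#'   (defaults to the hyperparameters and coefficients, excluding the
#'   high-dimensional latent and observation-effect blocks).
#' @return A tibble with `parameter`, `rhat`, `ess`.
#' @export
convergence_report <- function(fit, parameters = "^(phi_a|alpha|beta|sigma|zeta)") {
  draws <- fit$draws
  keep <- grep(parameters, coda::varnames(draws), value = TRUE)
  if (length(keep) == 0) stop("no monitored parameters match", call. = FALSE)
  single <- coda::nchain(draws) < 2
  if (single) warning("single chain: split R-hat unavailable", call. = FALSE)
  ess <- coda::effectiveSize(draws[, keep, drop = FALSE])
  rhat <- vapply(keep, function(p) {
    if (single) return(NA_real_)
    split_rhat(sapply(draws, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  tibble::tibble(parameter = keep, rhat = unname(rhat), ess = unname(ess[keep]))
}

#' Posterior summaries (median + HPD intervals)
#'
#' @param fit A `pop_fit` or `ratio_fit`.
#' @param parameters Regular expression selecting monitored scalars.
#' @param mass HPD interval mass.
#' @param mass50 Also include the 50% HPD interval.
#' @return A tibble with `parameter`, `median`, `lower`, `upper` (and
#'   `lower50`/`upper50`).
#' @export
posterior_summary <- function(fit, parameters = "^(phi_a|alpha|beta|sigma|zeta)",
                              mass = 0.9, mass50 = TRUE) {
  m <- draws_matrix(fit)
  keep <- grep(parameters, colnames(m), value = TRUE)
  out <- purrr::map_dfr(keep, function(p) {
    v <- m[, p]
    h <- hpd_interval(v, mass)
    row <- tibble::tibble(parameter = p, median = stats::median(v),
                          lower = h[["lower"]], upper = h[["upper"]])
    if (mass50) {
      h5 <- hpd_interval(v, 0.5)
      row$lower50 <- h5[["lower"]]; row$upper50 <- h5[["upper"]]
    }
    row
  })
  out
}

latent_total_draws <- function(fit, district) {
  u <- match(district, fit$districts)
  if (is.na(u)) stop("unknown district: ", district, call. = FALSE)
  m <- draws_matrix(fit)
  cols <- sprintf("%s[%d,%d]", c("Nc", "Naf", "Nam"), 1, u)
  if (!all(cols %in% colnames(m))) {
    stop("latent abundances were not monitored; refit with monitor = \"latent\"",
         call. = FALSE)
  }
  sapply(seq_along(fit$years), function(t) {
    m[, sprintf("Nc[%d,%d]", t, u)] + m[, sprintf("Naf[%d,%d]", t, u)] +
      m[, sprintf("Nam[%d,%d]", t, u)]
  })
}

#' Posterior annual population growth rates
#'
#' Per draw, `lambda_t = N_total_t / N_total_{t-1}` from the latent abundance
#' draws of one district; draws with a zero denominator are dropped from that
#' year's summary.
#'
#' @param fit A `pop_fit` with latent monitors.
#' @param district District identifier (default: all districts).
#' @param mass HPD interval mass.
#' @return A tibble `district`, `year`, `median`, `lower`, `upper` where `year`
#'   is the later year of each ratio.
#' @export
derive_lambda <- function(fit, district = NULL, mass = 0.9) {
  districts <- district %||% fit$districts
  purrr::map_dfr(districts, function(d) {
    tot <- latent_total_draws(fit, d)
    purrr::map_dfr(seq_along(fit$years)[-1], function(t) {
      lam <- tot[, t] / tot[, t - 1]
      lam <- lam[is.finite(lam)]
      h <- hpd_interval(lam, mass)
      tibble::tibble(district = d, year = fit$years[t],
                     median = stats::median(lam),
                     lower = h[["lower"]], upper = h[["upper"]])
    })
  })
}

#' Posterior latent abundance trajectory
#'
#' @param fit A `pop_fit` with latent monitors.
#' @param district District identifier.
#' @param mass HPD interval mass.
#' @return A tibble `year`, `median`, `lower`, `upper` of total abundance.
#' @export
latent_trajectory <- function(fit, district, mass = 0.9) {
  tot <- latent_total_draws(fit, district)
  purrr::map_dfr(seq_along(fit$years), function(t) {
    h <- hpd_interval(tot[, t], mass)
    tibble::tibble(district = district, year = fit$years[t],
                   median = stats::median(tot[, t]),
                   lower = h[["lower"]], upper = h[["upper"]])
  })
}

#' Posterior predicted recruitment at a covariate profile
#'
#' Per draw, `plogis(alpha + x . beta)` (plus a freshly drawn year effect when
#' `year_effect = "marginal"`, for predicting a new year rather than an
#' average one). A zero profile gives the posterior of mean recruitment in an
#' average year; mild/severe winter contrasts are profiles at the 5th/95th
#' percentiles of standardized snow-water equivalent.
#'
#' @param fit A `pop_fit`.
#' @param profile Numeric profile over the design terms; either a full-length
#'   vector in term order or a named vector of nonzero entries (remaining
#'   terms held at 0, i.e. their average).
#' @param year_effect `"average"` (zeta = 0) or `"marginal"` (draw a new
#'   year's zeta per posterior draw).
#' @return A numeric vector of posterior draws of the recruitment rate.
#' @export
predict_recruitment <- function(fit, profile = NULL,
                                year_effect = c("average", "marginal")) {
  year_effect <- match.arg(year_effect)
  x <- expand_profile(profile, fit$terms)
  m <- draws_matrix(fit)
  eta <- m[, "alpha"]
  if (length(fit$terms) > 0) {
    bcols <- sprintf("beta[%d]", seq_along(fit$terms))
    eta <- eta + drop(m[, bcols, drop = FALSE] %*% x)
  }
  if (year_effect == "marginal") {
    eta <- eta + stats::rnorm(length(eta), 0, m[, "sigma_zeta"])
  }
  stats::plogis(eta)
}

expand_profile <- function(profile, terms) {
  if (is.null(profile)) return(rep(0, length(terms)))
  if (!is.null(names(profile))) {
    bad <- setdiff(names(profile), terms)
    if (length(bad) > 0) stop("unknown design terms in profile: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    x <- stats::setNames(rep(0, length(terms)), terms)
    x[names(profile)] <- profile
    return(unname(x))
  }
  if (length(profile) != length(terms)) {
    stop("profile length ", length(profile), " does not match the ",
         length(terms), "-term design", call. = FALSE)
  }
  profile
}

#' Posterior contrast between two covariate profiles
#'
#' The draw-wise difference in predicted recruitment between two profiles
#' (e.g. mild minus severe winter); identical profiles give a distribution
#' degenerate at zero.
#'
#' @inheritParams predict_recruitment
#' @param profile_a,profile_b Profiles as in [predict_recruitment()].
#' @return Posterior draws of `tau(profile_a) - tau(profile_b)`.
#' @export
recruitment_contrast <- function(fit, profile_a, profile_b,
                                 year_effect = "average") {
  predict_recruitment(fit, profile_a, year_effect) -
    predict_recruitment(fit, profile_b, year_effect)
}
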