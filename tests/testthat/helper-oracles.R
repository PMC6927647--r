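# Independent brute-force oracles: term-by-term density sums written directly
# from the model equations, deliberately not sharing code paths with the
# package implementation.

oracle_joint_log_density <- function(surveys, latents, harvest, params, design,
                                     upper = 10000, eps = 1e-3, sigma_upper = 10) {
  lp <- 0
  # priors, one term at a time
  if (params$phi_a <= 0 || params$phi_a >= 1) return(-Inf)
  for (s in c(params$sigma_zeta, params$sigma_beta, params$sigma_count)) {
    if (s <= 0 || s >= sigma_upper) return(-Inf)
    lp <- lp + log(1 / sigma_upper)
  }
  lp <- lp + dbeta(params$phi_a, 1, 1, log = TRUE)
  lp <- lp + dnorm(params$alpha, 0, 1, log = TRUE)
  for (b in params$beta) lp <- lp + dnorm(b, 0, params$sigma_beta, log = TRUE)
  for (z in params$zeta) lp <- lp + dnorm(z, 0, params$sigma_zeta, log = TRUE)
  # process, district by district
  get_lat <- function(d, y) latents[latents$district == d & latents$year == y, ]
  get_h <- function(d, y) harvest[harvest$district == d & harvest$year == y, ]
  get_x <- function(d, y) {
    row <- design[design$district == d & design$year == y, ]
    as.numeric(row[setdiff(names(row), c("district", "year"))])
  }
  for (d in unique(latents$district)) {
    yrs <- sort(latents$year[latents$district == d])
    l1 <- get_lat(d, yrs[1]); h2 <- get_h(d, yrs[2])
    for (pair in list(c(l1$n_calves, h2$h_calves),
                      c(l1$n_adult_females, h2$h_adult_females),
                      c(l1$n_adult_males, h2$h_adult_males))) {
      if (pair[1] < pair[2] || pair[1] > upper) return(-Inf)
      lp <- lp + dunif(pair[1], pair[2], upper, log = TRUE)
    }
    for (y in yrs[-1]) {
      prev <- get_lat(d, y - 1); cur <- get_lat(d, y); h <- get_h(d, y)
      tau <- 1 / (1 + exp(-(params$alpha + params$zeta[[as.character(y)]] +
                              sum(get_x(d, y) * params$beta))))
      lp <- lp + dpois(cur$n_calves,
                       max(eps, tau * prev$n_adult_females - h$h_calves), log = TRUE)
      lp <- lp + dpois(cur$n_adult_females,
                       max(eps, params$phi_a * (params$delta * prev$n_calves +
                                                  prev$n_adult_females - h$h_adult_females)),
                       log = TRUE)
      lp <- lp + dpois(cur$n_adult_males,
                       max(eps, params$phi_a * ((1 - params$delta) * prev$n_calves +
                                                  prev$n_adult_males - h$h_adult_males)),
                       log = TRUE)
    }
  }
  # observations, row by row
  for (i in seq_len(nrow(surveys))) {
    s <- surveys[i, ]
    if (is.na(s$total_count)) next
    lat <- get_lat(s$district, s$year)
    ntot <- lat$n_calves + lat$n_adult_females + lat$n_adult_males
    g <- params$gamma[[paste0(s$district, ":", s$year)]]
    lp <- lp + dpois(s$total_count, ntot * exp(g), log = TRUE)
    lp <- lp + dnorm(g, 0, params$sigma_count, log = TRUE)
    if (!is.na(s$calves) && (s$calves + s$adult_females + s$adult_males) > 0) {
      lp <- lp + dmultinom(c(s$calves, s$adult_females, s$adult_males),
                           prob = c(lat$n_calves, lat$n_adult_females,
                                    lat$n_adult_males) / ntot, log = TRUE)
    }
  }
  lp
}

oracle_ageratio_log_density <- function(data, params, terms, alpha_sd = 100,
                                        sigma_upper = 10, sigma_ageratio_upper = 20) {
  if (params$sigma_zeta <= 0 || params$sigma_zeta >= sigma_upper ||
      params$sigma_beta <= 0 || params$sigma_beta >= sigma_upper ||
      params$sigma_ageratio <= 0 || params$sigma_ageratio >= sigma_ageratio_upper) {
    return(-Inf)
  }
  lp <- dnorm(params$alpha, 0, alpha_sd, log = TRUE) +
    log(1 / sigma_upper) + log(1 / sigma_upper) + log(1 / sigma_ageratio_upper)
  for (b in c(params$beta, params$beta_harvest)) {
    lp <- lp + dnorm(b, 0, params$sigma_beta, log = TRUE)
  }
  for (z in params$zeta) lp <- lp + dnorm(z, 0, params$sigma_zeta, log = TRUE)
  for (i in seq_len(nrow(data))) {
    mu <- params$alpha + params$zeta[[as.character(data$year[i])]]
    for (j in seq_along(terms)) mu <- mu + data[[terms[j]]][i] * params$beta[j]
    mu <- mu + params$beta_harvest * data$h_af[i]
    lp <- lp + dnorm(data$age_ratio[i], mu, params$sigma_ageratio, log = TRUE)
  }
  lp
}

# exhaustive-search HPD oracle: try every contiguous window of the sorted
# sample and keep the narrowest one containing >= ceiling(mass * n) points
oracle_hpd <- function(x, mass) {
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + k - 1])
  }
  best
}
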