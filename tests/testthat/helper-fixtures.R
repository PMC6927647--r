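# shared fixtures built in code

terms_small <- c("spring_precip", "summer_precip", "swe", "swe:lag1")

small_scenario <- function(seed = 42, ...) {
  args <- list(
    n_districts = 4, years = 2004:2009,
    design = terms_small,
    beta = stats::setNames(c(-0.2, 0.08, 0, 0), terms_small),
    observed_years_per_district = rep(5, 4),
    n_missing_classification = 1,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}

# a tiny 2-district x 4-year instance with hand-manageable pieces, used by the
# density tests; parameters are arbitrary but in-support
tiny_instance <- function(seed = 7) {
  withr::with_seed(seed, {
    districts <- c("A", "B")
    years <- 2001:2004
    harvest <- tidyr::expand_grid(district = districts, year = years) |>
      dplyr::mutate(h_calves = sample(0:5, 8, replace = TRUE),
                    h_adult_females = sample(5:20, 8, replace = TRUE),
                    h_adult_males = sample(10:30, 8, replace = TRUE))
    latents <- tidyr::expand_grid(district = districts, year = years) |>
      dplyr::mutate(n_calves = sample(50:120, 8, replace = TRUE),
                    n_adult_females = sample(200:400, 8, replace = TRUE),
                    n_adult_males = sample(80:160, 8, replace = TRUE))
    surveys <- tibble::tibble(
      district = c("A", "A", "B", "B"),
      year = c(2002, 2004, 2001, 2003),
      total_count = c(400L, 420L, 500L, 480L),
      calves = c(60L, NA, 80L, 70L),
      adult_females = c(220L, NA, 260L, 240L),
      adult_males = c(90L, NA, 120L, 110L)
    ) |> validate_surveys()
    design <- tidyr::expand_grid(district = districts, year = years[-1]) |>
      dplyr::mutate(x1 = round(stats::rnorm(6), 2), x2 = round(stats::rnorm(6), 2))
    params <- list(
      alpha = -1.1, beta = c(x1 = -0.2, x2 = 0.1),
      zeta = stats::setNames(round(stats::rnorm(3, 0, 0.4), 2), years[-1]),
      phi_a = 0.85, delta = 0.5,
      sigma_zeta = 0.5, sigma_beta = 0.4, sigma_count = 0.2,
      gamma = stats::setNames(round(stats::rnorm(4, 0, 0.1), 3),
                              paste0(surveys$district, ":", surveys$year))
    )
    list(surveys = surveys, latents = latents, harvest = harvest,
         design = design, params = params)
  })
}

# one small fitted population model, shared across test files (fit once)
.fit_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    study <- simulate_study(small_scenario())
    .fit_cache$study <- study
    .fit_cache$fit <- fit_population(
      study$surveys, study$harvest, study$covariates,
      design = terms_small,
      protocol = mcmc_protocol(1400, 400, 1, 2, adapt = 150),
      seed = 5, monitor = c("latent", "gamma"))
  }
  list(study = .fit_cache$study, fit = .fit_cache$fit)
}

# hand-built pop_fit carrying prescribed latent totals, for derived-quantity
# tests that need exact arithmetic
fake_latent_fit <- function(totals, n_draws = 50) {
  years <- 2001:(2000 + ncol(totals))
  districts <- sprintf("D%d", seq_len(nrow(totals)))
  cols <- character(0); vals <- numeric(0)
  for (u in seq_len(nrow(totals))) {
    for (t in seq_len(ncol(totals))) {
      third <- totals[u, t] / 3
      for (stem in c("Nc", "Naf", "Nam")) {
        cols <- c(cols, sprintf("%s[%d,%d]", stem, t, u))
        vals <- c(vals, third)
      }
    }
  }
  m <- matrix(rep(vals, each = n_draws), nrow = n_draws,
              dimnames = list(NULL, cols))
  m <- cbind(m, alpha = rep(-1, n_draws))
  draws <- coda::mcmc.list(coda::mcmc(m))
  structure(list(draws = draws, districts = districts, years = years,
                 terms = character(0), surveys = tibble::tibble(),
                 protocol = mcmc_protocol(100, 0, 1, 1)),
            class = "pop_fit")
}
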