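test_that("recruitment rate follows the logit link", {
  expect_equal(recruitment_rate(qlogis(0.25)), 0.25)
  expect_equal(recruitment_rate(0), 0.5)
  # a -0.2 effect at +1 sd moves mean recruitment from 0.25 to about 0.21
  tau <- recruitment_rate(qlogis(0.25), 0, x_row = 1, beta = -0.2)
  expect_equal(tau, plogis(qlogis(0.25) - 0.2))
  expect_lt(abs(tau - 0.214), 5e-4)
  expect_error(recruitment_rate(0, 0, x_row = c(1, 2), beta = 1), "lengths differ")
})

test_that("prior terms match their closed forms", {
  p <- list(alpha = 0, beta = numeric(0), zeta = numeric(0), phi_a = 0.5,
            sigma_zeta = 1, sigma_beta = 1, sigma_count = 1)
  # flat Beta(1,1), standard-normal intercept at 0, three Uniform(0,10) sds
  expect_equal(log_prior(p), -0.5 * log(2 * pi) + 3 * log(1 / 10))
  p$sigma_zeta <- 11
  expect_equal(log_prior(p), -Inf)
  p$sigma_zeta <- 1; p$phi_a <- 1.2
  expect_equal(log_prior(p), -Inf)
})

test_that("process density reduces to single Poisson terms and truncates", {
  harvest <- tibble::tibble(district = "A", year = 2001:2002,
                            h_calves = 0L, h_adult_females = 0L, h_adult_males = 0L)
  latents <- tibble::tibble(district = "A", year = 2001:2002,
                            n_calves = c(100L, 25L),
                            n_adult_females = c(250L, 250L),
                            n_adult_males = c(100L, 150L))
  design <- tibble::tibble(district = "A", year = 2002L, x1 = 0)
  params <- list(alpha = qlogis(0.25), beta = c(x1 = 0),
                 zeta = c("2002" = 0), phi_a = 1, delta = 0.5)
  got <- log_process_density(latents, harvest, params, design)
  init <- 3 * dunif(1, 0, 10000, log = TRUE)
  expected <- init +
    dpois(25, 0.25 * 250, log = TRUE) +
    dpois(250, 1 * (0.5 * 100 + 250), log = TRUE) +
    dpois(150, 1 * (0.5 * 100 + 100), log = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)

  # initial calves below next year's calf harvest violate the truncated prior
  harvest$h_calves <- c(0L, 150L)
  expect_equal(log_process_density(latents, harvest, params, design), -Inf)
})

test_that("observation density matches hand-computed Poisson/multinomial terms", {
  latents <- tibble::tibble(district = "A", year = 2001L, n_calves = 100L,
                            n_adult_females = 200L, n_adult_males = 100L)
  surveys <- validate_surveys(tibble::tibble(
    district = "A", year = 2001L, total_count = 400L,
    calves = 100L, adult_females = 200L, adult_males = 100L))
  params <- list(gamma = c("A:2001" = 0), sigma_count = 0.2)
  got <- log_observation_density(surveys, latents, params)
  expected <- dpois(400, 400, log = TRUE) + dnorm(0, 0, 0.2, log = TRUE) +
    dmultinom(c(100, 200, 100), prob = c(0.25, 0.5, 0.25), log = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)

  # a classification-missing survey contributes only the count and gamma terms
  surveys2 <- validate_surveys(tibble::tibble(
    district = "A", year = 2001L, total_count = 400L,
    calves = NA_integer_, adult_females = NA_integer_, adult_males = NA_integer_))
  got2 <- log_observation_density(surveys2, latents, params)
  expect_equal(got2, dpois(400, 400, log = TRUE) + dnorm(0, 0, 0.2, log = TRUE))
})

test_that("joint density equals the brute-force term-by-term oracle", {
  inst <- tiny_instance()
  mine <- joint_log_density(inst$surveys, inst$latents, inst$harvest,
                            inst$params, inst$design)
  oracle <- oracle_joint_log_density(inst$surveys, inst$latents, inst$harvest,
                                     inst$params, inst$design)
  expect_true(is.finite(mine))
  expect_equal(mine, oracle, tolerance = 1e-10)
  # and decomposes into prior + process + observation
  expect_equal(mine,
               log_prior(inst$params) +
                 log_process_density(inst$latents, inst$harvest, inst$params,
                                     inst$design) +
                 log_observation_density(inst$surveys, inst$latents, inst$params),
               tolerance = 1e-12)
})

test_that("joint density is invariant to permuting district labels", {
  inst <- tiny_instance()
  relabel <- c(A = "Zebra", B = "Yak")
  swap <- function(df) dplyr::mutate(df, district = unname(relabel[district]))
  params2 <- inst$params
  names(params2$gamma) <- paste0(relabel[inst$surveys$district], ":", inst$surveys$year)
  expect_equal(
    joint_log_density(swap(inst$surveys), swap(inst$latents), swap(inst$harvest),
                      params2, swap(inst$design)),
    joint_log_density(inst$surveys, inst$latents, inst$harvest, inst$params,
                      inst$design),
    tolerance = 1e-12)
})

test_that("expected age ratio and its density match closed forms and the oracle", {
  expect_equal(expected_ratio(25.3), 25.3)
  expect_equal(expected_ratio(25.3, beta_harvest = -2, h_af = 1), 23.3)
  expect_error(expected_ratio(0, x_row = c(1, 2), beta = 0), "lengths differ")

  # one row at its mode: the Gaussian normalizing constant
  data <- tibble::tibble(year = 2002L, age_ratio = 25, a = 0, h_af = 0)
  params <- list(alpha = 25, beta = c(a = 0), beta_harvest = 0,
                 zeta = c("2002" = 0), sigma_zeta = 1, sigma_beta = 1,
                 sigma_ageratio = 3)
  base <- log_density_ageratio(data, params, terms = "a")
  prior_terms <- dnorm(25, 0, 100, log = TRUE) +
    2 * dnorm(0, 0, 1, log = TRUE) + dnorm(0, 0, 1, log = TRUE) +
    2 * log(1 / 10) + log(1 / 20)
  expect_equal(base - prior_terms, -log(3 * sqrt(2 * pi)), tolerance = 1e-12)

  # two identical rows double the likelihood term exactly
  data2 <- dplyr::bind_rows(data, data)
  expect_equal(log_density_ageratio(data2, params, terms = "a") - prior_terms,
               2 * (-log(3 * sqrt(2 * pi))), tolerance = 1e-12)

  # small random instance against the independent oracle
  withr::with_seed(13, {
    d <- tibble::tibble(year = rep(2002:2004, each = 4),
                        age_ratio = rnorm(12, 25, 6),
                        a = rnorm(12), b = rnorm(12), h_af = rnorm(12))
    p <- list(alpha = 24, beta = c(a = -2, b = 1), beta_harvest = -1.5,
              zeta = c("2002" = 1, "2003" = -0.5, "2004" = 0.2),
              sigma_zeta = 2, sigma_beta = 3, sigma_ageratio = 6)
    expect_equal(log_density_ageratio(d, p, terms = c("a", "b")),
                 oracle_ageratio_log_density(d, p, terms = c("a", "b")),
                 tolerance = 1e-10)
  })
})
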