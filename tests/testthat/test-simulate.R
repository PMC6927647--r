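test_that("stage-structured expectations follow the transition equations", {
  e <- expected_transition(100, 200, 50, 0, 0, 0, phi_a = 1, tau = 0, delta = 0.5)
  expect_equal(unname(e), c(0, 250, 100))
  e2 <- expected_transition(100, 200, 50, 0, 0, 0, phi_a = 1, tau = 0.25, delta = 0.5)
  expect_equal(e2[["calves"]], 50)
  # delta = 0.5 splits surviving calves equally between the adult pools
  e3 <- expected_transition(100, 200, 200, 0, 0, 0, phi_a = 0.9, tau = 0.2, delta = 0.5)
  expect_equal(e3[["adult_females"]], e3[["adult_males"]])
  # full removal of the female pool
  e4 <- expected_transition(100, 200, 50, 0, 250, 0, phi_a = 0.9, tau = 0.2, delta = 0.5)
  expect_equal(e4[["adult_females"]], 0)
})

test_that("latent simulation draws Poisson transitions with the configured means", {
  cfg <- small_scenario(seed = 21)
  withr::with_seed(1, {
    # Monte-Carlo check of the Poisson layer: many draws at a fixed mean
    draws <- rpois(10000, 250)
    expect_lt(abs(mean(draws) - 250), 3 * sqrt(250 / 10000))
  })
  withr::with_seed(cfg$seed, {
    covs <- simulate_covariates(cfg)
    proc <- simulate_latent(cfg, covs)
  })
  # harvest never exceeds the class abundance it was drawn from
  joined <- dplyr::inner_join(
    proc$harvest,
    dplyr::mutate(proc$latents, year = year + 1L),
    by = c("district", "year"))
  expect_true(all(joined$h_calves <= joined$n_calves))
  expect_true(all(joined$h_adult_females <= joined$n_adult_females))
  expect_true(all(joined$h_adult_males <= joined$n_adult_males))
  expect_true(all(proc$latents$n_calves >= 0))
})

test_that("with no covariate effects and no year variance, realized recruitment
          converges to the inverse-logit intercept", {
  cfg <- small_scenario(
    seed = 31, n_districts = 12, years = 2004:2015,
    beta = stats::setNames(rep(0, 4), terms_small), sigma_zeta = 0,
    observed_years_per_district = rep(6, 12),
    harvest_rate_calves = c(0, 0),
    harvest_rate_adult_females = c(0.05, 0.15),
    harvest_rate_adult_males = c(0.15, 0.35))
  withr::with_seed(cfg$seed, {
    covs <- simulate_covariates(cfg)
    proc <- simulate_latent(cfg, covs)
  })
  lat <- dplyr::arrange(proc$latents, district, year)
  prev_af <- dplyr::mutate(lat, year = year + 1L) |>
    dplyr::select(district, year, prev_af = n_adult_females)
  cur <- dplyr::inner_join(lat, prev_af, by = c("district", "year"))
  realized <- mean(cur$n_calves / cur$prev_af)
  mc_se <- sd(cur$n_calves / cur$prev_af) / sqrt(nrow(cur))
  expect_lt(abs(realized - plogis(cfg$alpha)), 4 * mc_se)
})

test_that("observation layer reproduces multinomial class shares and coverage", {
  cfg <- small_scenario(seed = 41, sigma_count = 1e-8,
                        classification_fraction = c(1, 1),
                        n_missing_classification = 0)
  withr::with_seed(cfg$seed, {
    covs <- simulate_covariates(cfg)
    proc <- simulate_latent(cfg, covs)
    obs <- simulate_observations(proc$latents, cfg)
  })
  # with sigma_count ~ 0 and full classification, counts track latent totals
  # within Poisson noise and class counts track latent shares
  lat <- dplyr::inner_join(obs, proc$latents, by = c("district", "year"))
  ntot <- lat$n_calves + lat$n_adult_females + lat$n_adult_males
  expect_true(all(abs(lat$total_count - ntot) < 5 * sqrt(ntot)))
  expect_equal(lat$classified_total, lat$total_count)
  expect_true(all(abs(lat$calves - lat$classified_total * lat$n_calves / ntot)
                  < 5 * sqrt(lat$classified_total) + 1))
  # configured coverage pattern is honored exactly
  per_district <- dplyr::count(obs, district)
  expect_equal(per_district$n, cfg$observed_years_per_district)
})

test_that("count overdispersion exceeds Poisson variance when sigma_count > 0", {
  withr::with_seed(6, {
    n <- 40000; ntot <- 800; sig <- 0.2
    y <- rpois(n, ntot * exp(rnorm(n, 0, sig)))
    expect_gt(var(y), 2 * ntot)  # lognormal mixing inflates the variance
  })
})

test_that("classification fraction outside (0, 1] errors", {
  cfg <- small_scenario(seed = 51)
  cfg$classification_fraction <- c(0, 1.2)
  withr::with_seed(1, {
    covs <- simulate_covariates(small_scenario(seed = 51))
    proc <- simulate_latent(small_scenario(seed = 51), covs)
    expect_error(simulate_observations(proc$latents, cfg), "fraction")
  })
})

test_that("covariate simulation fills the district-year grid and passes the screen", {
  cfg <- scenario_config(seed = 61, design = terms_small)
  withr::with_seed(cfg$seed, covs <- simulate_covariates(cfg))
  expect_equal(nrow(covs), 17 * 13)
  expect_equal(nrow(collinearity_screen(standardize_covariates(covs), 0.5)), 0)
  # independent draws are uncorrelated on average across seeds
  withr::with_seed(2, {
    rs <- replicate(30, {
      z <- matrix(rnorm(120 * 2), ncol = 2)
      cor(z[, 1], z[, 2])
    })
    expect_lt(abs(mean(rs)), 0.05)
  })
})

test_that("the default scenario reproduces the reference survey-effort pattern", {
  cfg <- scenario_config(design = terms_small)
  study <- simulate_study(cfg)
  expect_equal(nrow(study$surveys), 140)
  expect_equal(sum(!is.na(study$surveys$classified_total)), 135)
  counts <- sort(table(study$surveys$district))
  expect_equal(median(cfg$observed_years_per_district), 7)
  expect_equal(range(cfg$observed_years_per_district), c(6, 13))
})

test_that("studies are reproducible and truth round-trips through disk", {
  cfg <- small_scenario(seed = 71)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  make_study(cfg, file.path(dir1, "study"), overwrite = FALSE)
  make_study(cfg, file.path(dir2, "study"), overwrite = FALSE)
  for (f in c("surveys.csv", "harvest.csv", "covariates.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir1, "study", f)),
                     readLines(file.path(dir2, "study", f)))
  }
  expect_error(make_study(cfg, file.path(dir1, "study")), "exists")
  truth <- read_truth(file.path(dir1, "study", "truth.json"))
  study <- simulate_study(cfg)
  expect_equal(truth$alpha, study$truth$alpha)
  expect_equal(truth$beta, unlist(study$truth$beta)[names(truth$beta)])
  expect_equal(as.data.frame(truth$latents), as.data.frame(study$truth$latents))
  surveys_back <- read_survey_table(file.path(dir1, "study", "surveys.csv"))
  expect_equal(as.data.frame(surveys_back), as.data.frame(study$surveys),
               ignore_attr = TRUE)
})
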