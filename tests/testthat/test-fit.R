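test_that("protocol bookkeeping reproduces the reference chain arithmetic", {
  pop <- mcmc_protocol()
  expect_equal(pop$kept_per_chain, 16000)
  expect_equal(pop$total_kept, 64000)
  ar <- ageratio_protocol()
  expect_equal(ar$kept_per_chain, 15000)
  expect_equal(ar$total_kept, 60000)
  expect_error(mcmc_protocol(1000, 500, 3), "divisible")
  expect_error(mcmc_protocol(500, 500), "iterations")
})

test_that("a small synthetic study is recovered by the population model", {
  pair <- cached_small_fit()
  fit <- pair$fit
  truth <- pair$study$truth
  expect_equal(coda::nchain(fit$draws), 2)
  expect_equal(coda::niter(fit$draws), 1000)
  td <- tidy(fit, "^(phi_a|alpha|beta|sigma)")
  expect_true(all(c("phi_a", "alpha", terms_small) %in% td$term))
  # posterior medians land in the right neighborhood of the truth
  est <- function(t) td$estimate[td$term == t]
  expect_lt(abs(est("alpha") - truth$alpha), 0.5)
  expect_lt(abs(est("phi_a") - truth$phi_a), 0.05)
  expect_lt(abs(est("spring_precip") - (-0.2)), 0.15)
  g <- glance(fit)
  expect_equal(g$total_kept, 2000)
  expect_true(g$min_ess > 0)
})

test_that("latent trajectories track the observed totals", {
  pair <- cached_small_fit()
  fit <- pair$fit
  obs <- dplyr::filter(pair$study$surveys, district == "HD01", !is.na(total_count))
  traj <- latent_trajectory(fit, "HD01")
  m <- dplyr::inner_join(traj, obs, by = "year")
  # posterior medians within ~3 x sqrt(N) + overdispersion of each count
  expect_true(all(abs(m$median - m$total_count) <
                    3 * sqrt(m$total_count) + 0.5 * m$total_count))
  lam <- derive_lambda(fit, "HD01")
  expect_equal(nrow(lam), length(fit$years) - 1)
  expect_true(all(lam$lower <= lam$median & lam$median <= lam$upper))
})

test_that("plot methods return ggplot objects", {
  pair <- cached_small_fit()
  expect_s3_class(autoplot(pair$fit), "ggplot")
  expect_s3_class(plot_trajectory(pair$fit, "HD01"), "ggplot")
  ppc <- posterior_predictive_check(pair$fit, "ssq", ndraws = 50, seed = 1)
  expect_s3_class(autoplot(ppc), "ggplot")
})

test_that("surveys outside the harvest window are rejected", {
  pair <- cached_small_fit()
  s <- pair$study$surveys
  s$year[1] <- 1999L
  expect_error(
    fit_population(s, pair$study$harvest, pair$study$covariates,
                   design = terms_small,
                   protocol = mcmc_protocol(200, 100, 1, 1, adapt = 50)),
    "outside the harvest window")
})

test_that("a single age-ratio record is dominated by its diffuse prior", {
  # one data point cannot pin the intercept against a Normal(0, 100^2) prior
  surveys <- validate_surveys(tibble::tibble(
    district = "HD01", year = 2005L, total_count = 400L,
    calves = 80L, adult_females = 240L, adult_males = 80L))
  harvest <- tibble::tibble(district = "HD01", year = 2004:2005,
                            h_calves = c(0L, 2L), h_adult_females = c(10L, 25L),
                            h_adult_males = c(20L, 30L))
  covs <- tibble::tibble(district = "HD01", year = c(2004L, 2005L), a = c(-1, 1))
  fit <- suppressMessages(fit_age_ratio(
    surveys, harvest, covs, design = "a",
    protocol = ageratio_protocol(6000, 1000, 1, 2, adapt = 200), seed = 8))
  alpha <- as.matrix(fit$draws)[, "alpha"]
  expect_gt(sd(alpha), 5)  # far wider than any data-dominated posterior
})
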