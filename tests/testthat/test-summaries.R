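test_that("HPD interval is the shortest window with the tie-break at the lowest start", {
  expect_equal(unname(hpd_interval(1:100, 0.9)), c(1, 90))
  expect_equal(unname(hpd_interval(rep(3.5, 20), 0.9)), c(3.5, 3.5))
  expect_error(hpd_interval(1:100, 1.2), "mass")
  expect_error(hpd_interval(1:5, 0.9), "at least 10")
})

test_that("HPD agrees with the exhaustive window-search oracle", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      x <- switch(1 + rep %% 3,
                  rnorm(200), rgamma(200, shape = 2), c(rnorm(100), rnorm(100, 4)))
      for (mass in c(0.5, 0.9)) {
        expect_equal(unname(hpd_interval(x, mass)), oracle_hpd(x, mass))
      }
    }
  })
})

test_that("HPD of a symmetric unimodal sample is close to the central interval", {
  withr::with_seed(9, {
    x <- rnorm(20000)
    h <- hpd_interval(x, 0.9)
    q <- quantile(x, c(0.05, 0.95))
    expect_lt(abs(h[["lower"]] - q[[1]]), 0.1)
    expect_lt(abs(h[["upper"]] - q[[2]]), 0.1)
  })
})

test_that("split R-hat separates mixed from unmixed chains", {
  withr::with_seed(10, {
    good <- matrix(rnorm(4000), ncol = 4)
    expect_lt(abs(split_rhat(good) - 1), 0.02)
    bad <- cbind(rnorm(1000), rnorm(1000, 3), rnorm(1000), rnorm(1000, -3))
    expect_gt(split_rhat(bad), 1.1)
  })
})

test_that("split R-hat matches an independently coded formula", {
  # direct transcription: split each chain, then B and W over the halves
  rhat_direct <- function(x) {
    n2 <- floor(nrow(x) / 2)
    halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
      cbind(x[1:n2, j], x[(nrow(x) - n2 + 1):nrow(x), j])
    }))
    m <- ncol(halves); n <- nrow(halves)
    means <- apply(halves, 2, mean)
    vars <- apply(halves, 2, var)
    B <- n / (m - 1) * sum((means - mean(means))^2)
    W <- mean(vars)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  withr::with_seed(12, {
    x <- matrix(rnorm(2000) + rep(c(0, 0.3), each = 500), ncol = 2)
    expect_equal(split_rhat(x), rhat_direct(x), tolerance = 1e-6)
  })
})

test_that("growth rates are exact ratios of latent totals", {
  totals <- rbind(c(900, 900, 900, 900),   # constant: lambda = 1
                  c(300, 600, 1200, 2400)) # doubling: lambda = 2
  fit <- fake_latent_fit(totals)
  lam <- derive_lambda(fit, "D1")
  expect_equal(lam$median, rep(1, 3))
  expect_equal(lam$lower, rep(1, 3))
  lam2 <- derive_lambda(fit, "D2")
  expect_equal(lam2$median, rep(2, 3))
  all_lam <- derive_lambda(fit)
  expect_equal(nrow(all_lam), 6)
})

test_that("recruitment predictions reduce to the intercept at the zero profile", {
  totals <- rbind(c(900, 900, 900, 900))
  fit <- fake_latent_fit(totals)  # alpha fixed at -1 in every draw
  tau <- predict_recruitment(fit)
  expect_equal(unique(tau), plogis(-1))
  expect_equal(unique(recruitment_contrast(fit, NULL, NULL)), 0)
})

test_that("profiles are validated against the design terms", {
  pair <- cached_small_fit()
  fit <- pair$fit
  expect_error(predict_recruitment(fit, profile = c(1, 2)), "4-term design")
  expect_error(predict_recruitment(fit, profile = c(nope = 1)), "unknown design terms")
  tau0 <- predict_recruitment(fit)
  tau_up <- predict_recruitment(fit, profile = c(spring_precip = 1))
  # the fitted spring-precipitation effect is negative: +1 sd lowers recruitment
  expect_lt(median(tau_up), median(tau0))
  # named and positional profiles agree
  tau_pos <- predict_recruitment(fit, profile = c(1, 0, 0, 0))
  expect_equal(sort(tau_up), sort(tau_pos))
})

test_that("convergence report covers the monitored hyperparameters", {
  pair <- cached_small_fit()
  conv <- convergence_report(pair$fit, "^(phi_a|alpha|sigma)")
  expect_setequal(conv$parameter,
                  c("phi_a", "alpha", "sigma_zeta", "sigma_beta", "sigma_count"))
  expect_true(all(is.finite(conv$rhat)))
  expect_true(all(conv$ess > 0))
  expect_equal(
    unname(conv$ess),
    unname(coda::effectiveSize(pair$fit$draws[, conv$parameter])[conv$parameter]))
})
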