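cov_table <- function(...) {
  vals <- list(...)
  n <- length(vals[[1]])
  tibble::tibble(district = sprintf("D%d", seq_len(n)), year = 2000L + seq_len(n),
                 !!!vals)
}

test_that("standardization centers, scales and inverts exactly", {
  x <- cov_table(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_covariates(x)
  expect_equal(s$a, c(-1, 0, 1))  # n - 1 denominator
  expect_equal(mean(s$b), 0, tolerance = 1e-12)
  expect_equal(sd(s$b), 1, tolerance = 1e-12)
  back <- unstandardize_covariates(s)
  expect_equal(back$a, x$a, tolerance = 1e-9)
  expect_equal(back$b, x$b, tolerance = 1e-9)
  expect_error(standardize_covariates(cov_table(a = c(5, 5, 5))), "zero-variance.*a")
})

test_that("standardization is invariant to affine transforms up to sign", {
  x <- cov_table(a = c(2.5, -1, 4, 0.5))
  s1 <- standardize_covariates(x)$a
  x2 <- x; x2$a <- -3 * x$a + 7
  s2 <- standardize_covariates(x2)$a
  expect_equal(s2, -s1, tolerance = 1e-12)
})

test_that("scaling metadata recovers raw units (one sd above the mean)", {
  x <- cov_table(lions = c(0.36, 4.12, 7.88))  # mean 4.12, sd 3.76
  s <- standardize_covariates(x)
  sc <- covariate_scaling(s)
  expect_equal(sc$mean, 4.12)
  expect_equal(sc$mean + 1 * sc$sd, 7.88)
  expect_equal(s$lions[3], 1)
})

test_that("collinearity screen flags duplicated columns and passes orthogonal ones", {
  x <- cov_table(a = c(1, 2, 3), b = c(1, 2, 3))
  hits <- collinearity_screen(x, threshold = 0.5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$r, 1)
  y <- cov_table(a = c(1, -1, 0), b = c(1, 1, -2))
  expect_equal(nrow(collinearity_screen(y, threshold = 0.5)), 0)
  expect_error(collinearity_screen(cov_table(a = 1:2, b = 2:1)), "three complete rows")
})

test_that("independent Gaussian columns pass the 0.5 screen at n = 200", {
  withr::with_seed(1, {
    x <- tibble::tibble(district = sprintf("D%d", 1:200), year = 2000L + 1:200,
                        a = rnorm(200), b = rnorm(200), c = rnorm(200))
    expect_equal(nrow(collinearity_screen(x, threshold = 0.5)), 0)
  })
})

test_that("design matrix builds main effects, lags and interactions in order", {
  x <- tibble::tibble(district = rep("D1", 3), year = 2001:2003,
                      a = c(1, 2, -1), b = c(0.5, -1, 2))
  d <- build_design_matrix(x, c("a", "b", "a*b", "a:lag1"))
  expect_equal(names(d), c("district", "year", "a", "b", "a*b", "a:lag1"))
  expect_equal(d$`a*b`, c(2 * -1, -1 * 2))
  expect_equal(d$`a:lag1`, c(1, 2))
  # a zero covariate row maps to a zero design row (average conditions)
  x0 <- tibble::tibble(district = rep("D1", 2), year = 2001:2002,
                       a = c(0, 0), b = c(0, 0))
  d0 <- build_design_matrix(x0, c("a", "b", "a*b"))
  expect_true(all(d0[, c("a", "b", "a*b")] == 0))
})

test_that("lag-1 terms without a prior covariate row are an error naming the rows", {
  x <- tibble::tibble(district = c("D1", "D1", "D2"), year = c(2001L, 2002L, 2002L),
                      a = c(1, 2, 3))
  expect_error(build_design_matrix(x, c("a:lag1"), years = 2002L), "D2:2002")
})

test_that("default designs have 20 and 21 terms, differing by adult-female harvest", {
  pop <- design_terms_population()
  ar <- design_terms_ageratio()
  expect_length(pop, 20)
  expect_length(ar, 21)
  expect_equal(setdiff(ar, pop), "af_harvest")
  expect_false(anyDuplicated(pop) > 0)
})

test_that("design specs round-trip through YAML and reject malformed terms", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(design_terms_population()), path)
  spec <- read_design_spec(path)
  expect_equal(spec$terms, design_terms_population())
  expect_error(design_spec(c("a", "a")), "duplicated")
  expect_error(design_spec("a*b*c"), "at most one")
  expect_error(design_spec("a:lag2"), "bad design term")
})
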