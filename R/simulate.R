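#' Scenario configuration for synthetic studies
#'
#' Describes one simulated monitoring program: the latent demographic truth
#' (intercept, covariate effects, year-effect spread, adult survival), the
#' observation layer (count overdispersion, classification fractions), harvest
#' pressure, and the survey coverage pattern. Defaults mirror the study
#' conditions the package is built around: 17 hunting districts followed over
#' 2004-2016 with discontinuous aerial surveys (140 observed district-years,
#' median 7 per district, minimum 6), 5 of which carry a total count but no
#' age/sex classification, mean recruitment 0.25, apparent adult survival 0.85,
#' year-effect standard deviation 0.6 and log-scale count overdispersion 0.15.
#'
#' @param n_districts Number of districts.
#' @param years Calendar years of the modelled window.
#' @param alpha Logit-scale mean recruitment.
#' @param beta Named vector of true covariate effects, aligned with `design`;
#'   defaults to all zeros.
#' @param phi_a Apparent adult survival in (0, 1).
#' @param delta Female fraction of calves.
#' @param sigma_zeta Standard deviation of year random effects (logit scale).
#' @param sigma_count Standard deviation of the log-scale observation effect.
#' @param design Character vector of design terms (see [design_spec()]).
#' @param init_calves,init_adult_females,init_adult_males Integer ranges
#'   (length 2) for initial abundances per district.
#' @param harvest_rate_calves,harvest_rate_adult_females,harvest_rate_adult_males
#'   Ranges of per-class annual harvest rates, drawn uniformly per
#'   district-year.
#' @param observed_years_per_district Integer vector (length `n_districts`) of
#'   surveyed-year counts per district. `NULL` uses the default pattern: at the
#'   17 x 13 default dimensions, counts summing to 140 with median 7; otherwise
#'   `min(6, n_years)` per district.
#' @param n_missing_classification Number of observed district-years whose
#'   classification is dropped (count retained).
#' @param classification_fraction Range of the fraction of counted animals that
#'   get classified.
#' @param seed RNG seed making the whole study reproducible.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_districts = 17,
                            years = 2004:2016,
                            alpha = stats::qlogis(0.25),
                            beta = NULL,
                            phi_a = 0.85,
                            delta = 0.5,
                            sigma_zeta = 0.6,
                            sigma_count = 0.15,
                            design = design_terms_population(),
                            init_calves = c(100, 400),
                            init_adult_females = c(300, 1200),
                            init_adult_males = c(100, 400),
                            harvest_rate_calves = c(0.01, 0.06),
                            harvest_rate_adult_females = c(0.05, 0.15),
                            harvest_rate_adult_males = c(0.15, 0.35),
                            observed_years_per_district = NULL,
                            n_missing_classification = 5,
                            classification_fraction = c(0.6, 0.95),
                            seed = 1) {
  if (is.null(beta)) beta <- stats::setNames(rep(0, length(design)), design)
  if (is.null(names(beta))) names(beta) <- design
  if (!setequal(names(beta), design) || length(beta) != length(design)) {
    stop("beta must be named by the design terms", call. = FALSE)
  }
  beta <- beta[design]
  if (is.null(observed_years_per_district)) {
    observed_years_per_district <-
      if (n_districts == 17 && length(years) == 13) {
        c(6, 6, 6, 6, 7, 7, 7, 7, 7, 8, 8, 9, 9, 10, 11, 13, 13)
      } else {
        rep(min(6L, length(years)), n_districts)
      }
  }
  cfg <- list(
    n_districts = n_districts, years = as.integer(years),
    alpha = alpha, beta = beta, phi_a = phi_a, delta = delta,
    sigma_zeta = sigma_zeta, sigma_count = sigma_count,
    design = design,
    init_calves = init_calves, init_adult_females = init_adult_females,
    init_adult_males = init_adult_males,
    harvest_rate_calves = harvest_rate_calves,
    harvest_rate_adult_females = harvest_rate_adult_females,
    harvest_rate_adult_males = harvest_rate_adult_males,
    observed_years_per_district = as.integer(observed_years_per_district),
    n_missing_classification = as.integer(n_missing_classification),
    classification_fraction = classification_fraction,
    seed = as.integer(seed)
  )
  rates <- c(cfg$harvest_rate_calves, cfg$harvest_rate_adult_females,
             cfg$harvest_rate_adult_males)
  stopifnot(
    length(cfg$years) >= 2,
    cfg$phi_a > 0, cfg$phi_a < 1, cfg$delta > 0, cfg$delta < 1,
    all(rates >= 0), all(rates < 1),
    length(cfg$observed_years_per_district) == n_districts,
    all(cfg$observed_years_per_district >= 2),
    all(cfg$observed_years_per_district <= length(cfg$years)),
    cfg$classification_fraction[1] > 0, cfg$classification_fraction[2] <= 1
  )
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$n_districts, " districts, years ",
      min(x$years), "-", max(x$years), ", ",
      sum(x$observed_years_per_district), " observed district-years\n", sep = "")
  cat("  alpha = ", signif(x$alpha, 4), " (mean recruitment ",
      signif(stats::plogis(x$alpha), 3), "), phi_a = ", x$phi_a,
      ", sigma_zeta = ", x$sigma_zeta, ", sigma_count = ", x$sigma_count, "\n", sep = "")
  nz <- x$beta[x$beta != 0]
  cat("  nonzero effects: ", if (length(nz) == 0) "none" else
    paste0(names(nz), " = ", nz, collapse = ", "), "\n", sep = "")
  invisible(x)
}

scenario_districts <- function(config) sprintf("HD%02d", seq_len(config$n_districts))

base_covariates_of <- function(design) {
  parsed <- lapply(design, parse_design_term)
  setdiff(unique(unlist(lapply(parsed, function(tt) vapply(tt, `[[`, "", "covariate")))),
          "af_harvest")
}

# realistic raw location/scale per named covariate (precipitation in m,
# time-integrated NDVI unitless, cumulative SWE in m-days, predators in counts)
covariate_scale_defaults <- function() {
  list(
    spring_precip = c(0.17, 0.05), summer_precip = c(0.15, 0.04),
    spring_ndvi = c(1.06, 0.34), summer_ndvi = c(4.10, 0.75),
    swe = c(8.15, 6.30),
    lions = c(4.12, 3.76), bears = c(21.31, 17.86), wolves = c(15.99, 14.50)
  )
}

#' Simulate district-year environmental covariates
#'
#' Each base covariate referenced by the scenario design is drawn from a
#' Gaussian model with independent among-year, among-district and residual
#' components (equal thirds of the variance), placed on a realistic raw scale
#' for the named covariate (precipitation in metres, cumulative SWE in
#' metre-days, predator indices in counts). The generated table is redrawn (up
#' to `max_redraws`) until its standardized version passes the 0.50
#' collinearity screen.
#'
#' @param config A [scenario_config()].
#' @param max_redraws Redraw budget before giving up.
#' @return A raw-scale covariate tibble (`district`, `year`, covariates).
#' @export
simulate_covariates <- function(config, max_redraws = 20) {
  covs <- base_covariates_of(config$design)
  districts <- scenario_districts(config)
  scales <- covariate_scale_defaults()
  grid <- tidyr::expand_grid(district = districts, year = config$years)
  for (try in seq_len(max_redraws)) {
    out <- grid
    for (nm in covs) {
      sc <- scales[[nm]] %||% c(0, 1)
      yr_eff <- stats::setNames(stats::rnorm(length(config$years)), config$years)
      dst_eff <- stats::setNames(stats::rnorm(length(districts)), districts)
      z <- (yr_eff[as.character(out$year)] + dst_eff[out$district] +
              stats::rnorm(nrow(out))) / sqrt(3)
      out[[nm]] <- sc[1] + sc[2] * unname(z)
    }
    screen <- collinearity_screen(standardize_covariates(out), threshold = 0.5)
    if (nrow(screen) == 0) return(out)
  }
  stop("covariate table failed the collinearity screen after ", max_redraws,
       " redraws", call. = FALSE)
}

#' Simulate latent herd trajectories and harvest
#'
#' Initial abundances are drawn uniformly from the configured ranges; for each
#' later year, class harvest is Binomial(previous-year class abundance, rate)
#' with rates drawn per district-year from the configured ranges, and the next
#' abundances are Poisson draws around the expected stage-structured
#' transition, with the calf mean guarded below at `eps`. Recruitment follows
#' the logit link with the scenario's true intercept, year effects and
#' covariate effects.
#'
#' @param config A [scenario_config()].
#' @param covariates Raw covariate tibble from [simulate_covariates()].
#' @param eps Positivity guard on the calf Poisson mean.
#' @return A list with `latents`, `harvest`, `zeta` (named by year) and `tau`
#'   (realized district-year recruitment rates).
#' @export
simulate_latent <- function(config, covariates, eps = 1e-3) {
  districts <- scenario_districts(config)
  years <- config$years
  std <- standardize_covariates(covariates)
  xmat <- build_design_matrix(std, config$design, years = years[-1])
  terms <- setdiff(names(xmat), c("district", "year"))
  xkey <- stats::setNames(seq_len(nrow(xmat)), paste0(xmat$district, ":", xmat$year))
  zeta <- stats::setNames(stats::rnorm(length(years) - 1, 0, config$sigma_zeta),
                          years[-1])
  lat <- list(); har <- list(); taus <- list()
  r_int <- function(rg) sample(seq(rg[1], rg[2]), 1)
  for (d in districts) {
    nc <- naf <- nam <- hc <- haf <- ham <- integer(length(years))
    tau_d <- rep(NA_real_, length(years))
    nc[1] <- r_int(config$init_calves)
    naf[1] <- r_int(config$init_adult_females)
    nam[1] <- r_int(config$init_adult_males)
    for (i in 2:length(years)) {
      hc[i] <- stats::rbinom(1, nc[i - 1], stats::runif(1, config$harvest_rate_calves[1],
                                                        config$harvest_rate_calves[2]))
      haf[i] <- stats::rbinom(1, naf[i - 1], stats::runif(1, config$harvest_rate_adult_females[1],
                                                          config$harvest_rate_adult_females[2]))
      ham[i] <- stats::rbinom(1, nam[i - 1], stats::runif(1, config$harvest_rate_adult_males[1],
                                                          config$harvest_rate_adult_males[2]))
      xrow <- as.numeric(xmat[xkey[[paste0(d, ":", years[i])]], terms])
      tau_d[i] <- recruitment_rate(config$alpha, zeta[[as.character(years[i])]],
                                   xrow, config$beta)
      mu <- expected_transition(nc[i - 1], naf[i - 1], nam[i - 1],
                                hc[i], haf[i], ham[i],
                                phi_a = config$phi_a, tau = tau_d[i],
                                delta = config$delta)
      if (mu[["adult_females"]] <= 0 || mu[["adult_males"]] <= 0) {
        stop("harvest drives expected abundance to zero in ", d, ":", years[i], call. = FALSE)
      }
      nc[i] <- stats::rpois(1, pois_guard(mu[["calves"]], eps))
      naf[i] <- stats::rpois(1, mu[["adult_females"]])
      nam[i] <- stats::rpois(1, mu[["adult_males"]])
    }
    lat[[d]] <- tibble::tibble(district = d, year = years, n_calves = nc,
                               n_adult_females = naf, n_adult_males = nam)
    har[[d]] <- tibble::tibble(district = d, year = years, h_calves = hc,
                               h_adult_females = haf, h_adult_males = ham)
    taus[[d]] <- tibble::tibble(district = d, year = years, tau = tau_d)
  }
  list(latents = dplyr::bind_rows(lat), harvest = dplyr::bind_rows(har),
       zeta = zeta, tau = dplyr::bind_rows(taus))
}

#' Simulate the survey observation layer
#'
#' For each district, the configured number of surveyed years is sampled from
#' the window; for each surveyed district-year a log-scale observation effect
#' `gamma ~ Normal(0, sigma_count^2)` perturbs the Poisson mean of the total
#' count, a classification fraction drawn from the configured range determines
#' how many counted animals are classified, and the class counts are a
#' multinomial draw around the latent class shares. A configured number of
#' observed district-years then have their classification dropped, emulating
#' surveys where a total was counted but no classification reported.
#'
#' @param latents Latent tibble from [simulate_latent()].
#' @param config A [scenario_config()].
#' @return A survey tibble (validated), with attribute `"gamma"` holding the
#'   drawn observation effects keyed by `district:year`.
#' @export
simulate_observations <- function(latents, config) {
  fr <- config$classification_fraction
  if (fr[1] <= 0 || fr[2] > 1) stop("classification fraction outside (0, 1]", call. = FALSE)
  districts <- scenario_districts(config)
  rows <- list()
  for (k in seq_along(districts)) {
    d <- districts[k]
    yrs <- sort(sample(config$years, config$observed_years_per_district[k]))
    rows[[d]] <- tibble::tibble(district = d, year = yrs)
  }
  obs <- dplyr::bind_rows(rows)
  lkey <- latent_lookup(latents)
  n <- nrow(obs)
  gamma <- stats::rnorm(n, 0, config$sigma_count)
  total <- calves <- af <- am <- integer(n)
  for (i in seq_len(n)) {
    lat <- latents[lkey[[paste0(obs$district[i], ":", obs$year[i])]], ]
    ntot <- lat$n_calves + lat$n_adult_females + lat$n_adult_males
    total[i] <- stats::rpois(1, ntot * exp(gamma[i]))
    ncls <- round(stats::runif(1, fr[1], fr[2]) * total[i])
    if (ntot > 0 && ncls > 0) {
      pr <- c(lat$n_calves, lat$n_adult_females, lat$n_adult_males) / ntot
      draw <- stats::rmultinom(1, ncls, pr)[, 1]
    } else {
      draw <- c(0L, 0L, 0L)
    }
    calves[i] <- draw[1]; af[i] <- draw[2]; am[i] <- draw[3]
  }
  out <- tibble::tibble(district = obs$district, year = obs$year,
                        total_count = total, calves = calves,
                        adult_females = af, adult_males = am)
  n_drop <- min(config$n_missing_classification, n)
  if (n_drop > 0) {
    drop <- sample(n, n_drop)
    out$calves[drop] <- NA_integer_
    out$adult_females[drop] <- NA_integer_
    out$adult_males[drop] <- NA_integer_
  }
  out <- validate_surveys(out)
  attr(out, "gamma") <- stats::setNames(gamma, paste0(obs$district, ":", obs$year))
  out
}

#' Simulate a complete synthetic study
#'
#' Covariates, latent trajectories, harvest and surveys drawn under the
#' scenario's seed; the same seed always yields the identical study.
#'
#' @param config A [scenario_config()].
#' @return A list of class `elk_study` with `surveys`, `harvest`, `covariates`
#'   (raw scale) and `truth` (every generating parameter, the year effects, the
#'   latent trajectories and realized recruitment rates).
#' @export
simulate_study <- function(config) {
  withr::with_seed(config$seed, {
    covariates <- simulate_covariates(config)
    proc <- simulate_latent(config, covariates)
    surveys <- simulate_observations(proc$latents, config)
  })
  truth <- list(
    alpha = config$alpha, beta = as.list(config$beta), phi_a = config$phi_a,
    delta = config$delta, sigma_zeta = config$sigma_zeta,
    sigma_count = config$sigma_count,
    zeta = as.list(proc$zeta),
    gamma = as.list(attr(surveys, "gamma")),
    latents = proc$latents, tau = proc$tau, seed = config$seed,
    config = unclass(config)
  )
  structure(list(surveys = surveys, harvest = proc$harvest,
                 covariates = covariates, truth = truth),
            class = "elk_study")
}

#' @export
print.elk_study <- function(x, ...) {
  cat("<elk_study> ", length(unique(x$harvest$district)), " districts, ",
      nrow(x$surveys), " observed district-years (",
      sum(!is.na(x$surveys$classified_total)), " with classification)\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `surveys.csv`, `harvest.csv`, `covariates.csv` and `truth.json`
#' (every generating parameter and the latent trajectories) into `dir`.
#' Identical seeds produce byte-identical files.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return The study object, invisibly.
#' @export
make_study <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop("directory exists (use overwrite = TRUE): ", dir, call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  write_survey_table(study$surveys, file.path(dir, "surveys.csv"))
  write_harvest_table(study$harvest, file.path(dir, "harvest.csv"))
  write_covariate_table(study$covariates, file.path(dir, "covariates.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

#' Read back a study's generating truth
#'
#' @param path Path to a `truth.json` written by [make_study()].
#' @return The truth list with `latents` and `tau` as tibbles.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$latents <- tibble::as_tibble(truth$latents)
  truth$tau <- tibble::as_tibble(truth$tau)
  truth$beta <- unlist(truth$beta)
  truth$zeta <- unlist(truth$zeta)
  truth$gamma <- unlist(truth$gamma)
  truth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
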