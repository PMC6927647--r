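#' Standardize covariate columns
#'
#' Centers every covariate column with its sample mean and divides by one
#' sample standard deviation (n - 1 denominator). The scaling metadata is kept
#' in the `"scaling"` attribute so raw units can be recovered exactly.
#'
#' @param x A covariate tibble (columns `district`, `year`, covariates).
#' @return The standardized tibble, with `attr(, "scaling")` a tibble of
#'   (`covariate`, `mean`, `sd`).
#' @seealso [unstandardize_covariates()], [covariate_scaling()]
#' @export
standardize_covariates <- function(x) {
  x <- validate_covariates(x)
  cov_names <- setdiff(names(x), c("district", "year"))
  sds <- purrr::map_dbl(x[cov_names], stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance covariate column(s): ",
         paste(cov_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  mus <- purrr::map_dbl(x[cov_names], mean)
  out <- x
  for (nm in cov_names) out[[nm]] <- (x[[nm]] - mus[[nm]]) / sds[[nm]]
  attr(out, "scaling") <- tibble::tibble(covariate = cov_names,
                                         mean = unname(mus), sd = unname(sds))
  out
}

#' @rdname standardize_covariates
#' @export
covariate_scaling <- function(x) {
  sc <- attr(x, "scaling")
  if (is.null(sc)) stop("no scaling metadata; was the table standardized?", call. = FALSE)
  sc
}

#' Invert standardization back to raw units
#'
#' @param x A standardized covariate tibble carrying scaling metadata.
#' @param scaling Optional scaling tibble, defaulting to `attr(x, "scaling")`.
#' @return The covariate tibble in raw units.
#' @export
unstandardize_covariates <- function(x, scaling = covariate_scaling(x)) {
  out <- x
  for (i in seq_len(nrow(scaling))) {
    nm <- scaling$covariate[i]
    out[[nm]] <- x[[nm]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(out, "scaling") <- NULL
  out
}

#' Pairwise collinearity screen
#'
#' Pearson correlations between all covariate pairs; pairs whose |r| exceeds
#' the threshold are returned, sorted by |r| descending. An empty result means
#' the screen passed (the analysis convention keeps every pairwise |r| at or
#' below 0.50).
#'
#' @param x A covariate tibble.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @return A tibble with columns `covariate1`, `covariate2`, `r`.
#' @export
collinearity_screen <- function(x, threshold = 0.5) {
  vals <- dplyr::select(x, -dplyr::any_of(c("district", "year")))
  if (ncol(vals) < 2) stop("need at least two covariates", call. = FALSE)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3) stop("need at least three complete rows", call. = FALSE)
  r <- stats::cor(as.matrix(vals))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble::tibble(
    covariate1 = rownames(r)[idx[, 1]],
    covariate2 = colnames(r)[idx[, 2]],
    r = r[idx]
  )
  out |>
    dplyr::filter(abs(.data$r) > threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
}

# ---- design specifications -------------------------------------------------

parse_design_term <- function(term) {
  parts <- strsplit(term, "*", fixed = TRUE)[[1]]
  if (length(parts) > 2) stop("bad design term (at most one '*'): ", term, call. = FALSE)
  parse_one <- function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) == 1) return(list(covariate = bits[1], lag = 0L))
    if (length(bits) == 2 && bits[2] == "lag1") return(list(covariate = bits[1], lag = 1L))
    stop("bad design term component: ", p, call. = FALSE)
  }
  lapply(parts, parse_one)
}

#' Design specification for recruitment covariate effects
#'
#' A design spec is an ordered list of terms written as `"name"` (main effect,
#' current year), `"name:lag1"` (previous year's value) or a pairwise
#' interaction `"a*b"` of two such components. Interactions are elementwise
#' products of the already-standardized parent columns.
#'
#' @param terms Character vector of term strings; names must be unique.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(terms) {
  if (anyDuplicated(terms)) {
    stop("duplicated design terms: ", paste(unique(terms[duplicated(terms)]), collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(terms, parse_design_term)
  structure(list(terms = terms, parsed = parsed), class = "design_spec")
}

#' @rdname design_spec
#' @param path A YAML file whose top level is a list of term strings.
#' @export
read_design_spec <- function(path) {
  design_spec(unlist(yaml::read_yaml(path)))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", length(x$terms), " terms\n", sep = "")
  cat(paste0("  ", x$terms, collapse = "\n"), "\n")
  invisible(x)
}

#' Default covariate designs
#'
#' The full term list of the original analysis is not public; this default is a
#' reconstruction containing every term the analysis names explicitly (spring
#' and summer precipitation, spring and summer time-integrated NDVI, current
#' and lagged winter snow-water equivalent, lagged summer precipitation and
#' NDVI, lion and bear harvest, wolf counts, and the named interactions with
#' winter severity), padded to 20 terms. The age-ratio design adds the
#' standardized adult-female harvest, giving 21 terms.
#'
#' @return A character vector of term strings.
#' @export
design_terms_population <- function() {
  c(
    "spring_precip", "summer_precip", "spring_ndvi", "summer_ndvi",
    "swe", "swe:lag1", "summer_precip:lag1", "summer_ndvi:lag1",
    "lions", "bears", "wolves",
    "summer_precip*swe", "spring_ndvi*swe",
    "lions*swe", "bears*swe", "wolves*swe",
    "summer_precip:lag1*swe:lag1", "summer_ndvi:lag1*swe:lag1",
    "spring_precip*swe", "spring_precip:lag1"
  )
}

#' @rdname design_terms_population
#' @export
design_terms_ageratio <- function() {
  c(design_terms_population(), "af_harvest")
}

#' Build a design matrix keyed by district-year
#'
#' One row per requested district-year; lag-1 components take the previous
#' year's covariate row of the same district, and interaction columns are
#' products of the standardized parents. The input table should already be
#' standardized (a zero covariate row is then the "average conditions"
#' profile).
#'
#' @param x A (standardized) covariate tibble.
#' @param spec A [design_spec()] or character vector of terms.
#' @param years Years to build rows for; defaults to all but the first year in
#'   `x` (lag-1 terms are undefined for the first year on record).
#' @return A tibble with `district`, `year` and one column per term, in spec
#'   order.
#' @export
build_design_matrix <- function(x, spec, years = NULL) {
  if (!inherits(spec, "design_spec")) spec <- design_spec(spec)
  cov_names <- setdiff(names(x), c("district", "year"))
  refs <- unique(unlist(lapply(spec$parsed, function(tt) vapply(tt, `[[`, "", "covariate"))))
  miss <- setdiff(refs, cov_names)
  if (length(miss) > 0) {
    stop("design references unknown covariates: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(years)) years <- sort(unique(x$year))[-1]
  base <- dplyr::filter(x, .data$year %in% years)
  prev <- x |>
    dplyr::mutate(year = .data$year + 1L) |>
    dplyr::filter(.data$year %in% years)
  needs_lag <- any(vapply(spec$parsed, function(tt) any(vapply(tt, `[[`, 0L, "lag") == 1L), TRUE))
  if (needs_lag) {
    gap <- dplyr::anti_join(base[c("district", "year")], prev[c("district", "year")],
                            by = c("district", "year"))
    if (nrow(gap) > 0) {
      stop("lag-1 terms need the prior year's covariate row; missing for: ",
           paste(paste0(gap$district, ":", gap$year), collapse = ", "), call. = FALSE)
    }
  }
  prev <- dplyr::rename_with(prev, ~ paste0(".lag1_", .x), -dplyr::all_of(c("district", "year")))
  joined <- dplyr::left_join(base, prev, by = c("district", "year"))
  col_of <- function(comp) {
    nm <- if (comp$lag == 1L) paste0(".lag1_", comp$covariate) else comp$covariate
    joined[[nm]]
  }
  out <- joined[c("district", "year")]
  for (i in seq_along(spec$terms)) {
    comps <- spec$parsed[[i]]
    v <- col_of(comps[[1]])
    if (length(comps) == 2) v <- v * col_of(comps[[2]])
    out[[spec$terms[i]]] <- v
  }
  out
}
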