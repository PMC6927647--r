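#' Read a spring survey table
#'
#' Reads district-year spring count and age/sex classification records from a
#' CSV file with columns `district`, `year`, `total_count`, `calves`,
#' `adult_females`, `adult_males`. Empty cells are missing values: a row may
#' carry a total count with no classification at all (all three class columns
#' empty), reflecting surveys where animals were counted but not classified.
#'
#' @param path Path to a CSV file (UTF-8, header row, empty string = missing).
#' @return A tibble with one row per district-year and a `classified_total`
#'   column (sum of the three class counts, `NA` when classification is
#'   missing).
#' @seealso [write_survey_table()], [validate_surveys()]
#' @export
read_survey_table <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      district = readr::col_character(),
      year = readr::col_integer(),
      total_count = readr::col_integer(),
      calves = readr::col_integer(),
      adult_females = readr::col_integer(),
      adult_males = readr::col_integer()
    ),
    na = c("", "NA")
  )
  validate_surveys(x)
}

#' Validate a survey tibble
#'
#' Checks non-negativity, joint presence of the classification columns, the
#' internal sum `calves + adult_females + adult_males = classified_total`, and
#' `classified_total <= total_count`. Adds/refreshes the `classified_total`
#' column.
#'
#' @param x A tibble with survey columns as in [read_survey_table()].
#' @return The validated tibble (invisibly the same data, with
#'   `classified_total`).
#' @export
validate_surveys <- function(x) {
  need <- c("district", "year", "total_count", "calves", "adult_females", "adult_males")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("survey table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste0(x$district, ":", x$year)
  if (anyDuplicated(key)) {
    stop("duplicated district-year rows: ", paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  cls <- cbind(x$calves, x$adult_females, x$adult_males)
  n_na <- rowSums(is.na(cls))
  bad <- which(n_na > 0 & n_na < 3)
  if (length(bad) > 0) {
    stop("classification columns must be jointly present or jointly missing: ",
         paste(key[bad], collapse = ", "), call. = FALSE)
  }
  neg <- which(apply(cbind(x$total_count, cls), 1, function(r) any(r < 0, na.rm = TRUE)))
  if (length(neg) > 0) {
    stop("negative counts in district-years: ", paste(key[neg], collapse = ", "), call. = FALSE)
  }
  classified_total <- rowSums(cls)
  over <- which(!is.na(classified_total) & !is.na(x$total_count) &
                  classified_total > x$total_count)
  if (length(over) > 0) {
    stop("classified_total exceeds total_count in district-years: ",
         paste(key[over], collapse = ", "), call. = FALSE)
  }
  x$classified_total <- as.integer(classified_total)
  tibble::as_tibble(x)
}

#' Read a harvest table
#'
#' District-year fall harvest of calves, adult females and adult males. Unlike
#' surveys the harvest series must be complete: one row for every district-year
#' of the modelled window.
#'
#' @param path Path to a CSV with columns `district`, `year`, `h_calves`,
#'   `h_adult_females`, `h_adult_males`.
#' @return A validated tibble.
#' @export
read_harvest_table <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      district = readr::col_character(),
      year = readr::col_integer(),
      h_calves = readr::col_integer(),
      h_adult_females = readr::col_integer(),
      h_adult_males = readr::col_integer()
    ),
    na = c("", "NA")
  )
  validate_harvest(x)
}

#' @rdname read_harvest_table
#' @param x A harvest tibble.
#' @export
validate_harvest <- function(x) {
  need <- c("district", "year", "h_calves", "h_adult_females", "h_adult_males")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("harvest table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  h <- cbind(x$h_calves, x$h_adult_females, x$h_adult_males)
  key <- paste0(x$district, ":", x$year)
  if (anyNA(h)) {
    stop("harvest values missing for district-years: ",
         paste(key[rowSums(is.na(h)) > 0], collapse = ", "), call. = FALSE)
  }
  if (any(h < 0)) {
    stop("negative harvest in district-years: ",
         paste(key[apply(h < 0, 1, any)], collapse = ", "), call. = FALSE)
  }
  yrs <- sort(unique(x$year))
  full <- tidyr::expand_grid(district = unique(x$district),
                             year = seq(min(yrs), max(yrs)))
  gap <- dplyr::anti_join(full, x, by = c("district", "year"))
  if (nrow(gap) > 0) {
    stop("harvest series must be continuous; missing district-years: ",
         paste(paste0(gap$district, ":", gap$year), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a covariate table
#'
#' One row per district-year; all columns other than `district` and `year` are
#' treated as raw covariates. Missing covariate cells are not allowed.
#'
#' @param path Path to a CSV file.
#' @return A tibble of raw covariate values.
#' @export
read_covariate_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    district = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  ), na = c("", "NA"))
  validate_covariates(x)
}

#' @rdname read_covariate_table
#' @param x A covariate tibble.
#' @export
validate_covariates <- function(x) {
  if (!all(c("district", "year") %in% names(x))) {
    stop("covariate table needs district and year columns", call. = FALSE)
  }
  vals <- dplyr::select(x, -dplyr::all_of(c("district", "year")))
  if (ncol(vals) == 0) stop("covariate table has no covariate columns", call. = FALSE)
  na_cols <- names(vals)[purrr::map_lgl(vals, anyNA)]
  if (length(na_cols) > 0) {
    stop("missing covariate values in columns: ", paste(na_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Write the tabular inputs back to CSV
#'
#' Round-trips losslessly through the corresponding readers, including
#' missingness (written as empty cells).
#'
#' @param x The tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, dplyr::all_of(c("district", "year", "total_count", "calves",
                                     "adult_females", "adult_males"))),
    path, na = "")
  invisible(path)
}

#' @rdname write_survey_table
#' @export
write_harvest_table <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, dplyr::all_of(c("district", "year", "h_calves",
                                     "h_adult_females", "h_adult_males"))),
    path, na = "")
  invisible(path)
}

#' @rdname write_survey_table
#' @export
write_covariate_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Observed calves per 100 adult females
#'
#' The traditional recruitment index. Vectorized; returns `NA` when the
#' classification is missing or no adult females were classified (the ratio is
#' then undefined, not an error).
#'
#' @param calves,adult_females Classified counts.
#' @return `100 * calves / adult_females`, `NA` where undefined.
#' @export
observed_age_ratio <- function(calves, adult_females) {
  out <- ifelse(!is.na(calves) & !is.na(adult_females) & adult_females > 0,
                100 * calves / adult_females, NA_real_)
  as.numeric(out)
}

#' Age-ratio records from a survey table
#'
#' Drops district-years without a usable classification and appends the
#' observed calves:100-females ratio.
#'
#' @param surveys A validated survey tibble.
#' @return A tibble of classification-complete rows with an `age_ratio` column.
#' @export
age_ratio_table <- function(surveys) {
  surveys |>
    dplyr::mutate(age_ratio = observed_age_ratio(.data$calves, .data$adult_females)) |>
    dplyr::filter(!is.na(.data$age_ratio))
}
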