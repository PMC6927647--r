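#' Pixel time series helpers
#'
#' A pixel series is a tibble with a strictly increasing `day` (day-of-year)
#' column and a `value` column (NDVI in \[-1, 1\], precipitation or snow-water
#' equivalent in mm).
#'
#' @param day Integer day-of-year vector, strictly increasing.
#' @param value Numeric values.
#' @return A tibble with columns `day`, `value`.
#' @export
pixel_series <- function(day, value) {
  if (length(day) != length(value)) stop("day and value lengths differ", call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  tibble::tibble(day = as.integer(day), value = as.numeric(value))
}

running_mean <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

upper_envelope <- function(day, v, tol = 1e-9, max_iter = 100L) {
  n <- length(v)
  if (n < 3) return(v)
  interior <- 2:(n - 1L)
  for (iter in seq_len(max_iter)) {
    # chord value at interior point i from its neighbours i-1, i+1 (by day)
    chord <- v[interior - 1L] + (v[interior + 1L] - v[interior - 1L]) *
      (day[interior] - day[interior - 1L]) / (day[interior + 1L] - day[interior - 1L])
    lifted <- pmax(v[interior], chord)
    delta <- max(lifted - v[interior])
    v[interior] <- lifted
    if (delta < tol) break
  }
  v
}

#' Smooth an NDVI pixel series
#'
#' A centered running mean (edge windows shrink symmetrically) followed by an
#' iterative upper-envelope correction: any interior point lying below the
#' straight line joining its two neighbours (by day) is lifted onto that line,
#' repeated to convergence. The envelope step encodes the assumption that
#' errant NDVI values (cloud, snow contamination) are biased low; it never
#' lowers a value and is idempotent once converged.
#'
#' @param series A [pixel_series()] tibble.
#' @param window Odd running-mean width in observations; `1` skips smoothing.
#' @return The smoothed series tibble.
#' @export
smooth_series <- function(series, window = 3L) {
  window <- as.integer(window)
  if (window != 1L && window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > nrow(series)) stop("window larger than series", call. = FALSE)
  v <- series$value
  if (window >= 3L) v <- running_mean(v, window)
  v <- upper_envelope(series$day, v)
  tibble::tibble(day = series$day, value = v)
}

season_window <- function() c(start = 60L, end = 304L)  # March 1 .. October 31 (non-leap)

#' Detect the growing season by the 50%-of-maximum threshold
#'
#' Evaluated inside the March-October window (days 60-304): the annual maximum
#' is taken within the window; the season starts at the first observation at or
#' above half that maximum and ends at the last observation at or above it
#' before the series next falls below (clamped to the window's final
#' observation when the series never falls back).
#'
#' @param series A smoothed [pixel_series()] covering at least March-October.
#' @return A one-row tibble with `start_day`, `end_day`, `annual_max`.
#' @export
detect_growing_season <- function(series) {
  w <- season_window()
  inwin <- dplyr::filter(series, .data$day >= w[["start"]], .data$day <= w[["end"]])
  if (nrow(inwin) == 0) stop("series has no observations in the March-October window", call. = FALSE)
  m <- max(inwin$value)
  if (m <= 0) stop("no growing season: all values are <= 0 in the window", call. = FALSE)
  thr <- 0.5 * m
  above <- inwin$value >= thr
  i_start <- which(above)[1]
  after <- seq(i_start, nrow(inwin))
  i_below <- after[which(!above[after])[1]]
  i_end <- if (is.na(i_below)) nrow(inwin) else i_below - 1L
  tibble::tibble(start_day = inwin$day[i_start], end_day = inwin$day[i_end], annual_max = m)
}

#' Time-integrated NDVI, split into spring and summer
#'
#' The cumulative sum of differences between observed NDVI and its value at the
#' start of the growing season, split at a calendar boundary (June 30 / July 1,
#' day 181 in non-leap years): spring integrates observations in
#' `[start, split_day]`, summer those in `(split_day, end]`. The two components
#' always add to the whole-season integral; a split outside the season zeroes
#' one component rather than erroring.
#'
#' @param series A smoothed [pixel_series()].
#' @param season A season tibble from [detect_growing_season()].
#' @param split_day Day-of-year boundary between the two periods.
#' @return A one-row tibble with `spring_ti` and `summer_ti`.
#' @export
time_integrated_ndvi <- function(series, season, split_day = 181L) {
  v0 <- series$value[series$day == season$start_day]
  if (length(v0) != 1) stop("season start day not found in series", call. = FALSE)
  inseason <- dplyr::filter(series, .data$day >= season$start_day, .data$day <= season$end_day)
  d <- inseason$value - v0
  spring <- sum(d[inseason$day <= split_day])
  summer <- sum(d[inseason$day > split_day])
  tibble::tibble(spring_ti = spring, summer_ti = summer)
}

#' Windowed cumulative sum (precipitation)
#'
#' Sum of values with day in `[start_day, end_day]`, inclusive. The analysis
#' convention uses May 1 - June 30 (neonatal period) and July 1 - September 30
#' (juvenile independence period).
#'
#' @param series A [pixel_series()].
#' @param start_day,end_day Inclusive day-of-year bounds.
#' @return The scalar sum (same units as `value`).
#' @export
windowed_cumulative <- function(series, start_day, end_day) {
  keep <- series$day >= start_day & series$day <= end_day
  if (!any(keep)) stop("no observations in window [", start_day, ", ", end_day, "]", call. = FALSE)
  sum(series$value[keep])
}

#' Cumulative winter snow-water equivalent
#'
#' Sums daily SWE (mm) over the winter window December 1 (year t-1) through
#' April 30 (year t) and reports the total in metre-days (mm-days / 1000), the
#' scale on which cumulative SWE severity indices are quoted. The series is a
#' tibble with a `date` (Date) column and `value` in mm; every day of the
#' window must be present.
#'
#' @param series A tibble with `date` and `value` columns.
#' @param winter_year Calendar year t of the window's April side; defaults to
#'   the latest year in the series.
#' @return Cumulative SWE in m-days.
#' @export
cumulative_swe <- function(series, winter_year = NULL) {
  if (!inherits(series$date, "Date")) stop("series$date must be a Date column", call. = FALSE)
  if (is.null(winter_year)) winter_year <- max(as.integer(format(series$date, "%Y")))
  lo <- as.Date(sprintf("%d-12-01", winter_year - 1L))
  hi <- as.Date(sprintf("%d-04-30", winter_year))
  need <- seq(lo, hi, by = "day")
  have <- series$date[series$date >= lo & series$date <= hi]
  missing_days <- setdiff(as.character(need), as.character(have))
  if (length(missing_days) > 0) {
    stop("winter window not fully covered; missing days: ",
         paste(utils::head(missing_days, 5), collapse = ", "),
         if (length(missing_days) > 5) sprintf(" (+%d more)", length(missing_days) - 5) else "",
         call. = FALSE)
  }
  sum(series$value[series$date >= lo & series$date <= hi]) / 1000
}

#' Mean over the pixels of a district range
#'
#' Per-pixel summaries (cumulative precipitation, time-integrated NDVI,
#' cumulative SWE) are aggregated to the district scale by their arithmetic
#' mean.
#'
#' @param values Numeric per-pixel results; at least one.
#' @return The mean.
#' @export
district_mean <- function(values) {
  if (length(values) == 0) stop("no pixels to aggregate", call. = FALSE)
  mean(values)
}
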