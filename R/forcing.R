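#' Daily forcing series
#'
#' Bundles daily rainfall and potential evapotranspiration (PET) depths, both
#' in cm per day. Depth-to-volume conversions happen in the hydrology module
#' via wetted and contributing areas.
#'
#' @param rain non-negative daily rainfall depths (cm d^-1).
#' @param pet non-negative daily PET depths (cm d^-1); recycled if scalar.
#' @return Object of class \code{"forcing_series"}: a data frame with columns
#'   \code{t} (0-based day index), \code{rain}, \code{pet}.
#' @export
forcing_series <- function(rain, pet) {
  rain <- as.numeric(rain)
  if (length(pet) == 1L) pet <- rep(as.numeric(pet), length(rain))
  pet <- as.numeric(pet)
  if (length(rain) != length(pet))
    stop("rain and pet must have equal length")
  if (any(!is.finite(rain)) || any(rain < 0))
    stop("rainfall depths must be finite and >= 0")
  if (any(!is.finite(pet)) || any(pet < 0))
    stop("PET depths must be finite and >= 0")
  structure(data.frame(t = seq_along(rain) - 1L, rain = rain, pet = pet),
            class = c("forcing_series", "data.frame"))
}

#' Generate marked-Poisson daily rainfall
#'
#' Rainfall arrives as a marked Poisson process aggregated to daily totals:
#' the number of events on each day is Poisson with mean
#' \code{lambda_freq} (events d^-1) and each event carries an exponentially
#' distributed depth with mean \code{alpha} (cm). The daily total is then a
#' compound Poisson sum with mean \code{alpha * lambda_freq} and variance
#' \code{2 * alpha^2 * lambda_freq}.
#'
#' @param alpha mean event depth (cm), > 0.
#' @param lambda_freq mean event frequency (d^-1), >= 0.
#' @param t_days number of days.
#' @param seed optional integer seed.
#' @return Numeric vector of daily depths (cm d^-1), length \code{t_days}.
#' @export
generate_rainfall <- function(alpha, lambda_freq, t_days, seed = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (lambda_freq < 0) stop("lambda_freq must be >= 0")
  if (t_days < 0) stop("t_days must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_events <- stats::rpois(t_days, lambda_freq)
  depth <- numeric(t_days)
  pos <- n_events > 0
  # sum of k iid Exp(mean alpha) marks is Gamma(shape = k, scale = alpha)
  depth[pos] <- stats::rgamma(sum(pos), shape = n_events[pos], scale = alpha)
  depth
}

#' Thornthwaite potential evapotranspiration
#'
#' Computes monthly PET from monthly mean air temperatures by Thornthwaite's
#' formula and spreads it uniformly over each month's days. The annual heat
#' index is \code{I = sum((T_m/5)^1.514)} over months with \code{T_m > 0};
#' monthly PET (mm) is \code{16 (L_m/12) (N_m/30) (10 T_m / I)^a} with
#' \code{a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239}, where
#' \code{L_m} is the mean day length (hours, from latitude and mid-month
#' solar declination) and \code{N_m} the number of days in the month.
#' Months with \code{T_m <= 0} contribute zero PET; if every month is
#' freezing the whole series is zero.
#'
#' @param monthly_mean_temp 12 monthly mean temperatures (deg C), Jan-Dec.
#' @param latitude degrees, |latitude| <= 66.5 (day-length formula validity).
#' @param t_days length of the daily series to produce; days cycle through a
#'   365-day (non-leap) calendar starting 1 January.
#' @return Numeric vector of daily PET (cm d^-1), length \code{t_days}.
#' @export
thornthwaite_pet <- function(monthly_mean_temp, latitude, t_days = 365L) {
  if (length(monthly_mean_temp) != 12L)
    stop("monthly_mean_temp must have 12 values (Jan-Dec)")
  if (abs(latitude) > 66.5)
    stop("|latitude| must be <= 66.5 degrees")
  Tm <- as.numeric(monthly_mean_temp)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  I <- sum((Tm[Tm > 0] / 5)^1.514)
  daily_by_month <- numeric(12)
  if (I > 0) {
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    L <- day_length_hours(latitude, mid_month_doy())
    pet_mm_month <- ifelse(Tm > 0,
                           16 * (L / 12) * (ndays / 30) * (10 * Tm / I)^a,
                           0)
    daily_by_month <- pet_mm_month / 10 / ndays  # mm/month -> cm/day
  }
  month_of_doy <- rep.int(seq_len(12), ndays)
  doy <- ((seq_len(t_days) - 1L) %% 365L) + 1L
  daily_by_month[month_of_doy[doy]]
}

mid_month_doy <- function() {
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(ndays) - ndays / 2
}

day_length_hours <- function(latitude, doy) {
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  24 * ws / pi
}

#' Read a daily forcing table
#'
#' Delimited text with header columns \code{date} (ISO yyyy-mm-dd),
#' \code{rain_cm} and optionally \code{pet_cm}. The series must be gap-free
#' and strictly daily; negative depths, duplicate or missing dates are
#' rejected naming the first offending row.
#'
#' @param path file path.
#' @param pet constant PET (cm d^-1) used when the table has no
#'   \code{pet_cm} column.
#' @return A [forcing_series()].
#' @export
read_forcing <- function(path, pet = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("date", "rain_cm") %in% names(df)))
    stop("forcing table must have columns 'date' and 'rain_cm'")
  dates <- as.Date(df$date)
  if (any(is.na(dates)))
    stop("unparseable date at row ", which(is.na(dates))[1])
  if (nrow(df) > 1) {
    dd <- as.integer(diff(dates))
    if (any(dd == 0))
      stop("duplicate date ", dates[which(dd == 0)[1] + 1],
           " at row ", which(dd == 0)[1] + 1)
    if (any(dd != 1))
      stop("date gap between ", dates[which(dd != 1)[1]], " and ",
           dates[which(dd != 1)[1] + 1], " (row ", which(dd != 1)[1] + 1, ")")
  }
  if (any(df$rain_cm < 0))
    stop("negative rainfall at row ", which(df$rain_cm < 0)[1])
  if ("pet_cm" %in% names(df)) {
    if (any(df$pet_cm < 0))
      stop("negative PET at row ", which(df$pet_cm < 0)[1])
    pet <- df$pet_cm
  } else if (is.null(pet)) {
    stop("table has no 'pet_cm' column and no constant 'pet' was supplied")
  }
  forcing_series(df$rain_cm, pet)
}
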