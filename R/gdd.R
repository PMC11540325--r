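#' Cumulative growing degree days per harvest cycle
#'
#' Thermal time is accumulated from daily temperature extremes as
#' `(tmax + tmin) / 2 - t_base`, with a base temperature of 4 degrees C by
#' default.  Negative daily increments (cold days) are clamped at zero
#' unless `clamp = FALSE`.  Accumulation restarts the day after each
#' harvest: the first cycle runs from the first weather record (planting)
#' up to and including the first harvest date, the next cycle starts the
#' following day.
#'
#' @param weather data frame with columns `date` (Date or coercible),
#'   `tmax`, `tmin` in degrees C.  Days must be consecutive; gaps are an
#'   error (no silent interpolation).
#' @param harvests vector of harvest dates splitting the record into
#'   cycles; may be empty for a single cycle.
#' @param t_base base temperature in degrees C.
#' @param clamp clamp negative daily increments at zero (standard
#'   agronomic practice).  The raw mean-minus-base increment can go
#'   negative on cold days.
#' @return data frame: `date`, `cycle` (1-based), `gdd_daily`, `gdd_cum`
#'   (cumulative within cycle).
#' @examples
#' w <- data.frame(date = as.Date("2020-05-01") + 0:9,
#'                 tmax = 20, tmin = 10)
#' g <- cumulative_gdd(w, harvests = as.Date("2020-05-06"))
#' subset(g, cycle == 2)$gdd_cum  # 11, 22, ...
#' @export
cumulative_gdd <- function(weather, harvests = NULL, t_base = 4,
                           clamp = TRUE) {
  if (!all(c("date", "tmax", "tmin") %in% names(weather))) {
    stop("weather needs columns date, tmax, tmin")
  }
  weather$date <- as.Date(weather$date)
  weather <- weather[order(weather$date), , drop = FALSE]
  if (anyDuplicated(weather$date)) {
    stop("duplicated dates in weather record")
  }
  if (any(weather$tmax < weather$tmin, na.rm = TRUE)) {
    stop("tmax < tmin on ",
         paste(weather$date[which(weather$tmax < weather$tmin)],
               collapse = ", "))
  }
  full <- seq(min(weather$date), max(weather$date), by = "day")
  gaps <- setdiff(as.character(full), as.character(weather$date))
  if (length(gaps)) {
    stop("weather record has missing days: ",
         paste(utils::head(gaps, 10), collapse = ", "),
         if (length(gaps) > 10) sprintf(" (and %d more)", length(gaps) - 10))
  }

  inc <- (weather$tmax + weather$tmin) / 2 - t_base
  if (clamp) inc <- pmax(inc, 0)

  harvests <- sort(as.Date(harvests))
  # cycle k covers dates after harvest k-1 up to and including harvest k
  cycle <- findInterval(weather$date - 1, harvests) + 1L
  gdd_cum <- stats::ave(inc, cycle, FUN = cumsum)
  data.frame(date = weather$date, cycle = cycle,
             gdd_daily = inc, gdd_cum = gdd_cum)
}

#' Look up cumulative GDD on given dates
#'
#' @param gdd result of [cumulative_gdd()].
#' @param dates dates to look up (must be present in the record).
#' @return data frame `date`, `cycle`, `gdd_cum`.
#' @export
gdd_on <- function(gdd, dates) {
  dates <- as.Date(dates)
  idx <- match(dates, gdd$date)
  if (anyNA(idx)) {
    stop("dates outside weather record: ",
         paste(dates[is.na(idx)], collapse = ", "))
  }
  data.frame(date = dates, cycle = gdd$cycle[idx],
             gdd_cum = gdd$gdd_cum[idx])
}
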