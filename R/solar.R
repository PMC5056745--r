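# Solar geometry: sunrise/sunset/astronomical twilight per station-date,
# diel-period classification, the sun-time transform that anchors sunrise
# at 06:00 and sunset at 18:00, and diel-period availability.
#
# The algorithm is the NOAA low-precision geometry (solar declination +
# equation of time + hour angle), accurate to about +/-2 minutes at
# mid-latitudes, which is immaterial at the resolution of camera-trap
# activity analysis.

deg2rad <- function(x) x * pi / 180

# fractional-year angle (radians) at local noon of a date
solar_gamma <- function(date) {
  2 * pi / 365 * (lubridate::yday(date) - 1)
}

solar_declination <- function(g) {
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) - 0.006758 * cos(2 * g) +
    0.000907 * sin(2 * g) - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

equation_of_time <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Sunrise/sunset-type solar event times
#'
#' Clock times (local standard, decimal hours) at which the sun crosses a
#' given altitude, for each (date, latitude, longitude). The default
#' altitude of -0.833 degrees gives apparent sunrise/sunset (refraction plus
#' solar radius); -18 degrees gives astronomical twilight. Dates without a
#' crossing (polar day/night) are flagged `no_event`, never silently
#' defaulted.
#'
#' @param date `Date` vector (recycled against the coordinates).
#' @param latitude,longitude station coordinates in degrees.
#' @param altitude_deg solar altitude defining the event (degrees).
#' @param tz_offset hours east of UTC of the local standard clock
#'   (default 8, China Standard Time).
#' @return a tibble with `date`, `rise`, `set` (decimal hours, `NA` when
#'   flagged) and `no_event`.
#' @export
solar_event_times <- function(date, latitude, longitude,
                              altitude_deg = -0.8333, tz_offset = 8) {
  n <- max(length(date), length(latitude), length(longitude))
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(latitude, n)
  lon <- rep_len(longitude, n)
  g <- solar_gamma(date)
  decl <- solar_declination(g)
  eqt <- equation_of_time(g)
  phi <- deg2rad(lat)
  cos_h <- (sin(deg2rad(altitude_deg)) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  no_event <- abs(cos_h) > 1
  ha <- acos(pmin(1, pmax(-1, cos_h))) * 180 / pi # degrees
  noon <- 12 - lon / 15 + tz_offset - eqt / 60
  rise <- ifelse(no_event, NA_real_, noon - ha / 15)
  set <- ifelse(no_event, NA_real_, noon + ha / 15)
  tibble::tibble(date = date, rise = rise, set = set, no_event = no_event)
}

#' Diel schedule for station-dates
#'
#' Per date and coordinate: start of morning astronomical twilight
#' (`dawn_start`, sun at -18 degrees rising), `sunrise`, `sunset` (both at
#' -0.833 degrees) and end of evening astronomical twilight (`dusk_end`),
#' all as local-standard decimal hours.
#'
#' @inheritParams solar_event_times
#' @return a tibble with `date`, `latitude`, `longitude`, `dawn_start`,
#'   `sunrise`, `sunset`, `dusk_end`.
#' @export
diel_schedule <- function(date, latitude, longitude, tz_offset = 8) {
  sun <- solar_event_times(date, latitude, longitude, -0.8333, tz_offset)
  twi <- solar_event_times(date, latitude, longitude, -18, tz_offset)
  tibble::tibble(
    date = sun$date,
    latitude = rep_len(latitude, nrow(sun)),
    longitude = rep_len(longitude, nrow(sun)),
    dawn_start = twi$rise, sunrise = sun$rise,
    sunset = sun$set, dusk_end = twi$set
  )
}

#' Classify clock hours into diel periods
#'
#' Crepuscular is dawn twilight (`[dawn_start, sunrise)`) plus dusk
#' twilight (`[sunset, dusk_end)`); diurnal is `[sunrise, sunset)`;
#' nocturnal is the remainder of the 24-h cycle.
#'
#' @param hour clock hour of day (decimal, `[0, 24)`).
#' @param dawn_start,sunrise,sunset,dusk_end schedule columns (decimal
#'   hours, see [diel_schedule()]).
#' @return character vector in
#'   `c("crepuscular", "diurnal", "nocturnal")`.
#' @export
classify_diel_period <- function(hour, dawn_start, sunrise, sunset, dusk_end) {
  if (anyNA(c(dawn_start, sunrise, sunset, dusk_end))) {
    abort("diel schedule has missing solar events; cannot classify")
  }
  dplyr::case_when(
    (hour >= dawn_start & hour < sunrise) |
      (hour >= sunset & hour < dusk_end) ~ "crepuscular",
    hour >= sunrise & hour < sunset ~ "diurnal",
    TRUE ~ "nocturnal"
  )
}

#' Transform clock time to relative sun time
#'
#' Rescales the clock hour so that the day's sunrise maps to 06:00 and its
#' sunset to 18:00 (linear within day and within night), removing the
#' seasonal variation of photoperiod. Night hours interpolate between the
#' same evening's sunset and the next morning's sunrise.
#'
#' @param time POSIXct clock times (local standard, stored as UTC).
#' @param latitude,longitude coordinates in degrees (recycled).
#' @param tz_offset hours east of UTC.
#' @return numeric vector of sun-time hours in `[0, 24)`.
#' @export
sun_time <- function(time, latitude, longitude, tz_offset = 8) {
  n <- length(time)
  lat <- rep_len(latitude, n)
  lon <- rep_len(longitude, n)
  date <- as.Date(lubridate::floor_date(time, "day"))
  h <- clock_hour(time)
  today <- solar_event_times(date, lat, lon, tz_offset = tz_offset)
  nxt <- solar_event_times(date + 1, lat, lon, tz_offset = tz_offset)
  prv <- solar_event_times(date - 1, lat, lon, tz_offset = tz_offset)
  if (any(today$no_event | nxt$no_event | prv$no_event)) {
    abort("sun does not rise/set on some dates; sun time undefined")
  }
  day_len <- today$set - today$rise
  if (any(day_len <= 0)) abort("zero-length day interval in sun-time transform")
  out <- numeric(n)
  in_day <- h >= today$rise & h < today$set
  out[in_day] <- 6 + 12 * (h[in_day] - today$rise[in_day]) / day_len[in_day]
  evening <- !in_day & h >= today$set
  night_len_e <- nxt$rise + 24 - today$set
  if (any(night_len_e <= 0)) abort("zero-length night interval in sun-time transform")
  out[evening] <- 18 + 12 * (h[evening] - today$set[evening]) / night_len_e[evening]
  morning <- !in_day & h < today$rise
  night_len_m <- today$rise + 24 - prv$set
  out[morning] <- 18 +
    12 * (h[morning] + 24 - prv$set[morning]) / night_len_m[morning]
  out %% 24
}

# inverse of the sun-time transform: clock hour (possibly >= 24, meaning
# the next calendar date) for a sun-time hour on a given date
sun_time_inverse <- function(sun_hour, date, latitude, longitude,
                             tz_offset = 8) {
  n <- length(sun_hour)
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(latitude, n)
  lon <- rep_len(longitude, n)
  today <- solar_event_times(date, lat, lon, tz_offset = tz_offset)
  nxt <- solar_event_times(date + 1, lat, lon, tz_offset = tz_offset)
  prv <- solar_event_times(date - 1, lat, lon, tz_offset = tz_offset)
  s <- sun_hour %% 24
  out <- numeric(n)
  in_day <- s >= 6 & s < 18
  out[in_day] <- today$rise[in_day] +
    (s[in_day] - 6) / 12 * (today$set[in_day] - today$rise[in_day])
  evening <- s >= 18
  night_len_e <- nxt$rise + 24 - today$set
  out[evening] <- today$set[evening] +
    (s[evening] - 18) / 12 * night_len_e[evening]
  morning <- s < 6
  night_len_m <- today$rise + 24 - prv$set
  out[morning] <- prv$set[morning] - 24 +
    (s[morning] + 6) / 12 * night_len_m[morning]
  out
}

#' Annotate detection events with solar context
#'
#' Joins station coordinates from the deployments, then adds the sun-time
#' hour and diel-period classification of each event.
#'
#' @param events detection events (see [independent_events()]).
#' @param deployments deployments providing station coordinates.
#' @param tz_offset hours east of UTC.
#' @return `events` with `latitude`, `longitude`, `sun_time` (hours) and
#'   `diel_period` columns added.
#' @export
annotate_events <- function(events, deployments, tz_offset = 8) {
  coords <- deployments |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      latitude = dplyr::first(.data$latitude),
      longitude = dplyr::first(.data$longitude)
    )
  out <- dplyr::inner_join(events, coords, by = "station_id")
  if (nrow(out) < nrow(events)) {
    warn(sprintf(
      "%d event(s) at stations with no deployment record were dropped",
      nrow(events) - nrow(out)
    ))
  }
  if (nrow(out) == 0) {
    return(dplyr::mutate(out, sun_time = numeric(0), diel_period = character(0)))
  }
  date <- as.Date(lubridate::floor_date(out$event_time, "day"))
  sched <- diel_schedule(date, out$latitude, out$longitude, tz_offset)
  out$sun_time <- sun_time(out$event_time, out$latitude, out$longitude, tz_offset)
  out$diel_period <- classify_diel_period(
    clock_hour(out$event_time),
    sched$dawn_start, sched$sunrise, sched$sunset, sched$dusk_end
  )
  out
}

# expand deployments into station-dates with the active clock-hour window
# clipped to the deployment interval
active_station_dates <- function(deployments) {
  deployments |>
    dplyr::mutate(.dep = dplyr::row_number()) |>
    dplyr::mutate(date = purrr::map2(.data$start, .data$end, function(s, e) {
      seq(as.Date(lubridate::floor_date(s, "day")),
          as.Date(lubridate::floor_date(e - lubridate::seconds(1), "day")),
          by = "day")
    })) |>
    tidyr::unnest("date") |>
    dplyr::mutate(
      from = pmax(0, as.numeric(
        .data$start - lubridate::as_datetime(.data$date), units = "hours"
      )),
      to = pmin(24, as.numeric(
        .data$end - lubridate::as_datetime(.data$date), units = "hours"
      ))
    ) |>
    dplyr::filter(.data$to > .data$from)
}

interval_overlap <- function(a_lo, a_hi, b_lo, b_hi) {
  pmax(0, pmin(a_hi, b_hi) - pmax(a_lo, b_lo))
}

#' Diel-period availability over a survey
#'
#' The availability of each diel period is the summed duration of that
#' period over all active station-dates (first and last days clipped to
#' the deployment interval), divided by the summed active time. Seasons can
#' be restricted with `season`.
#'
#' @param deployments deployments with coordinates.
#' @param season optional `"warm"` or `"winter"` restriction.
#' @param tz_offset hours east of UTC.
#' @return a tibble (`period`, `hours`, `proportion`) of class
#'   `availability`; proportions sum to 1.
#' @export
period_availability <- function(deployments, season = NULL, tz_offset = 8) {
  sd <- active_station_dates(deployments)
  if (!is.null(season)) {
    sd <- dplyr::filter(sd, season_of_month(lubridate::month(.data$date)) == !!season)
  }
  if (nrow(sd) == 0) abort("no active station-dates after filtering")
  sch <- diel_schedule(sd$date, sd$latitude, sd$longitude, tz_offset)
  if (anyNA(sch$dawn_start) || anyNA(sch$sunrise)) {
    abort("solar events undefined on some station-dates")
  }
  crep <- interval_overlap(sd$from, sd$to, sch$dawn_start, sch$sunrise) +
    interval_overlap(sd$from, sd$to, sch$sunset, sch$dusk_end)
  diur <- interval_overlap(sd$from, sd$to, sch$sunrise, sch$sunset)
  noct <- (sd$to - sd$from) - crep - diur
  period_hours <- c(crepuscular = sum(crep), diurnal = sum(diur),
                    nocturnal = sum(noct))[DIEL_PERIODS]
  out <- tibble::tibble(
    period = factor(DIEL_PERIODS, levels = DIEL_PERIODS),
    hours = as.numeric(period_hours),
    proportion = as.numeric(period_hours) / sum(period_hours)
  )
  class(out) <- c("availability", class(out))
  out
}

# availability as a named proportion vector in canonical period order
as_availability <- function(x) {
  if (inherits(x, "data.frame")) {
    assert_columns(x, c("period", "proportion"), "availability")
    v <- setNames(x$proportion, as.character(x$period))[DIEL_PERIODS]
  } else {
    v <- x[DIEL_PERIODS]
    if (anyNA(names(v))) v <- setNames(as.numeric(x)[1:3], DIEL_PERIODS)
  }
  if (anyNA(v)) abort("availability must cover crepuscular, diurnal, nocturnal")
  if (abs(sum(v) - 1) > 1e-6) abort("availability proportions must sum to 1")
  v
}
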