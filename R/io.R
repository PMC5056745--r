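# Ingest of tabulated camera-trap records, the detection-independence
# filter, survey-effort accounting and monthly relative activity indices.
#
# Clock times are local standard time for the survey region (no daylight
# saving). They are stored as POSIXct labelled UTC so that no timezone
# database rules are ever applied; the UTC offset matters only to the solar
# module and is carried separately.

default_photo_schema <- c(
  station_id = "station_id", species = "species",
  timestamp = "timestamp", n_individuals = "n_individuals"
)

default_deployment_schema <- c(
  station_id = "station_id", latitude = "latitude", longitude = "longitude",
  start = "start", end = "end", camera_speed = "camera_speed",
  lure_dates = "lure_dates"
)

parse_clock_time <- function(x) {
  lubridate::parse_date_time(
    x, orders = c("Ymd HMS", "Ymd HM", "Ymd", "mdY HMS", "mdY HM"),
    tz = "UTC", quiet = TRUE
  )
}

apply_schema <- function(df, schema, defaults, what) {
  schema <- utils::modifyList(as.list(defaults), as.list(schema %||% list()))
  required <- names(defaults)
  for (canon in required) {
    src <- schema[[canon]]
    if (!src %in% names(df)) next
    df[[canon]] <- df[[src]]
  }
  df
}

#' Read photo records
#'
#' Reads a delimited table of camera-trap photographs into the canonical
#' photo-record layout (`station_id`, `species`, `timestamp`,
#' `n_individuals`). Rows whose timestamp cannot be parsed, or whose
#' individual count is missing or non-positive, are collected into a
#' rejects table attached as the `"rejects"` attribute — never silently
#' dropped.
#'
#' @param path path to a CSV/TSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(timestamp = "DateTime", species = "Species")`.
#' @param quiet suppress the informational row-count message.
#' @return a tibble of photo records with attribute `"rejects"`.
#' @export
read_photo_records <- function(path, schema = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("empty input: %s has no data rows", path))
  df <- apply_schema(df, schema, default_photo_schema, "photo records")
  assert_columns(df, c("station_id", "species", "timestamp"), "photo records")
  if (!"n_individuals" %in% names(df)) df$n_individuals <- 1L
  as_photo_records(df, quiet = quiet, source = path)
}

#' Coerce a data frame to photo records
#'
#' The in-memory counterpart of [read_photo_records()]: validates columns,
#' parses timestamps and splits off a rejects table.
#'
#' @param df data frame with `station_id`, `species`, `timestamp` and
#'   optionally `n_individuals`.
#' @param quiet suppress messages.
#' @param source label used in messages.
#' @return a tibble of photo records with attribute `"rejects"`.
#' @export
as_photo_records <- function(df, quiet = FALSE, source = "photo records") {
  assert_columns(df, c("station_id", "species", "timestamp"), source)
  if (!"n_individuals" %in% names(df)) df$n_individuals <- 1L
  ts <- if (inherits(df$timestamp, "POSIXct")) {
    lubridate::with_tz(df$timestamp, "UTC")
  } else {
    parse_clock_time(df$timestamp)
  }
  n_ind <- suppressWarnings(as.numeric(df$n_individuals))
  bad_ts <- is.na(ts)
  bad_n <- !bad_ts & (is.na(n_ind) | n_ind < 1)
  reason <- dplyr::case_when(
    bad_ts ~ "unparseable timestamp",
    bad_n ~ "invalid n_individuals",
    TRUE ~ NA_character_
  )
  bad <- !is.na(reason)
  rejects <- tibble::tibble(
    row = which(bad),
    reason = reason[bad],
    station_id = as.character(df$station_id)[bad],
    raw_timestamp = as.character(df$timestamp)[bad]
  )
  keep <- !bad
  out <- tibble::tibble(
    station_id = as.character(df$station_id)[keep],
    species = as.character(df$species)[keep],
    timestamp = ts[keep],
    n_individuals = as.integer(n_ind[keep])
  )
  if (!quiet) {
    inform(sprintf(
      "%s: %d records parsed, %d rejected", source, nrow(out), nrow(rejects)
    ))
  }
  attr(out, "rejects") <- rejects
  out
}

parse_lure_dates <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(as.Date(character(0)))
    sort(as.Date(trimws(strsplit(as.character(s), ";")[[1]])))
  })
}

#' Read deployments
#'
#' Reads a delimited table of camera deployments (`station_id`, `latitude`,
#' `longitude`, `start`, `end`, `camera_speed`, `lure_dates`). `lure_dates`
#' is a `;`-separated list of dates the scent lure was applied; when the
#' column is absent each deployment is assumed lured at setup, the standard
#' baited-survey protocol. Deployments with non-positive span are rejected
#' with reason `"negative span"`.
#'
#' @inheritParams read_photo_records
#' @param fallback_coords optional `c(latitude, longitude)` used for
#'   stations missing coordinates (a study-area centroid); without it such
#'   stations are an error because the solar computations need coordinates.
#' @return a tibble of deployments with attribute `"rejects"`; `lure_dates`
#'   is a list-column of `Date` vectors.
#' @export
read_deployments <- function(path, schema = NULL, fallback_coords = NULL,
                             quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("empty input: %s has no data rows", path))
  df <- apply_schema(df, schema, default_deployment_schema, "deployments")
  as_deployments(df, fallback_coords = fallback_coords, quiet = quiet,
                 source = path)
}

#' Coerce a data frame to deployments
#'
#' @inheritParams read_deployments
#' @param df data frame in the deployment layout.
#' @param source label used in messages.
#' @return a tibble of deployments with attribute `"rejects"`.
#' @export
as_deployments <- function(df, fallback_coords = NULL, quiet = FALSE,
                           source = "deployments") {
  assert_columns(df, c("station_id", "start", "end"), source)
  start <- if (inherits(df$start, "POSIXct")) lubridate::with_tz(df$start, "UTC") else parse_clock_time(df$start)
  end <- if (inherits(df$end, "POSIXct")) lubridate::with_tz(df$end, "UTC") else parse_clock_time(df$end)
  lat <- suppressWarnings(as.numeric(df$latitude %||% NA))
  lon <- suppressWarnings(as.numeric(df$longitude %||% NA))
  if (any(is.na(lat) | is.na(lon))) {
    if (is.null(fallback_coords)) {
      abort(paste(
        "deployments without coordinates found and no fallback_coords",
        "configured; solar computations require station coordinates"
      ))
    }
    warn(sprintf(
      "%d deployment(s) missing coordinates; using fallback centroid (%.3f, %.3f)",
      sum(is.na(lat) | is.na(lon)), fallback_coords[1], fallback_coords[2]
    ))
    lat[is.na(lat)] <- fallback_coords[1]
    lon[is.na(lon)] <- fallback_coords[2]
  }
  speed <- tolower(as.character(df$camera_speed %||% "fast"))
  speed[is.na(speed) | !speed %in% c("fast", "slow")] <- "fast"
  reason <- dplyr::case_when(
    is.na(start) | is.na(end) ~ "unparseable start/end",
    end <= start ~ "negative span",
    abs(lat) > 90 | abs(lon) > 180 ~ "coordinates out of range",
    TRUE ~ NA_character_
  )
  bad <- !is.na(reason)
  rejects <- tibble::tibble(
    row = which(bad),
    reason = reason[bad],
    station_id = as.character(df$station_id)[bad]
  )
  keep <- !bad
  lure <- if ("lure_dates" %in% names(df)) {
    if (is.list(df$lure_dates)) df$lure_dates else parse_lure_dates(df$lure_dates)
  } else {
    purrr::map(as.Date(start), function(d) d)
  }
  out <- tibble::tibble(
    station_id = as.character(df$station_id)[keep],
    latitude = lat[keep], longitude = lon[keep],
    start = start[keep], end = end[keep],
    camera_speed = speed[keep],
    lure_dates = lure[keep]
  )
  empty_lure <- purrr::map_int(out$lure_dates, length) == 0
  out$lure_dates[empty_lure] <- purrr::map(as.Date(out$start[empty_lure]), identity)
  if (!quiet) {
    inform(sprintf(
      "%s: %d deployments parsed, %d rejected", source, nrow(out), nrow(rejects)
    ))
  }
  attr(out, "rejects") <- rejects
  out
}

#' Filter photographs into independent detection events
#'
#' Within each station-by-species photo stream (sorted by time), a new
#' event starts whenever the gap to the previous photograph strictly
#' exceeds `gap_minutes`; the event takes the first photograph's time.
#' Photographs of several individuals count as a single detection, and
#' photographs with identical timestamps collapse before gap evaluation.
#'
#' @param photos tibble of photo records (see [read_photo_records()]).
#' @param gap_minutes independence gap in minutes (default 30, i.e. the
#'   "more than half an hour apart" rule).
#' @return a tibble of detection events: `station_id`, `species`,
#'   `event_time`, `n_photos`, `month`, `year`, `season`.
#' @export
independent_events <- function(photos, gap_minutes = 30) {
  assert_columns(photos, c("station_id", "species", "timestamp"), "photos")
  if (nrow(photos) == 0) {
    return(tibble::tibble(
      station_id = character(0), species = character(0),
      event_time = as.POSIXct(character(0), tz = "UTC"),
      n_photos = integer(0), month = integer(0), year = integer(0),
      season = character(0)
    ))
  }
  photos |>
    dplyr::distinct(.data$station_id, .data$species, .data$timestamp) |>
    dplyr::arrange(.data$station_id, .data$species, .data$timestamp) |>
    dplyr::group_by(.data$station_id, .data$species) |>
    dplyr::mutate(
      gap_min = as.numeric(.data$timestamp - dplyr::lag(.data$timestamp),
                           units = "mins"),
      new_event = is.na(.data$gap_min) | .data$gap_min > gap_minutes,
      event_id = cumsum(.data$new_event)
    ) |>
    dplyr::group_by(.data$event_id, .add = TRUE) |>
    dplyr::summarise(
      event_time = dplyr::first(.data$timestamp),
      n_photos = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      month = lubridate::month(.data$event_time),
      year = lubridate::year(.data$event_time),
      season = season_of_month(.data$month)
    ) |>
    dplyr::select(-"event_id") |>
    dplyr::arrange(.data$station_id, .data$species, .data$event_time)
}

month_span_days <- function(year, month) {
  lubridate::days_in_month(lubridate::make_date(year, month, 1))
}

#' Survey effort by station, month and season
#'
#' Camera-days are computed from deployment spans (fractional days kept)
#' and apportioned to calendar months pro-rata by overlap. Seasons follow
#' the warm = March–November, winter = December–February convention.
#'
#' @param deployments tibble of deployments (see [read_deployments()]).
#' @return a tibble (`station_id`, `year`, `month`, `season`,
#'   `camera_days`) of class `effort_summary`.
#' @export
effort_summary <- function(deployments) {
  assert_columns(deployments, c("station_id", "start", "end"), "deployments")
  per <- deployments |>
    dplyr::mutate(months = purrr::map2(.data$start, .data$end, function(s, e) {
      seq(lubridate::floor_date(as.Date(s), "month"),
          lubridate::floor_date(as.Date(e), "month"), by = "month")
    })) |>
    tidyr::unnest("months")
  month_start <- lubridate::as_datetime(per$months)
  month_end <- lubridate::as_datetime(
    lubridate::add_with_rollback(per$months, lubridate::period(1, "month"))
  )
  lo <- pmax(per$start, month_start)
  hi <- pmin(per$end, month_end)
  per$camera_days <- pmax(0, as.numeric(hi - lo, units = "days"))
  out <- per |>
    dplyr::mutate(
      year = lubridate::year(.data$months),
      month = lubridate::month(.data$months),
      season = season_of_month(.data$month)
    ) |>
    dplyr::group_by(.data$station_id, .data$year, .data$month, .data$season) |>
    dplyr::summarise(camera_days = sum(.data$camera_days), .groups = "drop")
  class(out) <- c("effort_summary", class(out))
  out
}

#' Season and overall effort totals
#'
#' @param effort an [effort_summary()] table.
#' @return a one-row tibble with `warm`, `winter` and `total` camera-days.
#' @export
effort_totals <- function(effort) {
  effort |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(camera_days = sum(.data$camera_days)) |>
    tidyr::pivot_wider(names_from = "season", values_from = "camera_days") |>
    dplyr::mutate(
      warm = .data[["warm"]] %||% 0, winter = .data[["winter"]] %||% 0,
      total = .data$warm + .data$winter
    ) |>
    dplyr::select("warm", "winter", "total")
}

#' Monthly relative activity index
#'
#' The relative activity index (RAI) for month `j` is the number of
#' independent detections per 1,000 camera-days in that month, pooled
#' across years.
#'
#' @param events detection events from [independent_events()].
#' @param effort an [effort_summary()] table.
#' @param species optional character vector restricting the species
#'   reported; default all species present in `events`.
#' @return a tibble (`species`, `month`, `detections`, `camera_days`,
#'   `rai`, `undefined`): `rai` is `NA` with `undefined = TRUE` for months
#'   with no effort.
#' @export
monthly_rai <- function(events, effort, species = NULL) {
  species <- species %||% sort(unique(events$species))
  eff <- effort |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(camera_days = sum(.data$camera_days))
  grid <- tidyr::expand_grid(species = species, month = 1:12)
  det <- events |>
    dplyr::filter(.data$species %in% !!species) |>
    dplyr::count(.data$species, .data$month, name = "detections")
  out <- grid |>
    dplyr::left_join(det, by = c("species", "month")) |>
    dplyr::left_join(eff, by = "month") |>
    dplyr::mutate(
      detections = tidyr::replace_na(.data$detections, 0L),
      camera_days = tidyr::replace_na(.data$camera_days, 0)
    )
  bad <- out$camera_days == 0 & out$detections > 0
  if (any(bad)) {
    abort(sprintf(
      "detections recorded in months with zero camera-days: %s",
      paste(unique(out$month[bad]), collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(
      undefined = .data$camera_days == 0,
      rai = dplyr::if_else(.data$undefined, NA_real_,
                           1000 * .data$detections / .data$camera_days)
    )
}
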