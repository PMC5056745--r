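# Synthetic camera-trap surveys with known occupancy, co-occurrence, diel
# and seasonal structure. The generator works at the event level: latent
# site states come from the four-state occupancy distribution, events are
# a Poisson process in time thinned by monthly rate multipliers, and each
# event receives a sun-time drawn from the species' diel archetype and is
# converted back to clock time through the station's solar schedule — so
# simulated data exercise exactly the code paths real data do.

#' Define a diel activity archetype
#'
#' A mixture of von Mises components on the 24-h sun-time cycle.
#'
#' @param means component mean directions in sun-time hours.
#' @param kappas component concentrations.
#' @param weights mixture weights (normalised to sum to 1).
#' @return an object of class `diel_archetype`.
#' @export
diel_archetype <- function(means, kappas, weights = NULL) {
  weights <- weights %||% rep(1, length(means))
  stopifnot(length(means) == length(kappas),
            length(weights) == length(means), all(kappas >= 0),
            all(weights > 0))
  structure(
    list(means = means, kappas = kappas, weights = weights / sum(weights)),
    class = "diel_archetype"
  )
}

#' @rdname diel_archetype
#' @export
archetype_nocturnal <- function() {
  diel_archetype(c(22, 4), c(3, 3), c(0.55, 0.45))
}

#' @rdname diel_archetype
#' @export
archetype_diurnal <- function() {
  diel_archetype(c(9, 15), c(4, 4), c(0.5, 0.5))
}

#' @rdname diel_archetype
#' @export
archetype_crepuscular <- function() {
  diel_archetype(c(5.5, 18.5), c(10, 10), c(0.5, 0.5))
}

#' @rdname diel_archetype
#' @export
archetype_arrhythmic <- function() {
  diel_archetype(12, 0.2, 1)
}

#' Sample sun-times from a diel archetype
#'
#' i.i.d. draws from the archetype's von Mises mixture.
#'
#' @param archetype a [diel_archetype()].
#' @param n number of draws.
#' @param seed optional seed.
#' @param units `"hours"` (default) or `"radians"`.
#' @return `n` sun-times.
#' @export
simulate_activity_times <- function(archetype, n, seed = NULL,
                                    units = c("hours", "radians")) {
  units <- match.arg(units)
  stopifnot(inherits(archetype, "diel_archetype"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(archetype$weights), n, replace = TRUE,
                     prob = archetype$weights)
  theta <- numeric(n)
  for (j in seq_along(archetype$weights)) {
    idx <- which(comp == j)
    if (length(idx) == 0) next
    theta[idx] <- rvonmises(length(idx), hours_to_radians(archetype$means[j]),
                            archetype$kappas[j])
  }
  if (units == "hours") radians_to_hours(theta) else theta
}

default_species_table <- function() {
  flat12 <- rep(1, 12)
  # monthly multipliers indexed Jan..Dec
  summer_peak <- c(0.4, 0.4, 0.6, 0.8, 1, 1.4, 1.6, 1.6, 1.4, 0.8, 0.5, 0.4)
  winter_zero <- c(0, 0, 0.6, 0.8, 1, 1.4, 1.6, 1.6, 1.4, 0.8, 0.5, 0)
  winter_peak <- c(1.6, 1.2, 0.8, 0.8, 0.8, 0.8, 1, 1, 1, 1, 1.2, 1.8)
  bimodal <- c(1.4, 1.2, 1, 0.7, 0.7, 0.8, 1.3, 1.4, 1.3, 0.8, 0.9, 1.5)
  tibble::tibble(
    species = c("masked_palm_civet", "leopard_cat", "hog_badger",
                "yellow_throated_marten", "siberian_weasel"),
    psi = c(0.35, 0.35, 0.45, 0.30, 0.50),
    daily_rate = c(0.020, 0.017, 0.028, 0.016, 0.030),
    archetype = list(archetype_nocturnal(), archetype_nocturnal(),
                     archetype_nocturnal(), archetype_diurnal(),
                     archetype_arrhythmic()),
    winter_archetype = list(NULL, NULL, NULL, NULL, archetype_nocturnal()),
    monthly = list(winter_zero, summer_peak, winter_zero, winter_peak, bimodal)
  )
}

#' Configuration for a synthetic survey
#'
#' Defaults emulate the design of a multi-year baited camera-trap survey
#' of a five-species mesocarnivore guild at ~32.9N: 495 stations surveyed
#' 2004-2015 in 4-6-week deployments on a mountain-forest study area,
#' nocturnal/diurnal/arrhythmic diel archetypes, seasonal detection-rate
#' variation including zero winter detections for the civet-like species,
#' and a focal species pair whose site co-occurrence is governed by a
#' species interaction factor below 1 (avoidance).
#'
#' @param n_stations number of camera stations.
#' @param survey_start,survey_end `Date` bounds for deployment starts.
#' @param deployment_mean_days,deployment_sd_days deployment length
#'   distribution (normal, truncated to `[21, 56]` days).
#' @param centroid `c(latitude, longitude)` of the study area.
#' @param coord_jitter half-width (degrees) of the uniform station scatter.
#' @param tz_offset hours east of UTC of the local standard clock.
#' @param species species table: `species`, `psi`, `daily_rate`,
#'   `archetype` (list of [diel_archetype()]), `winter_archetype`
#'   (optional seasonal switch) and `monthly` (12 rate multipliers,
#'   January first; 0 emulates winter dormancy).
#' @param pairs focal co-occurrence pairs: `species_a`, `species_b`,
#'   `gamma`; species not in a pair occupy sites independently.
#' @param prob_slow_camera probability a deployment uses a slow-trigger
#'   camera model.
#' @param dup_photo_prob probability an event yields extra photographs
#'   within the independence gap (exercises the event filter).
#' @param seed master seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_stations = 495,
                         survey_start = as.Date("2004-03-01"),
                         survey_end = as.Date("2015-10-15"),
                         deployment_mean_days = 35,
                         deployment_sd_days = 5,
                         centroid = c(32.9, 104.1),
                         coord_jitter = 0.5,
                         tz_offset = 8,
                         species = default_species_table(),
                         pairs = tibble::tibble(
                           species_a = "masked_palm_civet",
                           species_b = "hog_badger",
                           gamma = 0.6
                         ),
                         prob_slow_camera = 0.4,
                         dup_photo_prob = 0.5,
                         seed = 1) {
  stopifnot(all(species$psi >= 0 & species$psi <= 1),
            all(species$daily_rate >= 0))
  for (i in seq_len(nrow(pairs))) {
    pa <- species$psi[species$species == pairs$species_a[i]]
    pb <- species$psi[species$species == pairs$species_b[i]]
    if (length(pa) == 0 || length(pb) == 0) {
      abort("pair references a species missing from the species table")
    }
    if (pairs$gamma[i] * pa * pb > min(pa, pb) + 1e-12 ||
        pairs$gamma[i] * pa * pb < max(0, pa + pb - 1) - 1e-12) {
      abort(sprintf("gamma = %g infeasible for pair %s-%s",
                    pairs$gamma[i], pairs$species_a[i], pairs$species_b[i]))
    }
  }
  structure(
    list(
      n_stations = n_stations, survey_start = survey_start,
      survey_end = survey_end,
      deployment_mean_days = deployment_mean_days,
      deployment_sd_days = deployment_sd_days,
      centroid = centroid, coord_jitter = coord_jitter,
      tz_offset = tz_offset, species = species, pairs = pairs,
      prob_slow_camera = prob_slow_camera, dup_photo_prob = dup_photo_prob,
      seed = seed
    ),
    class = "synth_config"
  )
}

#' A small fixed configuration for fast checks
#'
#' 60 stations over two survey years, four species forming two focal
#' pairs (an avoidance pair at gamma = 0.6 and an aggregation pair at
#' gamma = 1.4), with elevated detection rates so every analysis stage has
#' material to work with at this size.
#'
#' @param seed master seed.
#' @return a `synth_config`.
#' @export
minshan_mini_config <- function(seed = 1) {
  sp <- default_species_table() |>
    dplyr::filter(.data$species != "leopard_cat") |>
    dplyr::mutate(daily_rate = .data$daily_rate * 4, psi = c(0.5, 0.6, 0.45, 0.6))
  synth_config(
    n_stations = 60,
    survey_start = as.Date("2013-03-01"), survey_end = as.Date("2014-10-15"),
    deployment_mean_days = 40,
    species = sp,
    pairs = tibble::tibble(
      species_a = c("masked_palm_civet", "yellow_throated_marten"),
      species_b = c("hog_badger", "siberian_weasel"),
      gamma = c(0.6, 1.4)
    ),
    seed = seed
  )
}

# joint latent occupancy: paired species drawn from the four-state
# distribution, the rest independently
draw_occupancy <- function(config) {
  sp <- config$species
  n <- config$n_stations
  z <- matrix(FALSE, n, nrow(sp), dimnames = list(NULL, sp$species))
  paired <- character(0)
  for (i in seq_len(nrow(config$pairs))) {
    a <- config$pairs$species_a[i]; b <- config$pairs$species_b[i]
    g <- config$pairs$gamma[i]
    pa <- sp$psi[sp$species == a]; pb <- sp$psi[sp$species == b]
    pr <- pmax(0, c(g * pa * pb, pa - g * pa * pb, pb - g * pa * pb,
                    1 - pa - pb + g * pa * pb))
    state <- sample.int(4, n, replace = TRUE, prob = pr)
    z[, a] <- state %in% c(1, 2)
    z[, b] <- state %in% c(1, 3)
    paired <- c(paired, a, b)
  }
  for (s in setdiff(sp$species, paired)) {
    z[, s] <- runif(n) < sp$psi[sp$species == s]
  }
  z
}

#' Simulate a camera-trap survey
#'
#' Generates a deployment table and a photo table in the canonical
#' layouts, plus a truth record of all latent quantities. Events of an
#' occupied site-species pair arrive as a Poisson process with the
#' configured daily rate scaled by the monthly multiplier; each event's
#' sun-time comes from the species' (season-dependent) diel archetype and
#' is converted to clock time through the station's solar schedule. Some
#' events yield duplicate photographs within the independence gap, so the
#' event filter has work to do.
#'
#' @param config a [synth_config()].
#' @return a list: `photos`, `deployments` (tibbles in the layouts read by
#'   [as_photo_records()] / [as_deployments()]) and `truth` (latent
#'   occupancy matrix, per-event sun-times, the config).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_stations
  stations <- tibble::tibble(
    station_id = sprintf("ST%04d", seq_len(n)),
    latitude = config$centroid[1] + runif(n, -1, 1) * config$coord_jitter,
    longitude = config$centroid[2] + runif(n, -1, 1) * config$coord_jitter
  )
  span_days <- as.numeric(config$survey_end - config$survey_start)
  dep_len <- pmin(56, pmax(21, rnorm(n, config$deployment_mean_days,
                                     config$deployment_sd_days)))
  dep_start <- lubridate::as_datetime(config$survey_start) +
    lubridate::ddays(runif(n, 0, span_days)) # staggered multi-year coverage
  deployments <- stations |>
    dplyr::mutate(
      start = dep_start,
      end = dep_start + lubridate::ddays(dep_len),
      camera_speed = ifelse(runif(n) < config$prob_slow_camera, "slow", "fast"),
      lure_dates = purrr::map(as.Date(dep_start), identity)
    )
  z <- draw_occupancy(config)

  sd_tab <- active_station_dates(deployments) |>
    dplyr::mutate(month = lubridate::month(.data$date),
                  frac = (.data$to - .data$from) / 24)
  events <- purrr::map_dfr(seq_len(nrow(config$species)), function(si) {
    sp <- config$species[si, ]
    occ_stations <- stations$station_id[z[, sp$species]]
    cells <- sd_tab[sd_tab$station_id %in% occ_stations, ]
    if (nrow(cells) == 0) return(NULL)
    lambda <- sp$daily_rate * sp$monthly[[1]][cells$month] * cells$frac
    n_ev <- rpois(nrow(cells), lambda)
    cells <- cells[rep(seq_len(nrow(cells)), n_ev), ]
    if (nrow(cells) == 0) return(NULL)
    season <- season_of_month(lubridate::month(cells$date))
    arch_warm <- sp$archetype[[1]]
    arch_winter <- sp$winter_archetype[[1]] %||% arch_warm
    st <- numeric(nrow(cells))
    st[season == "warm"] <- simulate_activity_times(arch_warm, sum(season == "warm"))
    st[season == "winter"] <- simulate_activity_times(arch_winter,
                                                      sum(season == "winter"))
    clock <- sun_time_inverse(st, cells$date, cells$latitude, cells$longitude,
                              config$tz_offset)
    tibble::tibble(
      station_id = cells$station_id, species = sp$species,
      time = lubridate::as_datetime(cells$date) + lubridate::dhours(clock),
      sun_time_true = st,
      dep_start = cells$start, dep_end = cells$end
    )
  })
  if (nrow(events) > 0) {
    events <- dplyr::filter(events, .data$time >= .data$dep_start,
                            .data$time < .data$dep_end)
  }

  photos <- if (nrow(events) == 0) {
    tibble::tibble(station_id = character(0), species = character(0),
                   timestamp = character(0), n_individuals = integer(0))
  } else {
    extra <- rbinom(nrow(events), 2, config$dup_photo_prob)
    idx <- rep(seq_len(nrow(events)), 1 + extra)
    offset_min <- unlist(purrr::map(1 + extra, function(k) {
      c(0, sort(runif(k - 1, 0.5, 10)))
    }))
    tibble::tibble(
      station_id = events$station_id[idx],
      species = events$species[idx],
      timestamp = format(events$time[idx] + lubridate::dminutes(offset_min),
                         "%Y-%m-%d %H:%M:%S"),
      n_individuals = 1L + rpois(length(idx), 0.1)
    ) |>
      dplyr::arrange(.data$station_id, .data$species, .data$timestamp)
  }

  dep_out <- deployments |>
    dplyr::mutate(
      start = format(.data$start, "%Y-%m-%d %H:%M:%S"),
      end = format(.data$end, "%Y-%m-%d %H:%M:%S"),
      lure_dates = purrr::map_chr(.data$lure_dates,
                                  function(d) paste(format(d), collapse = ";"))
    )
  list(
    photos = photos,
    deployments = dep_out,
    truth = list(
      occupancy = z,
      events = if (nrow(events)) dplyr::select(events, "station_id", "species",
                                               "time", "sun_time_true")
               else NULL,
      config = config
    )
  )
}

#' Read / write a synthetic-survey configuration as YAML
#'
#' Archetypes serialise as their means/kappas/weights; the species and
#' pair tables as records.
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `read_synth_config()` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  arch_to_list <- function(a) {
    if (is.null(a)) NULL else list(means = a$means, kappas = a$kappas,
                                   weights = a$weights)
  }
  obj <- list(
    n_stations = config$n_stations,
    survey_start = format(config$survey_start),
    survey_end = format(config$survey_end),
    deployment_mean_days = config$deployment_mean_days,
    deployment_sd_days = config$deployment_sd_days,
    centroid = config$centroid, coord_jitter = config$coord_jitter,
    tz_offset = config$tz_offset,
    prob_slow_camera = config$prob_slow_camera,
    dup_photo_prob = config$dup_photo_prob,
    seed = config$seed,
    species = purrr::map(seq_len(nrow(config$species)), function(i) {
      r <- config$species[i, ]
      list(species = r$species, psi = r$psi, daily_rate = r$daily_rate,
           archetype = arch_to_list(r$archetype[[1]]),
           winter_archetype = arch_to_list(r$winter_archetype[[1]]),
           monthly = r$monthly[[1]])
    }),
    pairs = purrr::map(seq_len(nrow(config$pairs)), function(i) {
      as.list(config$pairs[i, ])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- yaml::read_yaml(path)
  arch_from_list <- function(x) {
    if (is.null(x)) NULL else diel_archetype(x$means, x$kappas, x$weights)
  }
  species <- purrr::map_dfr(obj$species, function(s) {
    tibble::tibble(
      species = s$species, psi = s$psi, daily_rate = s$daily_rate,
      archetype = list(arch_from_list(s$archetype)),
      winter_archetype = list(arch_from_list(s$winter_archetype)),
      monthly = list(unlist(s$monthly))
    )
  })
  pairs <- purrr::map_dfr(obj$pairs, tibble::as_tibble)
  synth_config(
    n_stations = obj$n_stations,
    survey_start = as.Date(obj$survey_start),
    survey_end = as.Date(obj$survey_end),
    deployment_mean_days = obj$deployment_mean_days,
    deployment_sd_days = obj$deployment_sd_days,
    centroid = unlist(obj$centroid), coord_jitter = obj$coord_jitter,
    tz_offset = obj$tz_offset, species = species, pairs = pairs,
    prob_slow_camera = obj$prob_slow_camera,
    dup_photo_prob = obj$dup_photo_prob, seed = obj$seed
  )
}
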