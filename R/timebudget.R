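# Diel time-budget selection: Manly selection ratios of period use versus
# availability, the chi-squared test of random use, and the multinomial
# randomization test with direction-tagged one-sided p-values.

check_counts_availability <- function(counts, availability) {
  pi_hat <- as_availability(availability)
  counts <- counts[DIEL_PERIODS]
  if (anyNA(names(counts)) || anyNA(counts)) {
    abort("counts must be a named vector covering crepuscular, diurnal, nocturnal")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  if (sum(counts) == 0) abort("no detections: selection undefined")
  if (any(pi_hat == 0 & counts > 0)) {
    abort("period with zero availability has detections (impossible availability)")
  }
  list(counts = counts, pi_hat = pi_hat)
}

#' Selection ratios of diel-period use versus availability
#'
#' The selection ratio for period `i` is `w_i = o_i / pi_i`, where `o_i`
#' is the proportion of detections in the period and `pi_i` its
#' proportional availability. `w_i > 1` indicates selection for the
#' period, `w_i < 1` avoidance.
#'
#' @param counts named vector of detection counts for `crepuscular`,
#'   `diurnal`, `nocturnal`.
#' @param availability an [period_availability()] table or a named
#'   proportion vector summing to 1.
#' @return a tibble (`period`, `n`, `use`, `availability`, `ratio`).
#' @export
selection_ratios <- function(counts, availability) {
  v <- check_counts_availability(counts, availability)
  n_total <- sum(v$counts)
  tibble::tibble(
    period = factor(DIEL_PERIODS, levels = DIEL_PERIODS),
    n = as.integer(v$counts),
    use = as.numeric(v$counts) / n_total,
    availability = as.numeric(v$pi_hat),
    ratio = (as.numeric(v$counts) / n_total) / as.numeric(v$pi_hat)
  )
}

#' Chi-squared test of random diel-period use
#'
#' Tests whether detections are distributed across the three diel periods
#' in proportion to their availability:
#' `chi2 = sum (n_i - N pi_i)^2 / (N pi_i)` on 2 degrees of freedom.
#'
#' @inheritParams selection_ratios
#' @return a one-row tibble (`chi2`, `df`, `p_value`).
#' @export
chisq_random_use <- function(counts, availability) {
  v <- check_counts_availability(counts, availability)
  expected <- sum(v$counts) * v$pi_hat
  if (any(expected == 0)) abort("expected count of zero in chi-squared test")
  chi2 <- sum((v$counts - expected)^2 / expected)
  df <- length(v$counts) - 1
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Multinomial randomization test of diel-period use
#'
#' Draws `n_reps` multinomial samples of the observed total under the
#' availability proportions and compares each period's observed count with
#' its randomization distribution. For periods used more than expected the
#' upper-tail p-value is reported (direction `"more than expected"`),
#' otherwise the lower tail (`"less than expected"`); p-values carry the
#' add-one correction `(1 + #extreme) / (n_reps + 1)` and so are never 0.
#'
#' @inheritParams selection_ratios
#' @param n_reps randomization replicates (default 10000).
#' @param seed optional integer seed.
#' @return a tibble (`period`, `n`, `expected`, `direction`, `p_value`,
#'   `n_reps`).
#' @export
randomization_test <- function(counts, availability, n_reps = 10000,
                               seed = NULL) {
  v <- check_counts_availability(counts, availability)
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(v$counts)
  sims <- rmultinom(n_reps, n_total, v$pi_hat) # 3 x n_reps
  expected <- n_total * v$pi_hat
  res <- purrr::map_dfr(seq_along(DIEL_PERIODS), function(i) {
    obs <- v$counts[i]
    if (obs > expected[i]) {
      p <- (1 + sum(sims[i, ] >= obs)) / (n_reps + 1)
      dir <- "more than expected"
    } else {
      p <- (1 + sum(sims[i, ] <= obs)) / (n_reps + 1)
      dir <- "less than expected"
    }
    tibble::tibble(
      period = DIEL_PERIODS[i], n = as.integer(obs),
      expected = as.numeric(expected[i]), direction = dir, p_value = p
    )
  })
  res$period <- factor(res$period, levels = DIEL_PERIODS)
  res$n_reps <- as.integer(n_reps)
  res
}

#' Diel time-budget selection analysis per species and season
#'
#' Runs [selection_ratios()], [chisq_random_use()] and
#' [randomization_test()] for each species within each season, against
#' that season's availability. Winter rows are reported only for species
#' with at least `min_n` winter detections.
#'
#' @param events annotated events with `species`, `season` and
#'   `diel_period` columns (see [annotate_events()]).
#' @param deployments deployments used to compute seasonal availability.
#' @param min_n minimum detections for a species-season row (default 25).
#' @param n_reps randomization replicates.
#' @param seed master seed; species-season cells get deterministic child
#'   streams.
#' @param tz_offset hours east of UTC.
#' @return a `selection_result` tibble: one row per species, season and
#'   period with counts, ratios, the chi-squared test and the directional
#'   randomization p-value.
#' @export
diel_selection <- function(events, deployments, min_n = 25, n_reps = 10000,
                           seed = NULL, tz_offset = 8) {
  assert_columns(events, c("species", "season", "diel_period"), "annotated events")
  cells <- events |>
    dplyr::count(.data$species, .data$season) |>
    dplyr::filter(.data$n >= min_n)
  avail <- purrr::map(
    setNames(unique(cells$season), unique(cells$season)),
    function(s) period_availability(deployments, season = s, tz_offset = tz_offset)
  )
  out <- purrr::pmap_dfr(cells, function(species, season, n) {
    sub <- events[events$species == species & events$season == season, ]
    counts <- table(factor(sub$diel_period, levels = DIEL_PERIODS))
    counts <- setNames(as.numeric(counts), DIEL_PERIODS)
    av <- avail[[season]]
    sr <- selection_ratios(counts, av)
    ch <- chisq_random_use(counts, av)
    rt <- randomization_test(counts, av, n_reps = n_reps,
                             seed = child_seed(seed, paste(species, season)))
    sr |>
      dplyr::mutate(
        species = species, season = season, total = as.integer(sum(counts)),
        chi2 = ch$chi2, df = ch$df, p_chi2 = ch$p_value,
        direction = rt$direction, p_random = rt$p_value,
        n_reps = as.integer(n_reps)
      ) |>
      dplyr::select(
        "species", "season", "total", "period", "n", "use",
        "availability", "ratio", "chi2", "df", "p_chi2",
        "direction", "p_random", "n_reps"
      )
  })
  class(out) <- c("selection_result", class(out))
  out
}
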