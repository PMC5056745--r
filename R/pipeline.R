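# End-to-end orchestration: photographs + deployments in, the full set of
# community summaries out (effort and detection totals, monthly RAI, diel
# activity and pairwise overlap, time-budget selection, two-species
# co-occurrence rankings), plus a machine-readable run manifest.

#' Run the full camera-trap community analysis
#'
#' Chains the package's stages: independence filtering, effort accounting
#' and seasonal detection totals, monthly relative activity indices,
#' solar annotation, pairwise diel-overlap estimation with bootstrap
#' intervals, diel time-budget selection tests, and two-species occupancy
#' model ranking for the requested focal pairs. The result bundle is a
#' pure function of the inputs, the options and the seed.
#'
#' @param photos photo records (tibble or path readable by
#'   [read_photo_records()]).
#' @param deployments deployments (tibble or path).
#' @param focal_pairs optional 2-column data frame / list of character
#'   pairs for co-occurrence modelling; `NULL` skips the occupancy stage.
#' @param gap_minutes independence gap (minutes).
#' @param segment_days occupancy occasion length (days).
#' @param adjust kernel smoothing multiplier.
#' @param n_boot bootstrap replicates per overlap interval (0 disables
#'   intervals).
#' @param n_reps randomization-test replicates.
#' @param cooccur_years,cooccur_season subset used for detection
#'   histories.
#' @param min_n_overlap,min_n_selection minimum events for a species to
#'   enter the overlap matrix / a species-season selection row.
#' @param n_starts optimisation starts per occupancy model.
#' @param tz_offset hours east of UTC of the local clock.
#' @param seed master seed; all stochastic stages draw deterministic child
#'   streams from it.
#' @param out_dir optional directory; when given, every table is written
#'   as CSV (the manifest and SIF reports as JSON).
#' @return a list of class `camtrap_analysis` with elements `events`,
#'   `effort`, `season_summary`, `rai`, `annotated`, `overlap`,
#'   `selection`, `cooccurrence` (list per pair) and `manifest`.
#' @export
run_full_analysis <- function(photos, deployments, focal_pairs = NULL,
                              gap_minutes = 30, segment_days = 15,
                              adjust = 1, n_boot = 10000, n_reps = 10000,
                              cooccur_years = 2011:2015,
                              cooccur_season = "warm",
                              min_n_overlap = 10, min_n_selection = 25,
                              n_starts = 3, tz_offset = 8, seed = 1,
                              out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  photos <- stage("ingest", {
    if (is.character(photos)) read_photo_records(photos, quiet = TRUE)
    else as_photo_records(photos, quiet = TRUE)
  })
  deployments <- stage("ingest", {
    if (is.character(deployments)) read_deployments(deployments, quiet = TRUE)
    else as_deployments(deployments, quiet = TRUE)
  })
  events <- stage("events", independent_events(photos, gap_minutes))
  effort <- stage("effort", effort_summary(deployments))
  season_summary <- stage("effort", {
    det <- events |>
      dplyr::count(.data$species, .data$season) |>
      tidyr::pivot_wider(names_from = "season", values_from = "n",
                         values_fill = 0L)
    for (col in c("warm", "winter")) {
      if (!col %in% names(det)) det[[col]] <- 0L
    }
    det |>
      dplyr::mutate(total = .data$warm + .data$winter) |>
      dplyr::select("species", "warm", "winter", "total")
  })
  rai <- stage("rai", monthly_rai(events, effort))
  annotated <- stage("activity", annotate_events(events, deployments, tz_offset))
  overlap <- stage("overlap", {
    counts <- dplyr::count(
      dplyr::filter(annotated, .data$season == "warm"), .data$species
    )
    sp <- counts$species[counts$n >= min_n_overlap]
    if (length(sp) >= 2) {
      overlap_matrix(
        dplyr::filter(annotated, .data$season == "warm"),
        species = sp, n_boot = n_boot, adjust = adjust,
        seed = child_seed(seed, "overlap")
      )
    } else {
      NULL
    }
  })
  selection <- stage("timebudget", diel_selection(
    annotated, deployments, min_n = min_n_selection, n_reps = n_reps,
    seed = child_seed(seed, "timebudget"), tz_offset = tz_offset
  ))
  cooccurrence <- NULL
  if (!is.null(focal_pairs)) {
    if (is.data.frame(focal_pairs)) {
      focal_pairs <- purrr::map(seq_len(nrow(focal_pairs)), function(i) {
        c(focal_pairs[[1]][i], focal_pairs[[2]][i])
      })
    }
    cooccurrence <- stage("cooccur", purrr::map(focal_pairs, function(pr) {
      hist <- build_detection_histories(
        events, deployments, pr[1], pr[2], segment_days = segment_days,
        years = cooccur_years, season = cooccur_season
      )
      fit_cooccurrence(hist, n_starts = n_starts,
                       seed = child_seed(seed, paste(pr, collapse = "-")))
    }))
    names(cooccurrence) <- purrr::map_chr(focal_pairs, paste, collapse = "_x_")
  }
  options <- list(
    gap_minutes = gap_minutes, segment_days = segment_days, adjust = adjust,
    n_boot = n_boot, n_reps = n_reps, cooccur_years = cooccur_years,
    cooccur_season = cooccur_season, tz_offset = tz_offset, seed = seed
  )
  tot <- effort_totals(effort)
  manifest <- list(
    package_version = as.character(utils::packageVersion("camtrapcoex")),
    seed = seed,
    options = options,
    config_hash = rlang::hash(options),
    n_photos = nrow(photos), n_events = nrow(events),
    camera_days = list(warm = tot$warm, winter = tot$winter, total = tot$total)
  )
  out <- structure(
    list(
      events = events, effort = effort, season_summary = season_summary,
      rai = rai, annotated = annotated, overlap = overlap,
      selection = selection, cooccurrence = cooccurrence, manifest = manifest
    ),
    class = "camtrap_analysis"
  )
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.camtrap_analysis <- function(x, ...) {
  tot <- x$manifest$camera_days
  cat(sprintf(
    "Camera-trap community analysis\n  %d photos -> %d independent events; %.0f camera-days (%.0f warm / %.0f winter)\n",
    x$manifest$n_photos, x$manifest$n_events, tot$total, tot$warm, tot$winter
  ))
  cat(sprintf("  species: %s\n", paste(x$season_summary$species, collapse = ", ")))
  if (!is.null(x$cooccurrence)) {
    for (nm in names(x$cooccurrence)) {
      s <- x$cooccurrence[[nm]]$sif
      cat(sprintf("  SIF %s: gamma = %.2f +/- %.2f (%s)\n", nm,
                  s$gamma_hat, s$se, s$interpretation))
    }
  }
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' CSV for the tables, JSON for the SIF reports and the run manifest.
#'
#' @param analysis a `camtrap_analysis` from [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_csv(df, file.path(dir, name))
  }
  w(analysis$events, "events.csv")
  w(analysis$effort, "effort.csv")
  w(analysis$season_summary, "season_summary.csv")
  w(analysis$rai, "rai.csv")
  w(analysis$overlap, "overlap.csv")
  w(analysis$selection, "selection.csv")
  if (!is.null(analysis$cooccurrence)) {
    for (nm in names(analysis$cooccurrence)) {
      rk <- analysis$cooccurrence[[nm]]
      w(rk$table, sprintf("cooccurrence_%s.csv", nm))
      jsonlite::write_json(
        rk$sif, file.path(dir, sprintf("sif_%s.json", nm)),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
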