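test_that("archetype sampling is sized, centred and concentrates", {
  arch <- diel_archetype(10, 5, 1)
  x <- simulate_activity_times(arch, 500, seed = 1, units = "radians")
  expect_length(x, 500)
  # circular mean within 3 SE of the component mean
  mu <- atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)
  kappa <- 5
  se <- 1 / sqrt(500 * kappa * besselI(kappa, 1) / besselI(kappa, 0))
  diff <- abs(((mu - 10 * 2 * pi / 24) + pi) %% (2 * pi) - pi)
  expect_lt(diff, 3 * se)

  # very high concentration: circular variance near zero
  tight <- simulate_activity_times(diel_archetype(3, 200, 1), 500,
                                   seed = 2, units = "radians")
  rbar <- sqrt(mean(cos(tight))^2 + mean(sin(tight))^2)
  expect_lt(1 - rbar, 0.01)

  expect_length(simulate_activity_times(arch, 0), 0)
  # mixture weights are normalised
  a2 <- diel_archetype(c(1, 2), c(1, 1), c(2, 6))
  expect_equal(a2$weights, c(0.25, 0.75))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- minshan_mini_config(seed = 4)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$photos, s2$photos)
  expect_identical(s1$deployments, s2$deployments)
  expect_identical(s1$truth$occupancy, s2$truth$occupancy)
  s3 <- simulate_survey(minshan_mini_config(seed = 5))
  expect_false(identical(s1$photos, s3$photos))
})

test_that("an infeasible interaction factor is rejected up front", {
  sp <- default_species_table()[c(1, 3), ]
  expect_error(
    synth_config(species = sp, pairs = tibble::tibble(
      species_a = "masked_palm_civet", species_b = "hog_badger", gamma = 9
    )),
    "infeasible"
  )
})

test_that("independent species co-occur at the product of occupancies", {
  sp <- default_species_table()[c(1, 3), ] |>
    dplyr::mutate(daily_rate = 0) # occupancy only, no events needed
  cfg <- synth_config(
    n_stations = 3000, species = sp,
    pairs = tibble::tibble(species_a = "masked_palm_civet",
                           species_b = "hog_badger", gamma = 1),
    seed = 8
  )
  z <- simulate_survey(cfg)$truth$occupancy
  p_joint <- mean(z[, 1] & z[, 2])
  expected <- sp$psi[1] * sp$psi[2]
  se <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(p_joint - expected), 3 * se)
})

test_that("an avoidance pair co-occurs at gamma times the product", {
  sp <- default_species_table()[c(1, 3), ] |> dplyr::mutate(daily_rate = 0)
  cfg <- synth_config(
    n_stations = 3000, species = sp,
    pairs = tibble::tibble(species_a = "masked_palm_civet",
                           species_b = "hog_badger", gamma = 0.6),
    seed = 9
  )
  z <- simulate_survey(cfg)$truth$occupancy
  expected <- 0.6 * sp$psi[1] * sp$psi[2]
  se <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(mean(z[, 1] & z[, 2]) - expected), 3 * se)
  # marginals are preserved too
  expect_lt(abs(mean(z[, 1]) - sp$psi[1]), 3 * sqrt(0.25 / 3000))
})

test_that("generated timestamps stay inside their deployments and sun-times
           reflect the archetype", {
  sim <- simulate_survey(minshan_mini_config(seed = 10))
  dep <- as_deployments(sim$deployments, quiet = TRUE)
  ph <- as_photo_records(sim$photos, quiet = TRUE)
  joined <- dplyr::inner_join(ph, dep, by = "station_id")
  expect_true(all(joined$timestamp >= joined$start &
                    joined$timestamp <= joined$end))

  # nocturnal archetype species: > 60% of events classified nocturnal
  ev <- annotate_events(independent_events(ph), dep)
  civet <- ev[ev$species == "masked_palm_civet", ]
  expect_gt(nrow(civet), 30)
  expect_gt(mean(civet$diel_period == "nocturnal"), 0.6)
  # diurnal archetype species: mostly diurnal
  marten <- ev[ev$species == "yellow_throated_marten", ]
  expect_gt(mean(marten$diel_period == "diurnal"), 0.6)

  # winter dormancy: no civet events in December-February
  expect_equal(sum(civet$season == "winter"), 0)
})

test_that("synth configs round-trip through YAML", {
  cfg <- minshan_mini_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  cfg2 <- read_synth_config(path)
  expect_equal(cfg2$n_stations, cfg$n_stations)
  expect_equal(cfg2$species$psi, cfg$species$psi)
  expect_equal(cfg2$species$archetype[[2]]$means, cfg$species$archetype[[2]]$means)
  expect_equal(cfg2$pairs$gamma, cfg$pairs$gamma)
  # identical simulations from the round-tripped config
  expect_identical(simulate_survey(cfg)$photos, simulate_survey(cfg2)$photos)
})

test_that("the shipped mini fixture config loads and matches the builder", {
  path <- system.file("extdata", "minshan-mini.yaml", package = "camtrapcoex")
  expect_true(nzchar(path))
  cfg <- read_synth_config(path)
  expect_equal(cfg$n_stations, 60)
  expect_identical(simulate_survey(cfg)$photos,
                   simulate_survey(minshan_mini_config(seed = 1))$photos)
})

test_that("the full pipeline recovers the generating interaction factor", {
  # default study-scale survey: 495 stations, avoidance pair at gamma = 0.6
  sim <- simulate_survey(synth_config(seed = 2))
  dep <- as_deployments(sim$deployments, quiet = TRUE)
  ev <- independent_events(as_photo_records(sim$photos, quiet = TRUE))
  h <- build_detection_histories(ev, dep, "masked_palm_civet", "hog_badger",
                                 years = NULL, season = "warm")
  spec <- list(gamma_free = TRUE, p_covariates = character(0),
               r_equals_p = TRUE)
  fit <- fit_occupancy_pair(h, spec, n_starts = 2, seed = 1)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  se <- setNames(fit$estimates$std.error, fit$estimates$term)
  expect_true(fit$convergence)
  expect_lt(abs(est["gamma"] - 0.6), 2 * se["gamma"])
  expect_lt(abs(est["psi_a"] - 0.35), 2.5 * se["psi_a"] + 0.02)

  # diel structure survives the clock-time round trip: nocturnal vs
  # diurnal archetypes overlap weakly
  ann <- annotate_events(ev, dep)
  warm <- ann[ann$season == "warm", ]
  o <- overlap_coefficient(
    fit_activity(warm$sun_time[warm$species == "masked_palm_civet"]),
    fit_activity(warm$sun_time[warm$species == "yellow_throated_marten"])
  )
  expect_lt(o$delta, 0.35)

  # observed diurnal use tracks the archetype's sun-time mass on [6, 18)
  civ <- warm[warm$species == "masked_palm_civet", ]
  grid <- seq(0, 2 * pi, length.out = 2001)[-2001]
  arch <- archetype_nocturnal()
  dens <- Reduce(`+`, purrr::map(seq_along(arch$weights), function(j) {
    arch$weights[j] * dvonmises(grid, arch$means[j] * 2 * pi / 24,
                                arch$kappas[j])
  }))
  day_mass <- mean(dens[grid >= pi / 2 & grid < 3 * pi / 2]) * pi
  expect_lt(abs(mean(civ$sun_time >= 6 & civ$sun_time < 18) - day_mass), 0.1)
})
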