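base_spec <- function(gamma_free = FALSE, cov = character(0),
                      r_equals_p = TRUE) {
  list(gamma_free = gamma_free, p_covariates = cov, r_equals_p = r_equals_p)
}

test_that("detection histories tile deployments into 15-day occasions", {
  dep <- toy_deployment(start = "2013-06-01 00:00:00",
                        end = "2013-07-16 00:00:00") # 45 days
  ev <- independent_events(dplyr::bind_rows(
    toy_photos("2013-06-18 03:00:00", species = "civet"), # day 17
    toy_photos("2013-06-02 03:00:00", species = "badger")
  ))
  h <- build_detection_histories(ev, dep, "civet", "badger",
                                 years = NULL, season = NULL)
  expect_equal(ncol(h$obs_a), 3)
  expect_equal(as.numeric(h$obs_a[1, ]), c(0, 1, 0))
  expect_equal(as.numeric(h$obs_b[1, ]), c(1, 0, 0))
  expect_equal(as.numeric(h$lure_bin[1, ]), c(1, 2, 3)) # lure ages 7.5, 22.5, 37.5 d
  expect_equal(as.numeric(h$cam_slow[1, ]), c(0, 0, 0))

  # a 50-day deployment leaves a 5-day remnant, dropped (< half a segment)
  dep2 <- toy_deployment(start = "2013-06-01 00:00:00",
                         end = "2013-07-21 00:00:00")
  h2 <- build_detection_histories(ev, dep2, "civet", "badger",
                                  years = NULL, season = NULL)
  expect_equal(ncol(h2$obs_a), 3)
  # ... but a 53-day deployment keeps its 8-day remnant
  dep3 <- toy_deployment(start = "2013-06-01 00:00:00",
                         end = "2013-07-24 00:00:00")
  h3 <- build_detection_histories(ev, dep3, "civet", "badger",
                                  years = NULL, season = NULL)
  expect_equal(ncol(h3$obs_a), 4)

  expect_error(
    build_detection_histories(ev, dep, "unknown_species", "badger",
                              years = NULL, season = NULL),
    "vocabulary"
  )
})

test_that("year and season filters restrict occasions", {
  dep <- dplyr::bind_rows(
    toy_deployment("ST01", "2010-06-01 00:00:00", "2010-07-01 00:00:00"),
    toy_deployment("ST02", "2013-06-01 00:00:00", "2013-07-01 00:00:00"),
    toy_deployment("ST03", "2013-12-01 00:00:00", "2014-01-01 00:00:00")
  )
  ev <- independent_events(dplyr::bind_rows(
    toy_photos("2013-06-05 02:00:00", "ST02", "civet"),
    toy_photos("2010-06-05 02:00:00", "ST01", "badger"),
    toy_photos("2013-12-10 02:00:00", "ST03", "badger")
  ))
  h <- build_detection_histories(ev, dep, "civet", "badger")
  expect_equal(h$sites, "ST02") # 2010 excluded by year, winter by season
  expect_equal(sum(h$obs_a, na.rm = TRUE), 1)
  expect_equal(sum(h$obs_b, na.rm = TRUE), 0)
})

test_that("the model set is the full 16-model crossing", {
  ms <- enumerate_model_set()
  expect_equal(nrow(ms), 16)
  expect_equal(length(unique(ms$model)), 16)
  expect_true("ψ(S)p(S)r(S)" %in% ms$model)
  expect_true("ψ(S)γ(.)p(S+Lr+Cam)r(S+Lr+Cam)" %in% ms$model)
  expect_equal(sum(ms$gamma_free), 8)
  # K under the package's counting convention
  expect_equal(ms$K[ms$model == "ψ(S)p(S)"], 4)
  expect_equal(ms$K[ms$model == "ψ(S)γ(.)p(S+Lr+Cam)r(S+Lr+Cam)"], 15)
})

test_that("the likelihood reproduces hand-computed single-site cases", {
  h <- random_history(1, 1)
  h$obs_a[1, 1] <- 1; h$obs_b[1, 1] <- 0
  h$lure_bin[1, 1] <- 1; h$cam_slow[1, 1] <- 0
  # forced occupancy, p = 0.5, A-only observed: L = 0.5 * 0.5
  big <- qlogis(1 - 1e-12)
  nll <- two_species_nll(c(big, big, qlogis(0.5), qlogis(0.5)), h,
                         base_spec())
  expect_equal(nll, -log(0.25), tolerance = 1e-6)

  # psi = 0.5 each, gamma = 1, p = 0.5, nothing observed:
  # L = 0.0625 + 0.125 + 0.125 + 0.25 = 0.5625
  h$obs_a[1, 1] <- 0
  nll2 <- two_species_nll(c(qlogis(0.5), qlogis(0.5), qlogis(0.5), qlogis(0.5)),
                          h, base_spec())
  expect_equal(nll2, -log(0.5625), tolerance = 1e-10)
  expect_equal(nll2, 0.5754, tolerance = 1e-4)
})

test_that("the likelihood equals exhaustive enumeration on random instances", {
  set.seed(51)
  ms <- enumerate_model_set()
  for (rep in 1:25) {
    h <- random_history(sample(2:6, 1), sample(2:5, 1))
    i <- sample(16, 1)
    spec <- list(gamma_free = ms$gamma_free[i],
                 p_covariates = ms$p_covariates[[i]],
                 r_equals_p = ms$r_equals_p[i])
    np <- length(camtrapcoex:::param_names(camtrapcoex:::as_model_spec(spec)))
    params <- rnorm(np, 0, 1)
    expect_equal(two_species_nll(params, h, spec),
                 naive_two_species_nll(params, h, spec), tolerance = 1e-10)
  }
})

test_that("with gamma = 1 and r = p the likelihood factorizes", {
  set.seed(52)
  for (rep in 1:5) {
    h <- random_history(8, 4)
    psi_a <- runif(1, 0.2, 0.8); psi_b <- runif(1, 0.2, 0.8)
    pa_int <- qlogis(runif(1, 0.2, 0.6))
    nll <- two_species_nll(c(qlogis(psi_a), qlogis(psi_b), pa_int, pa_int),
                           h, base_spec())
    single <- naive_single_species_nll(psi_a, pa_int, h$obs_a) +
      naive_single_species_nll(psi_b, pa_int, h$obs_b)
    expect_equal(nll, single, tolerance = 1e-8)
  }
})

test_that("fitting recovers simulated parameters and reports a sensible AIC", {
  h <- simulate_pair_histories(400, 8, 0.5, 0.4, 0.6, p = 0.35, seed = 61)
  spec <- base_spec(gamma_free = TRUE)
  fit <- fit_occupancy_pair(h, spec, n_starts = 2, seed = 2)
  expect_true(fit$convergence)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  se <- setNames(fit$estimates$std.error, fit$estimates$term)
  expect_lt(abs(est["psi_a"] - 0.5), 3 * se["psi_a"] + 0.02)
  expect_lt(abs(est["psi_b"] - 0.4), 3 * se["psi_b"] + 0.02)
  expect_lt(abs(est["gamma"] - 0.6), 3 * se["gamma"] + 0.02)
  expect_equal(fit$AIC, fit$neg2LL + 2 * fit$K)
  expect_equal(fit$K, 5)

  # gamma fixed: SIF reported as exactly 1 with zero SE
  fit1 <- fit_occupancy_pair(h, base_spec(), n_starts = 1, seed = 2)
  expect_equal(fit1$estimates$estimate[3], 1)
  expect_equal(fit1$estimates$std.error[3], 0)
})

test_that("ranking finds the avoidance signal and is label-symmetric", {
  h <- simulate_pair_histories(350, 7, 0.55, 0.45, 0.5, p = 0.35, seed = 71)
  models <- enumerate_model_set()[c(1, 3), ] # gamma fixed / free, no covariates
  rk <- fit_cooccurrence(h, models, n_starts = 2, seed = 3)
  expect_equal(min(rk$table$delta_aic), 0)
  expect_s3_class(glance(rk), "tbl_df")

  # swapping the species labels swaps psi estimates, same AIC ranking
  h_swap <- h
  h_swap$obs_a <- h$obs_b; h_swap$obs_b <- h$obs_a
  rk_swap <- fit_cooccurrence(h_swap, models, n_starts = 2, seed = 3)
  expect_equal(rk$table$AIC, rk_swap$table$AIC, tolerance = 1e-4)
  expect_equal(rk$sif$gamma_hat, rk_swap$sif$gamma_hat, tolerance = 1e-3)

  # site order is irrelevant
  perm <- sample(length(h$sites))
  h_perm <- h
  for (f in c("obs_a", "obs_b", "lure_bin", "cam_slow")) {
    h_perm[[f]] <- h[[f]][perm, ]
  }
  h_perm$sites <- h$sites[perm]
  rk_perm <- fit_cooccurrence(h_perm, models, n_starts = 2, seed = 3)
  expect_equal(rk$table$AIC, rk_perm$table$AIC, tolerance = 1e-6)
})

test_that("SIF interpretation follows the top-model set", {
  tab <- function(gamma_free, gamma_hat, delta) {
    tibble::tibble(gamma_free = gamma_free, gamma_hat = gamma_hat,
                   delta_aic = delta)
  }
  interp <- camtrapcoex:::interpret_sif
  expect_equal(interp(tab(TRUE, 0.6, 0)), "avoidance")
  expect_equal(interp(tab(TRUE, 1.5, 0)), "aggregation")
  expect_equal(interp(tab(c(FALSE, FALSE), c(1, 1), c(0, 1))), "independence")
  expect_equal(interp(tab(c(FALSE, TRUE), c(1, 0.7), c(0, 1))), "unclear")
})

test_that("detection histories round-trip through the text format", {
  set.seed(81)
  h <- random_history(6, 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_detection_histories(h, path)
  h2 <- read_detection_histories(path)
  expect_equal(h2$obs_a, h$obs_a)
  expect_equal(h2$obs_b, h$obs_b)
  expect_equal(h2$lure_bin, h$lure_bin)
  expect_equal(h2$cam_slow, h$cam_slow)
  expect_equal(h2$species_a, "A")
})
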