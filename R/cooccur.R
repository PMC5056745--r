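# Two-species occupancy modelling: detection-history construction on
# 15-day occasions, the joint likelihood parameterised by marginal
# occupancies (psi_A, psi_B) and the species interaction factor gamma
# (SIF: the ratio of joint occupancy to the product of the marginals),
# maximum-likelihood fitting, and AIC ranking of the standard 16-model
# set with detection covariates Lr (scent-lure age bin) and Cam (camera
# trigger-speed class).

LURE_BIN_LABELS <- c("0-15", "16-30", "31-45", ">45")

lure_age_bin <- function(age_days) {
  cut(age_days, breaks = c(-Inf, 15, 30, 45, Inf),
      labels = FALSE, right = TRUE)
}

#' Build two-species detection histories
#'
#' Tiles each deployment into occasions of `segment_days` from its start
#' (a trailing remnant is kept when it covers at least half a segment),
#' marks a species detected in an occasion when at least one independent
#' event falls in it, and attaches the occasion-level covariates: the
#' scent-lure age bin (days since the most recent lure application, at the
#' occasion midpoint; bins 0-15, 16-30, 31-45, >45) and the camera
#' trigger-speed class. By default only warm-season occasions from surveys
#' in 2011-2015 enter the histories, the closure-friendly subset.
#'
#' @param events independent detection events (see [independent_events()]).
#' @param deployments deployments with `camera_speed` and `lure_dates`.
#' @param species_a,species_b the two focal species codes.
#' @param segment_days occasion length in days (default 15).
#' @param years survey years to keep (`NULL` for all).
#' @param season `"warm"`, `"winter"` or `NULL` (all); filter applied at
#'   the occasion midpoint.
#' @param min_fraction minimum fraction of `segment_days` a trailing
#'   occasion must cover to be kept (default 0.5).
#' @return a `detection_history_pair`: site ids, observation matrices for
#'   both species (1/0/NA), lure-bin and camera-class matrices, and the
#'   occasion calendar.
#' @export
build_detection_histories <- function(events, deployments, species_a,
                                      species_b, segment_days = 15,
                                      years = 2011:2015, season = "warm",
                                      min_fraction = 0.5) {
  vocab <- unique(events$species)
  for (sp in c(species_a, species_b)) {
    if (!sp %in% vocab) {
      abort(sprintf("species '%s' absent from the event table's vocabulary", sp))
    }
  }
  occ <- deployments |>
    dplyr::mutate(.dep = dplyr::row_number()) |>
    dplyr::mutate(k = purrr::map2(.data$start, .data$end, function(s, e) {
      span <- as.numeric(e - s, units = "days")
      seq_len(max(1, ceiling(span / segment_days)))
    })) |>
    tidyr::unnest("k") |>
    dplyr::mutate(
      occ_start = .data$start + lubridate::ddays((.data$k - 1) * segment_days),
      occ_end = pmin(.data$end, .data$start + lubridate::ddays(.data$k * segment_days)),
      occ_len = as.numeric(.data$occ_end - .data$occ_start, units = "days")
    ) |>
    dplyr::filter(.data$occ_len >= min_fraction * segment_days |
                    .data$occ_len >= as.numeric(.data$end - .data$start, units = "days")) |>
    dplyr::mutate(
      midpoint = .data$occ_start + (.data$occ_end - .data$occ_start) / 2,
      mid_year = lubridate::year(.data$midpoint),
      mid_season = season_of_month(lubridate::month(.data$midpoint))
    )
  if (!is.null(years)) occ <- dplyr::filter(occ, .data$mid_year %in% !!years)
  if (!is.null(season)) occ <- dplyr::filter(occ, .data$mid_season == !!season)
  if (nrow(occ) == 0) abort("no occasions left after year/season filtering")
  occ$lure_age <- purrr::map2_dbl(
    occ$lure_dates, occ$midpoint,
    function(ld, mid) {
      ld <- ld[lubridate::as_datetime(ld) <= mid]
      if (length(ld) == 0) return(NA_real_)
      as.numeric(mid - lubridate::as_datetime(max(ld)), units = "days")
    }
  )
  # a deployment lured only after the midpoint behaves like a long-stale lure
  occ$lure_bin <- ifelse(is.na(occ$lure_age), 4L, lure_age_bin(occ$lure_age))
  occ$cam_slow <- as.integer(occ$camera_speed == "slow")

  count_in <- function(sp) {
    ev <- events[events$species == sp, ]
    purrr::pmap_int(
      list(occ$station_id, occ$occ_start, occ$occ_end),
      function(st, s, e) {
        as.integer(any(ev$station_id == st & ev$event_time >= s &
                         ev$event_time < e))
      }
    )
  }
  occ$det_a <- count_in(species_a)
  occ$det_b <- count_in(species_b)

  occ <- occ |>
    dplyr::arrange(.data$station_id, .data$occ_start) |>
    dplyr::group_by(.data$station_id) |>
    dplyr::mutate(j = dplyr::row_number()) |>
    dplyr::ungroup()
  sites <- sort(unique(occ$station_id))
  n_occ <- max(occ$j)
  to_matrix <- function(col) {
    m <- matrix(NA_real_, length(sites), n_occ,
                dimnames = list(sites, NULL))
    m[cbind(match(occ$station_id, sites), occ$j)] <- occ[[col]]
    m
  }
  structure(
    list(
      sites = sites,
      species_a = species_a, species_b = species_b,
      obs_a = to_matrix("det_a"), obs_b = to_matrix("det_b"),
      lure_bin = to_matrix("lure_bin"), cam_slow = to_matrix("cam_slow"),
      segment_days = segment_days,
      calendar = dplyr::select(
        occ, "station_id", occasion = "j", "occ_start", "occ_end",
        "lure_bin", "cam_slow"
      )
    ),
    class = "detection_history_pair"
  )
}

#' @export
print.detection_history_pair <- function(x, ...) {
  cat(sprintf(
    "Two-species detection histories: %s vs %s\n  %d sites x %d occasions (%g-day segments), %d non-missing occasions\n",
    x$species_a, x$species_b, length(x$sites), ncol(x$obs_a),
    x$segment_days, sum(!is.na(x$obs_a))
  ))
  invisible(x)
}

#' Enumerate the 16-model two-species occupancy set
#'
#' The full crossing of (species interaction factor free vs fixed at 1)
#' x (detection covariates none, Lr, Cam, Lr+Cam) x (detection when
#' co-occurring equal to or separate from detection when alone) gives 16
#' model specifications, named in the conventional psi/gamma/p/r notation:
#' absence of `γ(.)` means `γ = 1`, absence of `r(...)` means
#' `r = p`.
#'
#' @return a tibble with columns `model`, `gamma_free`, `p_covariates`
#'   (list-column), `r_equals_p`, `K` (free parameters under this
#'   package's counting: 2 occupancy intercepts + 1 if gamma is free +
#'   species intercepts and shared-covariate contrasts for p, and again
#'   for r when separate; Lr contributes 3 contrasts, Cam 1).
#' @export
enumerate_model_set <- function() {
  cov_sets <- list(character(0), "Lr", "Cam", c("Lr", "Cam"))
  grid <- tidyr::expand_grid(
    gamma_free = c(FALSE, TRUE),
    cov = cov_sets,
    r_equals_p = c(TRUE, FALSE)
  )
  purrr::pmap_dfr(grid, function(gamma_free, cov, r_equals_p) {
    tibble::tibble(
      model = model_name(gamma_free, cov, r_equals_p),
      gamma_free = gamma_free,
      p_covariates = list(cov),
      r_equals_p = r_equals_p,
      K = model_k(gamma_free, cov, r_equals_p)
    )
  })
}

n_contrasts <- function(cov) 3L * ("Lr" %in% cov) + 1L * ("Cam" %in% cov)

model_k <- function(gamma_free, cov, r_equals_p) {
  2L + as.integer(gamma_free) + (2L + n_contrasts(cov)) +
    if (r_equals_p) 0L else (2L + n_contrasts(cov))
}

model_name <- function(gamma_free, cov, r_equals_p) {
  cov_str <- paste0(c("S", cov), collapse = "+")
  paste0(
    "ψ(S)", if (gamma_free) "γ(.)" else "",
    "p(", cov_str, ")",
    if (!r_equals_p) paste0("r(", cov_str, ")") else ""
  )
}

as_model_spec <- function(spec) {
  if (inherits(spec, "data.frame")) {
    stopifnot(nrow(spec) == 1)
    spec <- list(
      model = spec$model, gamma_free = spec$gamma_free,
      p_covariates = spec$p_covariates[[1]], r_equals_p = spec$r_equals_p,
      K = spec$K
    )
  }
  spec$K <- spec$K %||%
    model_k(spec$gamma_free, spec$p_covariates, spec$r_equals_p)
  spec$model <- spec$model %||%
    model_name(spec$gamma_free, spec$p_covariates, spec$r_equals_p)
  spec
}

param_names <- function(spec) {
  cov <- spec$p_covariates
  cov_names <- c(
    if ("Lr" %in% cov) paste0("beta_lr", 2:4),
    if ("Cam" %in% cov) "beta_cam"
  )
  c(
    "logit_psi_a", "logit_psi_b",
    if (spec$gamma_free) "u_gamma",
    "alpha_p_a", "alpha_p_b", if (length(cov_names)) paste0(cov_names, "_p"),
    if (!spec$r_equals_p) c(
      "alpha_r_a", "alpha_r_b",
      if (length(cov_names)) paste0(cov_names, "_r")
    )
  )
}

# gamma mapped from an unconstrained parameter into the interval keeping
# all four latent-state probabilities in [0, 1]
gamma_bounds <- function(psi_a, psi_b) {
  c(
    lo = max(0, psi_a + psi_b - 1) / (psi_a * psi_b),
    hi = min(psi_a, psi_b) / (psi_a * psi_b)
  )
}

gamma_from_u <- function(u, psi_a, psi_b) {
  b <- gamma_bounds(psi_a, psi_b)
  b[["lo"]] + plogis(u) * (b[["hi"]] - b[["lo"]])
}

unpack_params <- function(params, spec) {
  nm <- param_names(spec)
  stopifnot(length(params) == length(nm))
  params <- setNames(as.numeric(params), nm)
  psi_a <- plogis(params[["logit_psi_a"]])
  psi_b <- plogis(params[["logit_psi_b"]])
  gamma <- if (spec$gamma_free) {
    gamma_from_u(params[["u_gamma"]], psi_a, psi_b)
  } else {
    1
  }
  list(params = params, psi_a = psi_a, psi_b = psi_b, gamma = gamma)
}

# linear predictor matrix for one detection process
detection_lp <- function(params, prefix, spec, hist) {
  cov <- spec$p_covariates
  suffix <- if (prefix == "p") "_p" else "_r"
  lp_a <- matrix(params[[paste0("alpha_", prefix, "_a")]],
                 nrow(hist$obs_a), ncol(hist$obs_a))
  lp_b <- matrix(params[[paste0("alpha_", prefix, "_b")]],
                 nrow(hist$obs_b), ncol(hist$obs_b))
  add <- 0
  if ("Lr" %in% cov) {
    lb <- hist$lure_bin
    add <- add + params[[paste0("beta_lr2", suffix)]] * (!is.na(lb) & lb == 2) +
      params[[paste0("beta_lr3", suffix)]] * (!is.na(lb) & lb == 3) +
      params[[paste0("beta_lr4", suffix)]] * (!is.na(lb) & lb == 4)
  }
  if ("Cam" %in% cov) {
    cs <- hist$cam_slow
    add <- add + params[[paste0("beta_cam", suffix)]] * (!is.na(cs) & cs == 1)
  }
  list(a = lp_a + add, b = lp_b + add)
}

occupancy_nll_factory <- function(hist, spec) {
  spec <- as_model_spec(spec)
  miss <- is.na(hist$obs_a)
  oa <- ifelse(miss, 0, hist$obs_a)
  ob <- ifelse(miss, 0, hist$obs_b)
  m <- 1 - miss
  any_a <- rowSums(oa) > 0
  any_b <- rowSums(ob) > 0
  r_equals_p <- spec$r_equals_p

  function(params) {
    if (any(!is.finite(params))) abort("non-finite parameters in likelihood")
    u <- unpack_params(params, spec)
    lp_p <- detection_lp(u$params, "p", spec, hist)
    lp_r <- if (r_equals_p) lp_p else detection_lp(u$params, "r", spec, hist)
    bern_ll <- function(obs, lp) {
      m * (obs * plogis(lp, log.p = TRUE) + (1 - obs) * plogis(-lp, log.p = TRUE))
    }
    ll_both <- rowSums(bern_ll(oa, lp_r$a) + bern_ll(ob, lp_r$b))
    ll_a_only <- ifelse(any_b, -Inf, rowSums(bern_ll(oa, lp_p$a)))
    ll_b_only <- ifelse(any_a, -Inf, rowSums(bern_ll(ob, lp_p$b)))
    ll_neither <- ifelse(any_a | any_b, -Inf, 0)
    pr <- pmax(1e-300, c(
      u$gamma * u$psi_a * u$psi_b,
      u$psi_a - u$gamma * u$psi_a * u$psi_b,
      u$psi_b - u$gamma * u$psi_a * u$psi_b,
      1 - u$psi_a - u$psi_b + u$gamma * u$psi_a * u$psi_b
    ))
    lmat <- cbind(
      log(pr[1]) + ll_both, log(pr[2]) + ll_a_only,
      log(pr[3]) + ll_b_only, log(pr[4]) + ll_neither
    )
    mx <- apply(lmat, 1, max)
    site_ll <- mx + log(rowSums(exp(lmat - mx)))
    -sum(site_ll)
  }
}

#' Negative log-likelihood of the two-species occupancy model
#'
#' Per site, the likelihood sums over the four latent co-occurrence states
#' (both, A only, B only, neither) whose probabilities derive from
#' `(psi_A, psi_B, gamma)`; conditional on the state, detections across
#' occasions are independent Bernoulli draws with probability `p` (other
#' species absent) or `r` (both present) on the logit scale, and a
#' detected species rules out states where it is absent. Missing occasions
#' contribute a factor of 1.
#'
#' @param params unconstrained parameter vector in the order given by the
#'   model spec: `logit(psi_A)`, `logit(psi_B)`, the gamma transform (if
#'   free), then detection intercepts and covariate coefficients for `p`
#'   (and `r` when separate).
#' @param histories a `detection_history_pair`.
#' @param spec one row of [enumerate_model_set()] (or an equivalent list).
#' @return the negative log-likelihood (scalar).
#' @export
two_species_nll <- function(params, histories, spec) {
  occupancy_nll_factory(histories, spec)(params)
}

default_start <- function(hist, spec) {
  naive_a <- mean(rowSums(hist$obs_a, na.rm = TRUE) > 0)
  naive_b <- mean(rowSums(hist$obs_b, na.rm = TRUE) > 0)
  clamp <- function(x) pmin(0.9, pmax(0.1, x))
  nm <- param_names(spec)
  st <- setNames(rep(0, length(nm)), nm)
  st[["logit_psi_a"]] <- qlogis(clamp(naive_a + 0.1))
  st[["logit_psi_b"]] <- qlogis(clamp(naive_b + 0.1))
  st[["alpha_p_a"]] <- qlogis(0.3)
  st[["alpha_p_b"]] <- qlogis(0.3)
  if (!spec$r_equals_p) {
    st[["alpha_r_a"]] <- qlogis(0.3)
    st[["alpha_r_b"]] <- qlogis(0.3)
  }
  st
}

random_start <- function(spec) {
  nm <- param_names(spec)
  st <- rnorm(length(nm), 0, 0.5)
  names(st) <- nm
  ints <- grep("^(logit_psi|alpha)", nm)
  st[ints] <- qlogis(runif(length(ints), 0.15, 0.85))
  st
}

#' Fit one two-species occupancy model
#'
#' Maximum likelihood via quasi-Newton (BFGS) optimisation with multiple
#' starts (one data-informed, the rest random). Standard errors come from
#' the numerically differentiated observed information; the standard error
#' of the species interaction factor uses the delta method through its
#' constraining transform.
#'
#' @param histories a `detection_history_pair`.
#' @param spec one row of [enumerate_model_set()].
#' @param n_starts number of optimisation starts (default 3).
#' @param seed optional seed for the random starts.
#' @param maxit maximum BFGS iterations per start.
#' @return an object of class `occu_pair_fit` with elements `estimates`
#'   (psi_a, psi_b, gamma and their SEs), `coefs` (tidy coefficient
#'   table), `neg2LL`, `K`, `AIC`, `convergence` and the spec.
#' @export
fit_occupancy_pair <- function(histories, spec, n_starts = 3, seed = NULL,
                               maxit = 500) {
  spec <- as_model_spec(spec)
  if (!any(rowSums(histories$obs_a, na.rm = TRUE) > 0) ||
      !any(rowSums(histories$obs_b, na.rm = TRUE) > 0)) {
    abort("each species must be detected at >= 1 site to fit the model")
  }
  if (!is.null(seed)) set.seed(seed)
  nll <- occupancy_nll_factory(histories, spec)
  starts <- c(
    list(default_start(histories, spec)),
    purrr::map(seq_len(max(0, n_starts - 1)), function(i) random_start(spec))
  )
  fits <- purrr::map(starts, function(st) {
    tryCatch(
      optim(st, nll, method = "BFGS", control = list(maxit = maxit)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  converged <- purrr::keep(fits, function(f) f$convergence == 0)
  pool <- if (length(converged) > 0) converged else fits
  if (length(pool) == 0) abort("all optimisation starts failed")
  best <- pool[[which.min(purrr::map_dbl(pool, "value"))]]
  hess <- tryCatch(
    optim(best$par, nll, method = "BFGS",
          control = list(maxit = 1), hessian = TRUE)$hessian,
    error = function(e) NULL
  )
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) sqrt(pmax(0, diag(vc))) else rep(NA_real_, length(best$par))
  u <- unpack_params(best$par, spec)

  transformed <- function(par) {
    uu <- unpack_params(par, spec)
    c(psi_a = uu$psi_a, psi_b = uu$psi_b, gamma = uu$gamma)
  }
  tr_se <- rep(NA_real_, 3)
  if (!is.null(vc)) {
    eps <- 1e-5
    jac <- vapply(seq_along(best$par), function(j) {
      hi <- lo <- best$par
      hi[j] <- hi[j] + eps; lo[j] <- lo[j] - eps
      (transformed(hi) - transformed(lo)) / (2 * eps)
    }, numeric(3))
    tr_vc <- jac %*% vc %*% t(jac)
    tr_se <- sqrt(pmax(0, diag(tr_vc)))
  }
  gamma_se <- if (spec$gamma_free) tr_se[3] else 0

  structure(
    list(
      spec = spec,
      model = spec$model,
      params = setNames(best$par, param_names(spec)),
      se = setNames(se, param_names(spec)),
      vcov = vc,
      estimates = tibble::tibble(
        term = c("psi_a", "psi_b", "gamma"),
        estimate = c(u$psi_a, u$psi_b, u$gamma),
        std.error = c(tr_se[1], tr_se[2], gamma_se)
      ),
      neg2LL = 2 * best$value,
      K = spec$K,
      AIC = 2 * best$value + 2 * spec$K,
      convergence = length(converged) > 0,
      n_sites = length(histories$sites) %||% nrow(histories$obs_a),
      n_occasions = ncol(histories$obs_a)
    ),
    class = "occu_pair_fit"
  )
}

#' @export
print.occu_pair_fit <- function(x, ...) {
  cat(sprintf("Two-species occupancy fit: %s\n", x$model))
  cat(sprintf(
    "  psi_A = %.3f, psi_B = %.3f, SIF gamma = %.3f +/- %.3f\n",
    x$estimates$estimate[1], x$estimates$estimate[2],
    x$estimates$estimate[3], x$estimates$std.error[3]
  ))
  cat(sprintf("  -2LL = %.2f, K = %d, AIC = %.2f%s\n", x$neg2LL, x$K, x$AIC,
              if (x$convergence) "" else " (NOT CONVERGED)"))
  invisible(x)
}

interpret_sif <- function(top) {
  if (all(!top$gamma_free)) return("independence")
  if (nrow(top) == 1 && top$gamma_free[1]) {
    if (top$gamma_hat[1] < 1) return("avoidance")
    if (top$gamma_hat[1] > 1) return("aggregation")
  }
  "unclear"
}

#' Fit and rank the two-species model set
#'
#' Fits every model in `models` to the detection histories, ranks the
#' converged fits by AIC, and summarises the species interaction factor
#' from the top set (all models within 2 AIC of the best). The
#' interpretation is `avoidance`/`aggregation` when a single gamma-free
#' top model estimates gamma below/above 1, `independence` when every top
#' model fixes gamma at 1, and `unclear` when the top set mixes the two
#' hypotheses.
#'
#' @param histories a `detection_history_pair`.
#' @param models a tibble of model specs (default [enumerate_model_set()]).
#' @param n_starts optimisation starts per model.
#' @param seed master seed (each model gets a deterministic child stream).
#' @return an object of class `cooccurrence_ranking`: `$table` (one row
#'   per converged model with `gamma_hat`, `gamma_se`, `delta_aic`, `K`,
#'   `neg2LL`), `$sif` (the SIF summary from the top set) and `$fits`.
#' @export
fit_cooccurrence <- function(histories, models = enumerate_model_set(),
                             n_starts = 3, seed = NULL) {
  fits <- purrr::map(seq_len(nrow(models)), function(i) {
    fit_occupancy_pair(histories, models[i, ], n_starts = n_starts,
                       seed = child_seed(seed, models$model[i]))
  })
  ok <- purrr::map_lgl(fits, "convergence")
  if (!any(ok)) abort("no model converged")
  if (any(!ok)) {
    warn(sprintf("%d model(s) failed to converge and were excluded from ranking",
                 sum(!ok)))
  }
  tab <- purrr::map_dfr(fits[ok], function(f) {
    tibble::tibble(
      model = f$model, gamma_free = f$spec$gamma_free,
      gamma_hat = f$estimates$estimate[3], gamma_se = f$estimates$std.error[3],
      K = f$K, neg2LL = f$neg2LL, AIC = f$AIC
    )
  }) |>
    dplyr::mutate(delta_aic = .data$AIC - min(.data$AIC)) |>
    dplyr::arrange(.data$delta_aic)
  top <- dplyr::filter(tab, .data$delta_aic < 2)
  sif <- list(
    gamma_hat = top$gamma_hat[1], se = top$gamma_se[1],
    interpretation = interpret_sif(top), top_models = top$model,
    species_a = histories$species_a, species_b = histories$species_b
  )
  structure(
    list(table = dplyr::select(
      tab, "model", "gamma_hat", "gamma_se", "delta_aic", "K", "neg2LL", "AIC",
      "gamma_free"
    ), sif = sif, fits = setNames(fits[ok], purrr::map_chr(fits[ok], "model"))),
    class = "cooccurrence_ranking"
  )
}

#' @export
print.cooccurrence_ranking <- function(x, ...) {
  cat(sprintf("Two-species co-occurrence ranking: %s vs %s\n",
              x$sif$species_a %||% "A", x$sif$species_b %||% "B"))
  print(dplyr::select(x$table, "model", "gamma_hat", "gamma_se",
                      "delta_aic", "K", "neg2LL"), n = 5)
  cat(sprintf("SIF from top set: gamma = %.2f +/- %.2f (%s)\n",
              x$sif$gamma_hat, x$sif$se, x$sif$interpretation))
  invisible(x)
}

#' Simulate two-species detection histories at the occasion level
#'
#' Draws latent site states from the four-state distribution implied by
#' `(psi_a, psi_b, gamma)` and occasion-level Bernoulli detections with
#' probability `p` (other species absent) or `r` (both present). Useful
#' for parameter-recovery and power studies of the occupancy machinery in
#' isolation from the event pipeline.
#'
#' @param n_sites,n_occasions dimensions of the history matrices.
#' @param psi_a,psi_b marginal occupancy probabilities.
#' @param gamma species interaction factor (must keep the four state
#'   probabilities in `[0, 1]`).
#' @param p,r detection probabilities (default `r = p`).
#' @param seed optional seed.
#' @return a `detection_history_pair` with constant covariates and a
#'   `truth` attribute recording the parameters and latent states.
#' @export
simulate_pair_histories <- function(n_sites, n_occasions, psi_a, psi_b,
                                    gamma = 1, p = 0.3, r = p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- c(
    gamma * psi_a * psi_b,
    psi_a - gamma * psi_a * psi_b,
    psi_b - gamma * psi_a * psi_b,
    1 - psi_a - psi_b + gamma * psi_a * psi_b
  )
  if (any(pr < -1e-12) || any(pr > 1 + 1e-12)) {
    abort("gamma is infeasible for the given psi_a, psi_b")
  }
  pr <- pmax(0, pr)
  state <- sample.int(4, n_sites, replace = TRUE, prob = pr)
  za <- state %in% c(1, 2)
  zb <- state %in% c(1, 3)
  det_p_a <- ifelse(state == 1, r, p)
  det_p_b <- ifelse(state == 1, r, p)
  obs_a <- matrix(rbinom(n_sites * n_occasions, 1, rep(det_p_a * za, n_occasions)),
                  n_sites, n_occasions)
  obs_b <- matrix(rbinom(n_sites * n_occasions, 1, rep(det_p_b * zb, n_occasions)),
                  n_sites, n_occasions)
  sites <- sprintf("S%04d", seq_len(n_sites))
  dimnames(obs_a) <- dimnames(obs_b) <- list(sites, NULL)
  ones <- matrix(1, n_sites, n_occasions, dimnames = list(sites, NULL))
  structure(
    list(
      sites = sites, species_a = "A", species_b = "B",
      obs_a = obs_a, obs_b = obs_b,
      lure_bin = ones, cam_slow = 0 * ones,
      segment_days = 15, calendar = NULL,
      truth = list(psi_a = psi_a, psi_b = psi_b, gamma = gamma, p = p, r = r,
                   z_a = za, z_b = zb)
    ),
    class = "detection_history_pair"
  )
}

#' Write / read a detection-history interchange file
#'
#' The observation matrix is serialised as one row of symbols per site
#' (`0` neither, `A`, `B`, `X` both, `.` missing) beside the site id; the
#' occasion covariates go to a sidecar CSV. The round trip is bit-exact.
#'
#' @param histories a `detection_history_pair`.
#' @param path base path; `path` gets the matrix, `path` + `.covariates.csv`
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_detection_histories <- function(histories, path) {
  sym <- matrix(".", nrow(histories$obs_a), ncol(histories$obs_a))
  oa <- histories$obs_a; ob <- histories$obs_b
  sym[!is.na(oa) & oa == 0 & ob == 0] <- "0"
  sym[!is.na(oa) & oa == 1 & ob == 0] <- "A"
  sym[!is.na(oa) & oa == 0 & ob == 1] <- "B"
  sym[!is.na(oa) & oa == 1 & ob == 1] <- "X"
  lines <- c(
    sprintf("# species_a=%s species_b=%s segment_days=%g",
            histories$species_a, histories$species_b, histories$segment_days),
    paste(histories$sites, apply(sym, 1, paste0, collapse = ""))
  )
  writeLines(lines, path)
  cov <- tibble::tibble(
    site = rep(histories$sites, ncol(histories$obs_a)),
    occasion = rep(seq_len(ncol(histories$obs_a)), each = nrow(histories$obs_a)),
    lure_bin = as.vector(histories$lure_bin),
    cam_slow = as.vector(histories$cam_slow)
  )
  readr::write_csv(cov[!is.na(cov$lure_bin) | !is.na(cov$cam_slow), ],
                   paste0(path, ".covariates.csv"))
  invisible(path)
}

#' @rdname write_detection_histories
#' @param path base path written by [write_detection_histories()].
#' @return for `read_detection_histories()`, the reconstructed
#'   `detection_history_pair`.
#' @export
read_detection_histories <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- setNames(
    sub("^[^=]+=", "", hdr),
    sub("=.*$", "", hdr)
  )
  body <- strsplit(lines[-1], " ")
  sites <- purrr::map_chr(body, 1)
  rows <- purrr::map(body, function(x) strsplit(x[2], "")[[1]])
  n_occ <- max(lengths(rows))
  sym <- t(vapply(rows, function(r) c(r, rep(".", n_occ - length(r))),
                  character(n_occ)))
  obs_a <- ifelse(sym == ".", NA_real_, as.numeric(sym %in% c("A", "X")))
  obs_b <- ifelse(sym == ".", NA_real_, as.numeric(sym %in% c("B", "X")))
  dimnames(obs_a) <- dimnames(obs_b) <- list(sites, NULL)
  cov <- readr::read_csv(paste0(path, ".covariates.csv"),
                         show_col_types = FALSE, progress = FALSE)
  lure <- cam <- matrix(NA_real_, length(sites), n_occ,
                        dimnames = list(sites, NULL))
  idx <- cbind(match(cov$site, sites), cov$occasion)
  lure[idx] <- cov$lure_bin
  cam[idx] <- cov$cam_slow
  structure(
    list(
      sites = sites, species_a = kv[["species_a"]], species_b = kv[["species_b"]],
      obs_a = obs_a, obs_b = obs_b, lure_bin = lure, cam_slow = cam,
      segment_days = as.numeric(kv[["segment_days"]]), calendar = NULL
    ),
    class = "detection_history_pair"
  )
}
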