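# Diel activity estimation: circular kernel density on the 24-h sun-time
# cycle with a von Mises plug-in bandwidth, the coefficient of overlap
# between two activity densities, and smoothed-bootstrap confidence
# intervals.

#' Plug-in kernel concentration for circular KDE
#'
#' The plug-in rule computes the kernel concentration from the ML von
#' Mises concentration `kappa` of the sample:
#' `((3 n kappa^2 I2(2 kappa)) / (4 sqrt(pi) I1(kappa)^2))^(2/5)`,
#' divided by the smoothing multiplier `adjust` (so `adjust > 1` smooths
#' more).
#'
#' @param kappa ML von Mises concentration of the sample.
#' @param n sample size (`>= 2`).
#' @param adjust smoothing multiplier; the kernel concentration is the
#'   plug-in value divided by `adjust` (default 1).
#' @param min_kappa floor used when `kappa = 0` (uniform sample), so the
#'   kernel stays proper.
#' @return the kernel concentration (a positive scalar).
#' @export
plugin_bandwidth <- function(kappa, n, adjust = 1, min_kappa = 0.01) {
  stopifnot(kappa >= 0, n >= 2, adjust > 0)
  if (kappa < min_kappa) {
    warn("sample concentration ~0; using minimal positive kernel concentration")
    kappa <- min_kappa
  }
  # exponentially scaled Bessels: the e^{2k} factors cancel exactly in
  # I2(2k) / I1(k)^2
  ratio <- besselI(2 * kappa, 2, expon.scaled = TRUE) /
    besselI(kappa, 1, expon.scaled = TRUE)^2
  (3 * n * kappa^2 * ratio / (4 * sqrt(pi)))^(2 / 5) / adjust
}

# density of the kernel mixture at angles `at` (radians)
kde_eval <- function(at, sample_theta, kappa_kernel) {
  i0 <- besselI(kappa_kernel, 0, expon.scaled = TRUE)
  k <- exp(kappa_kernel * (cos(outer(at, sample_theta, "-")) - 1)) /
    (2 * pi * i0)
  rowMeans(k)
}

#' Fit a circular kernel density of diel activity
#'
#' Treats detection times as a random sample from the species' continuous
#' diel activity distribution and estimates the density with a von Mises
#' kernel whose concentration comes from [plugin_bandwidth()].
#'
#' @param x detection times as sun-time hours in `[0, 24)` (or radians if
#'   `units = "radians"`).
#' @param adjust smoothing multiplier (default 1, the study convention).
#' @param kappa_max cap for the ML concentration.
#' @param grid_n number of equally spaced evaluation points (default 128).
#' @param units `"hours"` or `"radians"`.
#' @return an object of class `activity_density`: the sample (radians),
#'   `n`, `kappa_ml`, `kappa_kernel`, `adjust` and a `grid` tibble
#'   (`theta`, `hour`, `density`) whose density integrates to 1 over the
#'   cycle. Densities are per radian.
#' @export
fit_activity <- function(x, adjust = 1, kappa_max = 500, grid_n = 128,
                         units = c("hours", "radians")) {
  units <- match.arg(units)
  stopifnot(length(x) >= 1)
  theta <- if (units == "hours") hours_to_radians(x %% 24) else x %% (2 * pi)
  kappa_ml <- vonmises_kappa_ml(theta, kappa_max)
  kappa_kernel <- if (length(theta) >= 2) {
    plugin_bandwidth(kappa_ml, length(theta), adjust)
  } else {
    max(kappa_ml, 1) / adjust
  }
  grid_theta <- seq(0, 2 * pi, length.out = grid_n + 1)[seq_len(grid_n)]
  dens <- kde_eval(grid_theta, theta, kappa_kernel)
  structure(
    list(
      sample = theta, n = length(theta),
      kappa_ml = kappa_ml, kappa_kernel = kappa_kernel, adjust = adjust,
      grid = tibble::tibble(
        theta = grid_theta,
        hour = radians_to_hours(grid_theta),
        density = dens
      )
    ),
    class = "activity_density"
  )
}

#' @export
print.activity_density <- function(x, ...) {
  cat(sprintf(
    "Circular activity density: n = %d, kappa_ml = %.3f, kernel = %.3f (adjust = %g)\n",
    x$n, x$kappa_ml, x$kappa_kernel, x$adjust
  ))
  invisible(x)
}

#' Evaluate a fitted activity density
#'
#' @param object an `activity_density`.
#' @param at times at which to evaluate (same units as requested).
#' @param units `"hours"` or `"radians"`.
#' @param ... unused.
#' @return densities per radian at `at`.
#' @export
predict.activity_density <- function(object, at, units = c("hours", "radians"),
                                     ...) {
  units <- match.arg(units)
  theta <- if (units == "hours") hours_to_radians(at %% 24) else at %% (2 * pi)
  kde_eval(theta, object$sample, object$kappa_kernel)
}

# trapezoid integral of values on an equally spaced periodic grid
circular_trapezoid <- function(values, grid_n = length(values)) {
  sum(values) * 2 * pi / grid_n
}

new_overlap_estimate <- function(delta, estimator, dhat1, dhat4, n1, n2,
                                 ci_low = NA_real_, ci_high = NA_real_,
                                 conf = NA_real_, n_boot = NA_integer_,
                                 seed = NULL, fits = NULL) {
  structure(
    list(
      delta = delta, estimator = estimator, dhat1 = dhat1, dhat4 = dhat4,
      n1 = n1, n2 = n2, ci_low = ci_low, ci_high = ci_high, conf = conf,
      n_boot = n_boot, seed = seed, fits = fits
    ),
    class = "overlap_estimate"
  )
}

#' @export
print.overlap_estimate <- function(x, ...) {
  cat(sprintf("Coefficient of overlap: Dhat = %.3f (%s; Dhat1 = %.3f, Dhat4 = %.3f)\n",
              x$delta, x$estimator, x$dhat1, x$dhat4))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %g%% CI: %.3f-%.3f (%d bootstrap replicates)\n",
                100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  }
  invisible(x)
}

choose_estimator <- function(estimator, n1, n2, threshold = 75) {
  estimator <- match.arg(estimator, c("auto", "Dhat1", "Dhat4"))
  if (estimator == "auto") {
    if (min(n1, n2) < threshold) "Dhat1" else "Dhat4"
  } else {
    estimator
  }
}

compute_dhats <- function(fit_a, fit_b, grid_n = 128, floor = 1e-12) {
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)[seq_len(grid_n)]
  fa <- kde_eval(grid, fit_a$sample, fit_a$kappa_kernel)
  fb <- kde_eval(grid, fit_b$sample, fit_b$kappa_kernel)
  dhat1 <- circular_trapezoid(pmin(fa, fb), grid_n)
  f_at_x <- pmax(floor, kde_eval(fit_a$sample, fit_a$sample, fit_a$kappa_kernel))
  g_at_x <- kde_eval(fit_a$sample, fit_b$sample, fit_b$kappa_kernel)
  f_at_y <- kde_eval(fit_b$sample, fit_a$sample, fit_a$kappa_kernel)
  g_at_y <- pmax(floor, kde_eval(fit_b$sample, fit_b$sample, fit_b$kappa_kernel))
  dhat4 <- 0.5 * (mean(pmin(1, g_at_x / f_at_x)) + mean(pmin(1, f_at_y / g_at_y)))
  list(dhat1 = dhat1, dhat4 = dhat4)
}

#' Coefficient of overlap between two activity densities
#'
#' The coefficient of overlap `Dhat` is the area under the pointwise
#' minimum of the two densities; it ranges from 0 (no overlap) to 1
#' (identical activity). `Dhat1` integrates the minimum of the two kernel
#' densities on a shared grid; `Dhat4` averages density ratios at the
#' observed points and is preferred for larger samples. With
#' `estimator = "auto"`, `Dhat1` is used when the smaller sample has fewer
#' than 75 observations, `Dhat4` otherwise; both are always reported.
#'
#' @param fit_a,fit_b `activity_density` objects (see [fit_activity()]).
#' @param estimator `"auto"`, `"Dhat1"` or `"Dhat4"`.
#' @param grid_n grid size for the `Dhat1` integral.
#' @return an `overlap_estimate` (point estimate only; see
#'   [bootstrap_overlap_ci()] for confidence intervals).
#' @export
overlap_coefficient <- function(fit_a, fit_b, estimator = "auto",
                                grid_n = 128) {
  stopifnot(inherits(fit_a, "activity_density"),
            inherits(fit_b, "activity_density"))
  est <- choose_estimator(estimator, fit_a$n, fit_b$n)
  d <- compute_dhats(fit_a, fit_b, grid_n)
  new_overlap_estimate(
    delta = if (est == "Dhat1") d$dhat1 else d$dhat4,
    estimator = est, dhat1 = d$dhat1, dhat4 = d$dhat4,
    n1 = fit_a$n, n2 = fit_b$n, fits = list(a = fit_a, b = fit_b)
  )
}

#' Smoothed-bootstrap confidence interval for the overlap coefficient
#'
#' Each replicate draws samples of the original sizes from the two fitted
#' kernel densities (a smoothed bootstrap: resample the data, then add von
#' Mises kernel noise), refits both densities and recomputes `Dhat`. The
#' interval is the percentile interval by default; `"normal"` and
#' `"basic"` intervals are available.
#'
#' @param x,y detection times (sun-time hours) for the two groups.
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level.
#' @param estimator passed to [overlap_coefficient()].
#' @param adjust smoothing multiplier for all fits.
#' @param ci_type `"percentile"`, `"normal"` or `"basic"`.
#' @param grid_n grid size for `Dhat1`.
#' @param seed optional integer seed for reproducibility.
#' @return an `overlap_estimate` with `ci_low`/`ci_high` filled in and the
#'   bootstrap replicates in `$boot`.
#' @export
bootstrap_overlap_ci <- function(x, y, n_boot = 10000, conf = 0.95,
                                 estimator = "auto", adjust = 1,
                                 ci_type = c("percentile", "normal", "basic"),
                                 grid_n = 128, seed = NULL) {
  ci_type <- match.arg(ci_type)
  if (!is.null(seed)) set.seed(seed)
  fit_a <- fit_activity(x, adjust = adjust)
  fit_b <- fit_activity(y, adjust = adjust)
  est <- choose_estimator(estimator, fit_a$n, fit_b$n)
  point <- overlap_coefficient(fit_a, fit_b, estimator = est, grid_n = grid_n)
  draw_smoothed <- function(fit) {
    centers <- sample(fit$sample, fit$n, replace = TRUE)
    (centers + rvonmises(fit$n, 0, fit$kappa_kernel)) %% (2 * pi)
  }
  boot <- vapply(seq_len(n_boot), function(i) {
    fa <- fit_activity(draw_smoothed(fit_a), adjust = adjust, units = "radians")
    fb <- fit_activity(draw_smoothed(fit_b), adjust = adjust, units = "radians")
    d <- compute_dhats(fa, fb, grid_n)
    if (est == "Dhat1") d$dhat1 else d$dhat4
  }, numeric(1))
  alpha <- 1 - conf
  ci <- switch(ci_type,
    percentile = unname(quantile(boot, c(alpha / 2, 1 - alpha / 2))),
    normal = point$delta + c(-1, 1) * stats::qnorm(1 - alpha / 2) * sd(boot),
    basic = 2 * point$delta -
      unname(quantile(boot, c(1 - alpha / 2, alpha / 2)))
  )
  ci <- pmin(1, pmax(0, ci))
  if (point$delta < ci[1] || point$delta > ci[2]) {
    warn("overlap point estimate lies outside its bootstrap interval")
  }
  out <- new_overlap_estimate(
    delta = point$delta, estimator = est,
    dhat1 = point$dhat1, dhat4 = point$dhat4,
    n1 = fit_a$n, n2 = fit_b$n,
    ci_low = ci[1], ci_high = ci[2], conf = conf,
    n_boot = as.integer(n_boot), seed = seed,
    fits = list(a = fit_a, b = fit_b)
  )
  out$boot <- boot
  out
}

#' Pairwise overlap matrix for a set of species
#'
#' Convenience wrapper computing [bootstrap_overlap_ci()] (or the point
#' estimate when `n_boot = 0`) for every pair of species in an annotated
#' event table.
#'
#' @param events annotated events with `species` and `sun_time` columns
#'   (see [annotate_events()]).
#' @param species species to include; default all with `>= min_n` events.
#' @param min_n minimum events per species.
#' @param n_boot bootstrap replicates per pair (0 to skip intervals).
#' @param seed master seed; each pair gets a deterministic child stream.
#' @inheritParams bootstrap_overlap_ci
#' @return a tibble with one row per unordered species pair: `delta`,
#'   `estimator`, `dhat1`, `dhat4`, `n1`, `n2`, `ci_low`, `ci_high`.
#' @export
overlap_matrix <- function(events, species = NULL, min_n = 10, n_boot = 10000,
                           adjust = 1, conf = 0.95, seed = NULL) {
  assert_columns(events, c("species", "sun_time"), "annotated events")
  counts <- dplyr::count(events, .data$species)
  species <- species %||% counts$species[counts$n >= min_n]
  pairs <- utils::combn(sort(species), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    x <- events$sun_time[events$species == a]
    y <- events$sun_time[events$species == b]
    o <- if (n_boot > 0) {
      bootstrap_overlap_ci(
        x, y, n_boot = n_boot, conf = conf, adjust = adjust,
        seed = child_seed(seed, paste(a, b))
      )
    } else {
      overlap_coefficient(fit_activity(x, adjust), fit_activity(y, adjust))
    }
    tibble::tibble(
      species_a = a, species_b = b, delta = o$delta, estimator = o$estimator,
      dhat1 = o$dhat1, dhat4 = o$dhat4, n1 = o$n1, n2 = o$n2,
      ci_low = o$ci_low, ci_high = o$ci_high
    )
  })
}
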