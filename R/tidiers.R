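# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' @exportS3Method generics::tidy
tidy.activity_density <- function(x, ...) {
  x$grid
}

#' @exportS3Method generics::glance
glance.activity_density <- function(x, ...) {
  tibble::tibble(
    n = x$n, kappa_ml = x$kappa_ml, kappa_kernel = x$kappa_kernel,
    adjust = x$adjust,
    integral = circular_trapezoid(x$grid$density, nrow(x$grid))
  )
}

#' @exportS3Method generics::tidy
tidy.overlap_estimate <- function(x, ...) {
  tibble::tibble(
    estimator = c("Dhat1", "Dhat4"),
    estimate = c(x$dhat1, x$dhat4),
    selected = c(x$estimator == "Dhat1", x$estimator == "Dhat4")
  )
}

#' @exportS3Method generics::glance
glance.overlap_estimate <- function(x, ...) {
  tibble::tibble(
    delta = x$delta, estimator = x$estimator, n1 = x$n1, n2 = x$n2,
    ci_low = x$ci_low, ci_high = x$ci_high, conf = x$conf, n_boot = x$n_boot
  )
}

#' @exportS3Method generics::tidy
tidy.occu_pair_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$estimates,
    tibble::tibble(term = names(x$params), estimate = as.numeric(x$params),
                   std.error = as.numeric(x$se))
  )
}

#' @exportS3Method generics::glance
glance.occu_pair_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, K = x$K, neg2LL = x$neg2LL, AIC = x$AIC,
    converged = x$convergence, n_sites = x$n_sites,
    n_occasions = x$n_occasions
  )
}

#' @exportS3Method generics::tidy
tidy.cooccurrence_ranking <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.cooccurrence_ranking <- function(x, ...) {
  tibble::tibble(
    species_a = x$sif$species_a, species_b = x$sif$species_b,
    gamma_hat = x$sif$gamma_hat, gamma_se = x$sif$se,
    interpretation = x$sif$interpretation,
    n_top_models = length(x$sif$top_models),
    n_models = nrow(x$table)
  )
}

#' Plot a diel activity density
#'
#' Kernel density on the sun-time axis (sunrise at 06:00, sunset at
#' 18:00); density is rescaled to "per hour" so the curve integrates to 1
#' over the 24-h cycle.
#'
#' @param object an `activity_density`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.activity_density <- function(object, ...) {
  df <- object$grid
  df$per_hour <- df$density * 2 * pi / 24
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$per_hour)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(6, 18), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Sun time (h)", y = "Activity density (per hour)") +
    ggplot2::theme_minimal()
}

#' Plot two activity densities with their overlap shaded
#'
#' @param object an `overlap_estimate` carrying its fitted densities.
#' @param names labels for the two groups.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.overlap_estimate <- function(object, names = c("A", "B"), ...) {
  if (is.null(object$fits)) abort("overlap estimate carries no fitted densities")
  grid <- object$fits$a$grid$hour
  fa <- object$fits$a$grid$density * 2 * pi / 24
  fb <- predict(object$fits$b, grid) * 2 * pi / 24
  df <- tibble::tibble(
    hour = rep(grid, 2),
    density = c(fa, fb),
    group = rep(names, each = length(grid))
  )
  shade <- tibble::tibble(hour = grid, density = pmin(fa, fb))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$density)) +
    ggplot2::geom_area(data = shade, fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$group)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(
      x = "Sun time (h)", y = "Activity density (per hour)",
      linetype = NULL,
      subtitle = sprintf("Overlap Dhat = %.2f", object$delta)
    ) +
    ggplot2::theme_minimal()
}

#' Plot monthly relative activity indices
#'
#' @param rai output of [monthly_rai()].
#' @return a ggplot faceted by species.
#' @export
plot_rai <- function(rai) {
  ggplot2::ggplot(rai, ggplot2::aes(x = factor(.data$month), y = .data$rai)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "Month", y = "Detections per 1,000 camera-days") +
    ggplot2::theme_minimal()
}
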