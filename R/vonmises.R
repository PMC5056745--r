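# von Mises primitives used by the circular KDE and the synthetic generator.
# All angles are radians on [0, 2*pi); the exponentially scaled Bessel
# functions keep every expression finite up to the kappa cap.

#' von Mises density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, evaluated at angles `theta` (radians).
#' `kappa = 0` gives the circular uniform density `1 / (2 pi)`.
#'
#' @param theta numeric vector of angles in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of densities.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  # besselI(..., expon.scaled) = exp(-kappa) I0(kappa), so the ratio below
  # is exp(kappa * (cos(d) - 1)) / I0.scaled -- stable for large kappa
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler; exact for all
#' `kappa >= 0` (uniform when `kappa = 0`).
#'
#' @param n sample size.
#' @inheritParams dvonmises
#' @return numeric vector of `n` angles on `[0, 2 pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(f[keep])
    take <- theta[seq_len(min(length(theta), n - got))]
    out[got + seq_along(take)] <- take
    got <- got + length(take)
  }
  (out + mu) %% (2 * pi)
}

# A1(kappa) = I1(kappa) / I0(kappa): mean resultant length of a von Mises
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves `A1(kappa) = Rbar` for the sample mean resultant length `Rbar`,
#' by monotone root bracketing of `A1 = I1/I0`. Degenerate samples
#' (`Rbar` at or numerically near 1) return `kappa_max`.
#'
#' @param theta angles in radians.
#' @param kappa_max cap on the returned concentration (default 500).
#' @return the ML concentration estimate `kappa`.
#' @export
vonmises_kappa_ml <- function(theta, kappa_max = 500) {
  stopifnot(length(theta) >= 1)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar <= 0) return(0)
  if (rbar >= vm_a1(kappa_max)) return(kappa_max)
  uniroot(function(k) vm_a1(k) - rbar, c(1e-12, kappa_max), tol = 1e-10)$root
}
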