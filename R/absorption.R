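#' Bi-exponential carbohydrate absorption rate
#'
#' Rate of appearance of glucose from an oral carbohydrate load under the
#' two-compartment gut model with equal transfer constants, which collapses
#' to the closed form
#' \deqn{Ra(t) = D \, f \, t \, e^{-t/\tau_{max}} / \tau_{max}^2,}
#' where \eqn{D} is the dose (g), \eqn{f} the carbohydrate bioavailability
#' and \eqn{\tau_{max}} the time-to-peak (min). The rate is zero at the
#' instant of ingestion, peaks at \eqn{t = \tau_{max}} and integrates to
#' \eqn{D f} over \eqn{[0, \infty)}.
#'
#' @param dose Carbohydrate dose in grams (>= 0).
#' @param bioavailability Fraction of the dose that appears in plasma,
#'   in (0, 1].
#' @param tau_max Time-to-peak of absorption in minutes (> 0).
#' @param t_since Minutes elapsed since ingestion (vectorised); negative
#'   times return 0.
#' @return Absorption rate in g/min, same length as `t_since`.
#' @examples
#' cho_absorption_rate(30, 1, 40, c(0, 40, 200))
#' @export
cho_absorption_rate <- function(dose, bioavailability, tau_max, t_since) {
  if (!is.numeric(tau_max) || any(tau_max <= 0)) {
    stop("`tau_max` must be strictly positive", call. = FALSE)
  }
  if (dose < 0) stop("`dose` must be non-negative", call. = FALSE)
  if (bioavailability <= 0 || bioavailability > 1) {
    stop("`bioavailability` must lie in (0, 1]", call. = FALSE)
  }
  t <- pmax(t_since, 0)
  dose * bioavailability * t * exp(-t / tau_max) / tau_max^2
}

#' Cumulative fraction of a carbohydrate dose absorbed
#'
#' Closed-form integral of the bi-exponential absorption curve:
#' \eqn{F(t) = 1 - (1 + t/\tau_{max}) e^{-t/\tau_{max}}}.
#'
#' @inheritParams cho_absorption_rate
#' @return Fraction in [0, 1), same length as `t_since`.
#' @export
cho_absorbed_fraction <- function(tau_max, t_since) {
  if (any(tau_max <= 0)) stop("`tau_max` must be strictly positive", call. = FALSE)
  t <- pmax(t_since, 0)
  1 - (1 + t / tau_max) * exp(-t / tau_max)
}
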