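# Rate and generation-time arithmetic.

#' Average generation time from age at maturity and adult survival
#'
#' T = a + s/(1 - s) (Lande et al.): age at first breeding plus the mean
#' number of further breeding seasons implied by a constant annual adult
#' survival rate s.
#'
#' @param a age at maturity (years).
#' @param s annual adult survival rate, 0 <= s < 1.
#' @return generation time in years.
#' @export
generation_time <- function(a, s) {
  stopifnot(a >= 0)
  if (any(s < 0) || any(s >= 1)) stop("survival rate must satisfy 0 <= s < 1")
  a + s / (1 - s)
}

#' Geometric mean of substitution rates
#'
#' @param rates positive numeric vector of rates.
#' @return exp(mean(log(rates))).
#' @export
geometric_mean_rate <- function(rates) {
  if (any(rates <= 0)) stop("all rates must be positive")
  exp(mean(log(rates)))
}

#' Convert a per-generation rate to a per-year rate
#'
#' @param mu_gen mutation rate per generation.
#' @param T generation time in years (> 0).
#' @return mu_gen / T.
#' @export
per_generation_to_per_year <- function(mu_gen, T) {
  if (any(T <= 0)) stop("generation time must be positive")
  mu_gen / T
}
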