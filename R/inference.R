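#' Moment estimator of theta from SMM equilibrium heterozygosity
#'
#' Inverts the stepwise-mutation-model equilibrium relation
#' \eqn{H_e = 1 - 1/\sqrt{1 + 2\theta}} to
#' \eqn{\theta = ((1/(1 - H_e))^2 - 1)/2}.
#'
#' @param he gene diversity in \code{[0, 1)}.
#' @return theta (\eqn{4 \mu N_e}).
#' @examples
#' theta_from_he_smm(1 - 1/3) # 4
#' @export
theta_from_he_smm <- function(he) {
  if (any(he < 0 | he >= 1)) stop("He must be in [0, 1)")
  ((1 / (1 - he))^2 - 1) / 2
}

#' Equilibrium heterozygosity under the stepwise mutation model
#'
#' @param theta scaled mutation parameter \eqn{4 \mu N_e}.
#' @return \eqn{1 - 1/\sqrt{1 + 2\theta}}.
#' @export
he_smm_equilibrium <- function(theta) {
  stopifnot(all(theta >= 0))
  1 - 1 / sqrt(1 + 2 * theta)
}

#' Effective population size from theta
#'
#' \eqn{N_e = \theta / (4\mu)} for a diploid genome.
#'
#' @param theta scaled mutation parameter.
#' @param mu per-allele per-generation mutation rate.
#' @export
ne_from_theta <- function(theta, mu) {
  if (any(mu <= 0)) stop("mu must be > 0")
  theta / (4 * mu)
}

#' Expected TMRCA in years from theta
#'
#' Uses the large-sample coalescent expectation of \eqn{4 N_e} generations
#' for the time to the most recent common ancestor, i.e.
#' \eqn{(\theta/\mu)} generations, converted with the generation time.
#'
#' @param theta scaled mutation parameter.
#' @param mu per-allele per-generation mutation rate.
#' @param generation_time years per generation.
#' @return TMRCA in years.
#' @examples
#' tmrca_from_theta(7.033, 0.01, 12) # 8439.6 years, i.e. ~8.44 ka
#' @export
tmrca_from_theta <- function(theta, mu, generation_time) {
  if (any(mu <= 0)) stop("mu must be > 0")
  (theta / mu) * generation_time
}

#' Theta trajectory under exponential growth
#'
#' \eqn{\theta_t = \theta_{now} \exp(-g t)} with \eqn{t} measured backward in
#' mutational time units.  Under this convention a positive \eqn{g} means a
#' smaller parameter (smaller population) in the past, i.e. forward-in-time
#' growth; \code{backward_growth = TRUE} flips the sign for the opposite
#' reading.
#'
#' @param theta_now present-day theta.
#' @param g_rate exponential growth parameter per mutational time unit.
#' @param t time to coalescence in mutational units.
#' @param backward_growth flip the sign convention.
#' @export
theta_at_time <- function(theta_now, g_rate, t, backward_growth = FALSE) {
  s <- if (backward_growth) -1 else 1
  theta_now * exp(-s * g_rate * t)
}

#' Migrants per generation from the scaled migration rate
#'
#' \eqn{N_e m = M \theta / 4} where \eqn{M = 4 N_e m / \theta}.
#'
#' @param M scaled migration rate.
#' @param theta scaled mutation parameter.
#' @export
nem_from_migration <- function(M, theta) {
  if (any(M < 0) || any(theta < 0)) stop("M and theta must be >= 0")
  M * theta / 4
}

#' Coalescent parameter report
#'
#' Bundles the closed-form conversions: theta from mean He (SMM moment
#' estimator), Ne, and TMRCA in years.
#'
#' @param he mean expected heterozygosity.
#' @param mu mutation rate per allele per generation.
#' @param generation_time years per generation.
#' @return list with \code{theta}, \code{Ne}, \code{tmrca_years}.
#' @export
coalescent_params <- function(he, mu = 0.01, generation_time = 12) {
  theta <- theta_from_he_smm(he)
  list(theta = theta,
       Ne = ne_from_theta(theta, mu),
       tmrca_years = tmrca_from_theta(theta, mu, generation_time))
}
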