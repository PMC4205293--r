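#' Reference distribution of simulated mean diversity for one scenario
#'
#' Repeats the full coalescent + stepwise-mutation simulation and records,
#' per replicate, the expected heterozygosity averaged over loci and demes --
#' the statistic compared against the observed mean diversity during model
#' selection.
#'
#' @param scenario a \code{"demographic_scenario"}.
#' @param config a \code{"simulation_config"}.
#' @param R number of replicates.
#' @return numeric vector of R replicate mean-He values.
#' @export
simulate_reference_distribution <- function(scenario, config, R = 2000L) {
  stopifnot(R >= 1)
  vapply(seq_len(R), function(i) {
    gd <- simulate_dataset(scenario, config)
    mean_he_dataset(gd)
  }, numeric(1))
}

#' Mean expected heterozygosity of a dataset
#'
#' Nei's unbiased He per population and locus, averaged over loci within
#' population and then over populations -- the summary used for observed vs
#' simulated comparisons.
#'
#' @param gd genotype data frame.
#' @return scalar mean He.
#' @export
mean_he_dataset <- function(gd) {
  gd <- as_genotype_data(gd)
  per_pop <- vapply(split(gd, gd$pop), function(sub) {
    cts <- lapply(split(sub, sub$locus), function(d)
      table(c(d$allele1, d$allele2)))
    expected_heterozygosity(cts)$mean
  }, numeric(1))
  mean(per_pop, na.rm = TRUE)
}

#' Relative support of a demographic model
#'
#' Proportion of simulated values strictly higher than the observed value;
#' ties count as not higher.
#'
#' @param simulated replicate statistic values.
#' @param observed observed statistic.
#' @export
relative_support <- function(simulated, observed) {
  stopifnot(length(simulated) >= 1)
  mean(simulated > observed)
}

#' Two-tailed probability from relative support
#'
#' \eqn{P = 2 \min(RS, 1 - RS)}: the probability of not rejecting the model
#' given where the observed value falls in the simulated distribution.
#'
#' @param rs relative support in \code{[0, 1]}.
#' @export
two_tailed_probability <- function(rs) {
  if (any(rs < 0 | rs > 1)) stop("RS must be in [0, 1]")
  2 * pmin(rs, 1 - rs)
}

#' Model likelihood from the simulated frequency distribution
#'
#' Smooths the replicate values into an empirical density (Gaussian kernel,
#' Silverman's bandwidth, or fixed-bin histogram heights) and returns the
#' height at the observed value relative to the maximum height, a ratio in
#' \code{[0, 1]}.  The likelihood is zero -- and the model not estimable --
#' when the observed value falls outside the support (range) of the
#' simulated values.
#'
#' @param simulated replicate statistic values (>= 2 distinct values).
#' @param observed observed statistic.
#' @param method \code{"kernel"} or \code{"histogram"}.
#' @param bins bin count for the histogram method.
#' @return list with \code{likelihood} and \code{estimable}.
#' @export
model_likelihood <- function(simulated, observed,
                             method = c("kernel", "histogram"), bins = 30L) {
  method <- match.arg(method)
  if (length(unique(simulated)) < 2)
    return(list(likelihood = NA_real_, estimable = FALSE))
  if (observed < min(simulated) || observed > max(simulated))
    return(list(likelihood = 0, estimable = FALSE))
  if (method == "kernel") {
    den <- stats::density(simulated, bw = "nrd0")
    h_obs <- stats::approx(den$x, den$y, xout = observed)$y
    L <- h_obs / max(den$y)
  } else {
    br <- seq(min(simulated), max(simulated), length.out = bins + 1)
    hh <- graphics::hist(simulated, breaks = br, plot = FALSE)$counts
    idx <- min(findInterval(observed, br, rightmost.closed = TRUE), bins)
    L <- hh[idx] / max(hh)
  }
  list(likelihood = unname(L), estimable = TRUE)
}

#' AIC weights from model likelihoods
#'
#' \eqn{AIC = -2 \ln L} (the parameter-count term is identical across the
#' compared demographic models and cancels in the differences);
#' \eqn{AICw = \exp(-0.5 (AIC - AIC_{min}))}, normalised to sum to one over
#' the estimable models.
#'
#' @param likelihoods likelihood ratios in \code{[0, 1]}; zeros/NAs receive
#'   NA weight.
#' @return vector of weights (NA for inestimable models).
#' @examples
#' aic_weights(c(1, exp(-1))) # 0.731, 0.269
#' @export
aic_weights <- function(likelihoods) {
  ok <- !is.na(likelihoods) & likelihoods > 0
  w <- rep(NA_real_, length(likelihoods))
  names(w) <- names(likelihoods)
  if (!any(ok)) return(w)
  aic <- -2 * log(likelihoods[ok])
  rel <- exp(-0.5 * (aic - min(aic)))
  w[ok] <- rel / sum(rel)
  w
}

#' Multi-model comparison table
#'
#' Builds the reference distribution for each scenario, computes relative
#' support, the two-tailed probability, the distribution-based likelihood
#' and AIC weights, and ranks the estimable models.
#'
#' @param observed observed mean expected heterozygosity.
#' @param scenarios list of \code{"demographic_scenario"} objects (or
#'   character names passed to \code{\link{build_scenario}}).
#' @param config a \code{"simulation_config"}.
#' @param R replicates per scenario (default 2000).
#' @param seed optional integer seed.
#' @param ... passed to \code{\link{build_scenario}} for character scenarios.
#' @return data frame of class \code{"model_comparison"} with one row per
#'   scenario (model, RS, P, likelihood, AICw, estimable, n_replicates);
#'   the replicate values are kept in attribute \code{"distributions"}.
#' @export
rank_models <- function(observed, scenarios, config, R = 2000L, seed = NULL,
                        ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, build_scenario, ...)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  sims <- lapply(scenarios, simulate_reference_distribution, config = config,
                 R = R)
  rs <- vapply(sims, relative_support, numeric(1), observed = observed)
  lik <- lapply(sims, model_likelihood, observed = observed)
  L <- vapply(lik, `[[`, numeric(1), "likelihood")
  est <- vapply(lik, `[[`, logical(1), "estimable")
  out <- data.frame(
    model = names(scenarios),
    n_replicates = R,
    RS = rs,
    P = ifelse(est, two_tailed_probability(rs), NA_real_),
    likelihood = ifelse(est, L, NA_real_),
    AICw = aic_weights(ifelse(est, L, NA_real_)),
    estimable = est,
    stringsAsFactors = FALSE)
  out <- out[order(-replace(out$AICw, is.na(out$AICw), -1)), ]
  rownames(out) <- NULL
  attr(out, "observed") <- observed
  attr(out, "distributions") <- sims
  class(out) <- c("model_comparison", "data.frame")
  out
}
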