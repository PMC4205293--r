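#' Demographic scenarios for the structured coalescent
#'
#' Builds one of six named demographic hypotheses for a multi-deme system.
#' Each scenario fixes per-deme effective sizes at three time anchors --
#' \code{t0 = 0} (present), \code{t500 = 500} and \code{t1750 = 1750}
#' generations before present (matching the mid-Holocene and the Last Glacial
#' Maximum under a 12-year generation time) -- together with a backward
#' migration rule.  Sizes are interpolated exponentially between anchors and
#' held constant beyond the oldest anchor.
#'
#' The named scenarios are parameterised as follows (diploid sizes per deme;
#' all use a migration rate of 0.01 per lineage per generation):
#' \describe{
#'   \item{Stability_21_0}{constant size, \code{N0 = N500 = N1750 = 10000}.}
#'   \item{Retraction_21_6}{\code{N0 = N500 = 10000}, growing backward to
#'     \code{N1750 = 50000}; all lineages are relocated to deme 1 at
#'     \code{t = 1750} ("shrink until extinction" of the peripheral demes).}
#'   \item{Expansion_21_0}{a single backward-exponential decline from
#'     \code{N0 = 10000} to \code{N1750 = 1000}.}
#'   \item{Expansion_21_6}{constant \code{10000} until \code{t500}, then
#'     declining backward to \code{N1750 = 1000}.}
#'   \item{Expansion_6_0}{bottleneck at the mid-Holocene:
#'     \code{N500 = 1000}, recovering backward to \code{N1750 = 10000}.}
#'   \item{MultipleRefugia_21_0}{as Expansion_21_0 but with island-model
#'     migration (uniform among the other demes) instead of the deme-1 sink.}
#' }
#'
#' @param name scenario name, one of the six above.
#' @param n_demes number of demes (default 20).
#' @param migration_rate backward migration probability per lineage per
#'   generation (default 0.01).
#' @param anchors optional length-3 numeric override of \code{c(N0, N500,
#'   N1750)}.
#' @param fusion_time optional override of the generation at which all
#'   lineages are moved to deme 1.
#' @param time_cap hard fusion cap guaranteeing termination (default 50000
#'   generations).
#' @return an object of class \code{"demographic_scenario"}.
#' @examples
#' sc <- build_scenario("Retraction_21_6")
#' deme_size_at(sc, c(0, 500, 1750))
#' @export
build_scenario <- function(name,
                           n_demes = 20L,
                           migration_rate = 0.01,
                           anchors = NULL,
                           fusion_time = NULL,
                           time_cap = 50000) {
  name <- match.arg(name, scenario_names())
  # N500 on the single-exponential path 10000 -> 1000 over [0, 1750]
  n500_exp <- 10000 * (1000 / 10000)^(500 / 1750)
  defs <- list(
    Stability_21_0      = list(anchors = c(10000, 10000, 10000), mig = "sink"),
    Retraction_21_6     = list(anchors = c(10000, 10000, 50000), mig = "sink",
                               fusion_time = 1750),
    Expansion_21_0      = list(anchors = c(10000, n500_exp, 1000), mig = "sink"),
    Expansion_21_6      = list(anchors = c(10000, 10000, 1000), mig = "sink"),
    Expansion_6_0       = list(anchors = c(10000, 1000, 10000), mig = "sink"),
    MultipleRefugia_21_0 = list(anchors = c(10000, n500_exp, 1000), mig = "island")
  )
  d <- defs[[name]]
  if (!is.null(anchors)) {
    stopifnot(length(anchors) == 3L, all(is.finite(anchors)), all(anchors >= 1))
    d$anchors <- as.numeric(anchors)
  }
  ft <- if (!is.null(fusion_time)) fusion_time else
    if (!is.null(d$fusion_time)) d$fusion_time else time_cap
  stopifnot(n_demes >= 1, migration_rate >= 0, migration_rate <= 1,
            ft > 0, time_cap > 0)
  structure(list(
    name = name,
    n_demes = as.integer(n_demes),
    anchor_times = c(0, 500, 1750),
    anchors = d$anchors,
    migration = list(model = if (migration_rate > 0) d$mig else "none",
                     rate = migration_rate),
    fusion_time = ft,
    time_cap = max(time_cap, ft)
  ), class = "demographic_scenario")
}

#' Names of the built-in demographic scenarios
#' @return character vector of the six scenario names.
#' @export
scenario_names <- function() {
  c("Stability_21_0", "Retraction_21_6", "Expansion_21_0",
    "Expansion_21_6", "Expansion_6_0", "MultipleRefugia_21_0")
}

#' Deme size at a time in the past
#'
#' Piecewise-exponential interpolation of the per-deme effective size:
#' within an epoch \eqn{[t_a, t_b]},
#' \eqn{N(t) = N(t_a) (N(t_b)/N(t_a))^{(t - t_a)/(t_b - t_a)}}; constant
#' beyond the oldest anchor.
#'
#' @param scenario a \code{"demographic_scenario"}.
#' @param t generations before present (vectorised, must be \eqn{\ge 0}).
#' @return diploid effective size(s) at \code{t}.
#' @export
deme_size_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  at <- scenario$anchor_times
  an <- scenario$anchors
  vapply(t, function(ti) {
    if (ti >= at[length(at)]) return(an[length(an)])
    e <- findInterval(ti, at)
    frac <- (ti - at[e]) / (at[e + 1] - at[e])
    an[e] * (an[e + 1] / an[e])^frac
  }, numeric(1))
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("Demographic scenario:", x$name, "\n")
  cat(sprintf("  %d demes; N0 = %.6g, N500 = %.6g, N1750 = %.6g\n",
              x$n_demes, x$anchors[1], x$anchors[2], x$anchors[3]))
  cat(sprintf("  migration: %s, rate %.4g/generation; fusion at %.6g gen\n",
              x$migration$model, x$migration$rate, x$fusion_time))
  invisible(x)
}

#' Simulation configuration
#'
#' @param sample_sizes diploid sample sizes per deme (recycled to the
#'   scenario's deme count when simulating).
#' @param n_loci number of independent microsatellite loci (default 11).
#' @param mutation_rate per-allele per-generation stepwise mutation
#'   probability (default 0.01).
#' @param ancestral_allele_size root repeat count (default 100, far from the
#'   size floor of 1).
#' @return an object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(sample_sizes,
                              n_loci = 11L,
                              mutation_rate = 0.01,
                              ancestral_allele_size = 100L) {
  sample_sizes <- as.integer(sample_sizes)
  stopifnot(length(sample_sizes) >= 1, all(sample_sizes >= 1),
            n_loci >= 1,
            mutation_rate > 0, mutation_rate < 1,
            ancestral_allele_size >= 1)
  structure(list(sample_sizes = sample_sizes,
                 n_loci = as.integer(n_loci),
                 mutation_rate = mutation_rate,
                 ancestral_allele_size = as.integer(ancestral_allele_size)),
            class = "simulation_config")
}
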