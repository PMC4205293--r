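#' Default per-population diploid sample sizes
#'
#' The sampling design emulated by the synthetic genotype generator: 414
#' individuals across 20 savanna populations (named by their population
#' codes).
#'
#' @return named integer vector of length 20 summing to 414.
#' @export
default_sample_sizes <- function() {
  c(AGE = 30L, ARA = 12L, BAG = 26L, BAR = 15L, BOD = 22L, CAC = 30L,
    CHG = 24L, FAT = 35L, GSV = 8L, NIQ = 28L, PAN = 23L, PNE = 16L,
    POT = 16L, PTU = 32L, SCA = 29L, SDO = 3L, SEC = 4L, STZ = 17L,
    SUM = 14L, VIB = 30L)
}

#' Specification of a synthetic genotype study
#'
#' @param n_populations number of populations (default 20).
#' @param sample_sizes diploid counts per population (default
#'   \code{\link{default_sample_sizes}}).
#' @param n_loci microsatellite loci (default 11).
#' @param mutation_rate per-allele per-generation rate (default 0.01).
#' @param generation_time years per generation (default 12).
#' @param inbreeding probability that an individual's two gene copies are
#'   identical by descent at sampling (default 0.21).
#' @param truth_scenario demographic scenario generating the data (default
#'   \code{"Expansion_6_0"}).
#' @param seed integer seed.
#' @return object of class \code{"synthetic_study_spec"}.
#' @export
synthetic_study_spec <- function(n_populations = 20L,
                                 sample_sizes = default_sample_sizes(),
                                 n_loci = 11L,
                                 mutation_rate = 0.01,
                                 generation_time = 12,
                                 inbreeding = 0.21,
                                 truth_scenario = "Expansion_6_0",
                                 seed = 1L) {
  nm <- names(sample_sizes)
  sample_sizes <- rep_len(as.integer(sample_sizes), n_populations)
  if (!is.null(nm)) names(sample_sizes) <- rep_len(nm, n_populations)
  stopifnot(n_populations >= 1, all(sample_sizes >= 1),
            mutation_rate > 0, mutation_rate < 1,
            inbreeding >= 0, inbreeding <= 1,
            generation_time > 0)
  truth_scenario <- match.arg(truth_scenario, scenario_names())
  structure(list(n_populations = as.integer(n_populations),
                 sample_sizes = sample_sizes, n_loci = as.integer(n_loci),
                 mutation_rate = mutation_rate,
                 generation_time = generation_time,
                 inbreeding = inbreeding, truth_scenario = truth_scenario,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Random population coordinates inside a bounding box
#'
#' Stand-in for a sampling map: uniform unique lon/lat points.
#'
#' @param n number of populations.
#' @param extent bounding box \code{c(xmin, ymin, xmax, ymax)} in degrees
#'   (default roughly Central Brazil).
#' @param seed integer seed.
#' @return data frame \code{pop_id}, \code{lon}, \code{lat}.
#' @export
gen_population_coords <- function(n, extent = c(-60, -20, -42, -8),
                                  seed = 1L) {
  stopifnot(n >= 1, length(extent) == 4, all(is.finite(extent)))
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent is degenerate")
  set.seed(seed)
  repeat {
    lon <- stats::runif(n, extent[1], extent[3])
    lat <- stats::runif(n, extent[2], extent[4])
    if (!anyDuplicated(cbind(lon, lat))) break
  }
  data.frame(pop_id = paste0("P", seq_len(n)), lon = lon, lat = lat,
             stringsAsFactors = FALSE)
}

#' Generate an observed-style genotype dataset with known truth
#'
#' Simulates the coalescent under the spec's truth scenario, then converts
#' the gene pool into diploid genotypes applying the within-population
#' inbreeding level: with probability \code{inbreeding} an individual's
#' second gene copy duplicates the first at every locus (identity by descent
#' through selfing-like mating), otherwise the two simulated copies are kept.
#'
#' @param spec a \code{"synthetic_study_spec"}.
#' @return genotype data frame; population labels follow the sample-size
#'   names when present.
#' @export
gen_observed_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  sc <- build_scenario(spec$truth_scenario, n_demes = spec$n_populations)
  cfg <- simulation_config(spec$sample_sizes, n_loci = spec$n_loci,
                           mutation_rate = spec$mutation_rate)
  gd <- simulate_dataset(sc, cfg)
  inds <- unique(gd$individual)
  selfed <- inds[stats::runif(length(inds)) < spec$inbreeding]
  sel <- gd$individual %in% selfed
  gd$allele2[sel] <- gd$allele1[sel]
  if (!is.null(names(spec$sample_sizes)) &&
      !anyDuplicated(names(spec$sample_sizes)))
    gd$pop <- names(spec$sample_sizes)[gd$pop]
  as_genotype_data(gd)
}

#' Specification of a synthetic suitability-map ensemble
#'
#' Defines a stack of gridded suitability layers with a planted hierarchical
#' variance structure and planted range dynamics.  Component effects are
#' drawn independently per cell on a logit-like latent scale and squashed
#' through the logistic function; the four variance fractions are the
#' expected proportional sums of squares that \code{\link{variance_partition}}
#' recovers (the generator solves for the latent effect variances that
#' produce them under the nested design).
#'
#' @param grid_shape \code{c(rows, cols)} (default 60 x 60).
#' @param cell_size degrees (default 0.5).
#' @param n_algorithms,n_aogcms ensemble dimensions (defaults 13 and 4).
#' @param periods ordered period labels, oldest first (default
#'   \code{c("21ka", "6ka", "0ka")}).
#' @param var_time,var_aogcm,var_algorithm,var_noise nonnegative variance
#'   fractions summing to one (defaults 0.25, 0.35, 0.18, 0.22).
#' @param planted_dynamic range dynamic per successive period pair: one
#'   label (recycled) or one per pair, from \code{"Stability"},
#'   \code{"Retraction"}, \code{"Expansion"}.
#' @param effect_sd total latent standard deviation of the drawn effects
#'   (default 0.3; small enough that the logistic squash stays near-linear).
#' @param base_radius radius (cells) of the high-suitability disc in the
#'   oldest period (default 16).
#' @param dynamic_cells planted change in suitable area, in grid cells, per
#'   Expansion / Retraction step (default 350; comfortably beyond the
#'   199-cell stability cut-off so classification recovers the truth).
#' @param xll,yll lower-left corner coordinates (defaults -60, -25).
#' @param seed integer seed.
#' @return object of class \code{"synthetic_map_spec"}.
#' @export
synthetic_map_spec <- function(grid_shape = c(60L, 60L), cell_size = 0.5,
                               n_algorithms = 13L, n_aogcms = 4L,
                               periods = c("21ka", "6ka", "0ka"),
                               var_time = 0.25, var_aogcm = 0.35,
                               var_algorithm = 0.18, var_noise = 0.22,
                               planted_dynamic = "Stability",
                               effect_sd = 0.3, base_radius = 16,
                               dynamic_cells = 350,
                               xll = -60, yll = -25, seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), cell_size > 0,
            n_algorithms >= 1, n_aogcms >= 1, length(periods) >= 2,
            var_time >= 0, var_aogcm >= 0, var_algorithm >= 0, var_noise >= 0)
  if (abs(var_time + var_aogcm + var_algorithm + var_noise - 1) > 1e-9)
    stop("variance fractions must sum to 1")
  planted_dynamic <- match.arg(planted_dynamic,
                               c("Stability", "Retraction", "Expansion"),
                               several.ok = TRUE)
  planted_dynamic <- rep_len(planted_dynamic, length(periods) - 1)
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 n_algorithms = as.integer(n_algorithms),
                 n_aogcms = as.integer(n_aogcms), periods = periods,
                 var = c(time = var_time, aogcm = var_aogcm,
                         algorithm = var_algorithm, noise = var_noise),
                 planted_dynamic = planted_dynamic,
                 effect_sd = effect_sd, base_radius = base_radius,
                 dynamic_cells = dynamic_cells,
                 xll = xll, yll = yll, seed = as.integer(seed)),
            class = "synthetic_map_spec")
}

# latent effect variances whose expected ANOVA sums of squares match the
# requested proportional-SS fractions under the nested balanced design
.solve_latent_variances <- function(frac, p, a, e) {
  s_n <- frac["noise"] / (p * (a - 1) * (e - 1))
  s_e <- (frac["algorithm"] / (p * (e - 1)) - s_n) / a
  s_a <- (frac["aogcm"] / (p * (a - 1)) - s_n) / e
  s_t <- (frac["time"] / (p - 1) - e * s_a - a * s_e - s_n) / (a * e)
  v <- c(time = unname(s_t), aogcm = unname(s_a), algorithm = unname(s_e),
         noise = unname(s_n))
  if (any(v < -1e-12))
    stop("requested variance fractions are not realisable under this design")
  pmax(v, 0)
}

#' Generate a synthetic suitability stack
#'
#' Builds the latent surface per period (a soft-edged high-suitability disc
#' whose radius follows the planted range dynamics), adds per-cell Gaussian
#' component effects (time, AOGCM-within-time, algorithm-within-time,
#' residual noise) with variances solved from the requested fractions, and
#' squashes through the logistic function into \code{[0, 1]}.  TSS weights
#' are drawn uniformly in \code{[0.4, 0.9]} per (algorithm, AOGCM).
#'
#' @param spec a \code{"synthetic_map_spec"}.
#' @return a \code{"suitability_stack"}.
#' @export
gen_suitability_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  ncell <- nr * nc
  p <- length(spec$periods); a <- spec$n_aogcms; e <- spec$n_algorithms
  # planted radii, oldest -> most recent; each Expansion/Retraction step
  # changes the disc AREA by a fixed cell count so every step clears the
  # classification cut-off by the same margin
  radii <- numeric(p)
  radii[1] <- spec$base_radius
  for (k in seq_len(p - 1)) {
    area <- pi * radii[k]^2
    area_next <- switch(spec$planted_dynamic[k],
      Stability = area,
      Expansion = area + spec$dynamic_cells,
      Retraction = area - spec$dynamic_cells)
    if (area_next <= 0)
      stop("planted retraction exhausts the range; increase base_radius")
    radii[k + 1] <- sqrt(area_next / pi)
  }
  # soft-edged disc on the latent scale, centred on the grid
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist <- sqrt((row - (nr + 1) / 2)^2 + (col - (nc + 1) / 2)^2)
  hi <- 2.2; lo <- -2.5
  base <- vapply(radii, function(r)
    as.vector(t(lo + (hi - lo) * stats::plogis(r - dist))), numeric(ncell))
  v <- .solve_latent_variances(spec$var, p, a, e)
  scl <- spec$effect_sd / sqrt(sum(v))
  sd_v <- sqrt(v) * scl
  lay <- expand.grid(algorithm = paste0("alg", seq_len(e)),
                     aogcm = paste0("gcm", seq_len(a)),
                     period = spec$periods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff_t <- matrix(stats::rnorm(ncell * p, 0, sd_v["time"]), ncell, p,
                  dimnames = list(NULL, spec$periods))
  ta <- unique(lay[c("period", "aogcm")])
  te <- unique(lay[c("period", "algorithm")])
  eff_ta <- matrix(stats::rnorm(ncell * nrow(ta), 0, sd_v["aogcm"]), ncell,
                   dimnames = list(NULL, paste(ta$period, ta$aogcm)))
  eff_te <- matrix(stats::rnorm(ncell * nrow(te), 0, sd_v["algorithm"]), ncell,
                   dimnames = list(NULL, paste(te$period, te$algorithm)))
  latent <- base[, match(lay$period, spec$periods), drop = FALSE] +
    eff_t[, lay$period, drop = FALSE] +
    eff_ta[, paste(lay$period, lay$aogcm), drop = FALSE] +
    eff_te[, paste(lay$period, lay$algorithm), drop = FALSE] +
    matrix(stats::rnorm(ncell * nrow(lay), 0, sd_v["noise"]), ncell)
  values <- stats::plogis(latent)
  combos <- unique(lay[c("algorithm", "aogcm")])
  tss <- data.frame(combos,
                    tss = stats::runif(nrow(combos), 0.4, 0.9),
                    stringsAsFactors = FALSE)
  suitability_stack(values, lay,
                    grid = list(nrow = nr, ncol = nc, xll = spec$xll,
                                yll = spec$yll, cellsize = spec$cell_size),
                    tss = tss)
}
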