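#' Simulate one gene genealogy under a demographic scenario
#'
#' Runs the structured coalescent backward in time for one locus.  Within a
#' deme of current size \eqn{N(t)} each pair of lineages coalesces at rate
#' \eqn{1/(2N(t))} per generation; lineages migrate according to the
#' scenario's rule (deme-1 sink or island model) at the scenario rate; at the
#' fusion time all surviving lineages are relocated to deme 1.  The result is
#' a rooted binary tree with tips at time 0.
#'
#' @param scenario a \code{"demographic_scenario"} from
#'   \code{\link{build_scenario}}.
#' @param config a \code{"simulation_config"}; gene copies sampled per deme
#'   are twice the diploid sample sizes.
#' @return a \code{"genealogy"}: list with \code{parent} (parent index per
#'   node, 0 at the root), \code{time} (node times in generations), tip
#'   demes, and the TMRCA.  Tips are nodes \code{1..n}; internal nodes follow
#'   in coalescence order.
#' @export
simulate_genealogy <- function(scenario, config) {
  stopifnot(inherits(scenario, "demographic_scenario"),
            inherits(config, "simulation_config"))
  sizes <- rep_len(config$sample_sizes, scenario$n_demes)
  tip_demes <- rep(seq_len(scenario$n_demes), times = 2L * sizes)
  mig_model <- match(scenario$migration$model, c("none", "sink", "island")) - 1L
  res <- .sim_genealogy_cpp(as.integer(tip_demes), scenario$n_demes,
                            scenario$anchor_times, scenario$anchors,
                            scenario$migration$rate, mig_model,
                            scenario$fusion_time, scenario$time_cap)
  structure(list(parent = res$parent, time = res$time,
                 n_tips = res$n_tips, tip_demes = tip_demes,
                 n_migrations = res$n_migrations, tmrca = res$tmrca),
            class = "genealogy")
}

#' Drop stepwise mutations on a genealogy
#'
#' Each branch receives a Poisson number of mutations with mean
#' \code{rate * length}; each mutation shifts the repeat count by +1 or -1
#' with equal probability (the strict stepwise mutation model).  A tip's
#' allele size is the ancestral size plus the signed sum of mutations along
#' its root-to-tip path, floored at 1 repeat.
#'
#' @param genealogy a \code{"genealogy"}.
#' @param mutation_rate per-allele per-generation mutation probability.
#' @param ancestral_allele_size root repeat count (must be >= 1).
#' @return integer allele sizes, one per tip.
#' @export
apply_smm_mutations <- function(genealogy, mutation_rate,
                                ancestral_allele_size = 100L) {
  stopifnot(inherits(genealogy, "genealogy"))
  if (ancestral_allele_size < 1) stop("ancestral allele size must be >= 1")
  if (mutation_rate < 0) stop("mutation rate must be >= 0")
  parent <- genealogy$parent
  tm <- genealogy$time
  n_nodes <- length(parent)
  root <- which(parent == 0L)
  len <- ifelse(parent == 0L, 0, tm[pmax(parent, 1L)] - tm)
  nmut <- stats::rpois(n_nodes, mutation_rate * len)
  # net displacement of a +/-1 random walk with nmut steps
  net <- 2L * stats::rbinom(n_nodes, nmut, 0.5) - nmut
  state <- numeric(n_nodes)
  state[root] <- ancestral_allele_size
  # parents always have strictly larger times than children, so processing
  # nodes by decreasing time visits every parent first
  ord <- order(tm, decreasing = TRUE)
  for (i in ord) {
    if (parent[i] > 0L) state[i] <- state[parent[i]] + net[i]
  }
  pmax(as.integer(round(state[seq_len(genealogy$n_tips)])), 1L)
}

#' Simulate a multilocus microsatellite dataset
#'
#' Draws one independent genealogy per locus under the scenario, drops
#' stepwise mutations, and pairs consecutive gene copies within each deme
#' into diploid individuals.
#'
#' @inheritParams simulate_genealogy
#' @return a genotype data frame with columns \code{individual}, \code{pop},
#'   \code{locus}, \code{allele1}, \code{allele2} (allele sizes as integer
#'   repeat counts).
#' @examples
#' sc <- build_scenario("Stability_21_0", n_demes = 2)
#' cfg <- simulation_config(sample_sizes = c(4, 4), n_loci = 2)
#' set.seed(1)
#' gd <- simulate_dataset(sc, cfg)
#' head(gd)
#' @export
simulate_dataset <- function(scenario, config) {
  stopifnot(inherits(scenario, "demographic_scenario"),
            inherits(config, "simulation_config"))
  sizes <- rep_len(config$sample_sizes, scenario$n_demes)
  n_ind <- sum(sizes)
  pop <- rep(seq_len(scenario$n_demes), times = sizes)
  ind <- paste0("ind", seq_len(n_ind))
  out <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    g <- simulate_genealogy(scenario, config)
    sizes_tips <- apply_smm_mutations(g, config$mutation_rate,
                                      config$ancestral_allele_size)
    # tips are ordered by deme; copies 2i-1, 2i form individual i
    a1 <- sizes_tips[seq(1L, length(sizes_tips), by = 2L)]
    a2 <- sizes_tips[seq(2L, length(sizes_tips), by = 2L)]
    out[[l]] <- data.frame(individual = ind, pop = pop,
                           locus = paste0("L", l),
                           allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE)
  }
  gd <- do.call(rbind, out)
  rownames(gd) <- NULL
  gd <- gd[order(match(gd$individual, ind), gd$locus), , drop = FALSE]
  rownames(gd) <- NULL
  class(gd) <- c("genotype_data", "data.frame")
  gd
}

#' Validate a genotype data frame
#'
#' Checks the long genotype layout used throughout the package: one row per
#' individual and locus with two integer allele sizes.
#'
#' @param x a data frame with columns \code{individual}, \code{pop},
#'   \code{locus}, \code{allele1}, \code{allele2}.
#' @return \code{x}, classed as \code{"genotype_data"}.
#' @export
as_genotype_data <- function(x) {
  need <- c("individual", "pop", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing genotype columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(x[, c("allele1", "allele2")])
  if (any(x$allele1[ok] < 1 | x$allele2[ok] < 1))
    stop("allele sizes must be >= 1")
  if (anyDuplicated(x[, c("individual", "locus")]))
    stop("duplicated individual x locus rows")
  class(x) <- unique(c("genotype_data", class(x)))
  x
}
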