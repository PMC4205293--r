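#' Nei's unbiased expected heterozygosity
#'
#' Gene diversity per locus for one population,
#' \eqn{\hat H_e = \frac{2n}{2n-1}(1 - \sum_k \hat p_k^2)} with \eqn{n}
#' diploids, averaged over loci.
#'
#' @param counts a named list of per-locus allele count vectors (one
#'   population), or a single count vector.
#' @param unbiased if \code{FALSE}, returns the plain \eqn{1 - \sum p^2}.
#' @return list with per-locus values (\code{per_locus}) and their mean
#'   (\code{mean}).
#' @examples
#' expected_heterozygosity(c(A = 2, B = 2))$mean # 4/3 * 0.5
#' @export
expected_heterozygosity <- function(counts, unbiased = TRUE) {
  if (!is.list(counts)) counts <- list(counts)
  per <- vapply(counts, function(ct) {
    ct <- ct[ct > 0]
    ntot <- sum(ct)
    if (ntot < 2) return(NA_real_)
    p <- ct / ntot
    h <- 1 - sum(p^2)
    if (unbiased) h * ntot / (ntot - 1) else h
  }, numeric(1))
  if (all(is.na(per))) warning("no locus with at least 2 gene copies")
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Observed heterozygosity
#'
#' Fraction of heterozygous genotypes per locus, averaged over loci, for one
#' population.
#'
#' @param genotypes genotype data frame rows for a single population.
#' @return list with \code{per_locus} and \code{mean}.
#' @export
observed_heterozygosity <- function(genotypes) {
  genotypes <- as_genotype_data(genotypes)
  het <- tapply(genotypes$allele1 != genotypes$allele2, genotypes$locus, mean,
                na.rm = TRUE)
  list(per_locus = c(het), mean = mean(het, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of \code{g} gene copies,
#' \eqn{Ar = \sum_k [1 - \binom{2n - N_k}{g} / \binom{2n}{g}]}, per locus and
#' averaged over loci.  The default \code{g = 4} corresponds to a reference
#' sample of two diploid individuals.
#'
#' @param counts per-locus allele counts (list or single vector) for one
#'   population.
#' @param g reference number of gene copies.
#' @return list with \code{per_locus} and \code{mean}; loci with fewer than
#'   \code{g} copies give an error (exclude such populations instead).
#' @examples
#' allelic_richness(c(A = 2, B = 2), g = 2)$mean # 5/3
#' @export
allelic_richness <- function(counts, g = 4L) {
  if (!is.list(counts)) counts <- list(counts)
  stopifnot(g >= 1)
  per <- vapply(counts, function(ct) {
    ct <- ct[ct > 0]
    ntot <- sum(ct)
    if (ntot < g) stop("fewer than g gene copies at a locus; exclude this population")
    # exp(lchoose) is exact enough here and avoids overflow
    sum(1 - exp(lchoose(ntot - ct, g) - lchoose(ntot, g)))
  }, numeric(1))
  list(per_locus = per, mean = mean(per))
}

# per-locus, per-population allele count tables
.allele_counts <- function(gd) {
  gd <- as_genotype_data(gd)
  long <- data.frame(pop = rep(gd$pop, 2), locus = rep(gd$locus, 2),
                     allele = c(gd$allele1, gd$allele2))
  long <- long[!is.na(long$allele), , drop = FALSE]
  out <- split(long, long$locus)
  lapply(out, function(d) table(factor(d$pop), factor(d$allele)))
}

#' Weir--Cockerham F-statistics
#'
#' Estimates Wright's fixation indices from the analysis of variance of
#' allele frequencies (Weir & Cockerham's theta framework): variance
#' components \code{a} (among populations), \code{b} (among individuals
#' within populations) and \code{c} (within individuals) are computed per
#' allele and locus and summed, giving \eqn{F_{ST} = a/(a+b+c)},
#' \eqn{F_{IT} = (a+b)/(a+b+c)}, \eqn{F_{IS} = b/(b+c)}.
#'
#' @param gd genotype data frame (\eqn{\ge 2} populations).
#' @return named numeric vector \code{c(FIS, FST, FIT)} (NA when every locus
#'   is monomorphic), with the summed components as attribute
#'   \code{"components"}.
#' @export
fstats_wc <- function(gd) {
  gd <- as_genotype_data(gd)
  pops <- unique(gd$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  A <- B <- C <- 0
  for (loc in unique(gd$locus)) {
    d <- gd[gd$locus == loc & !is.na(gd$allele1) & !is.na(gd$allele2), ]
    if (!nrow(d)) next
    comp <- .wc_components_locus(d)
    A <- A + comp[1]; B <- B + comp[2]; C <- C + comp[3]
  }
  tot <- A + B + C
  if (tot == 0) {
    res <- c(FIS = NA_real_, FST = NA_real_, FIT = NA_real_)
  } else {
    res <- c(FIS = if ((B + C) > 0) B / (B + C) else NA_real_,
             FST = A / tot, FIT = (A + B) / tot)
  }
  attr(res, "components") <- c(a = unname(A), b = unname(B), c = unname(C))
  res
}

# Weir & Cockerham (1984) per-locus variance components, summed over alleles
.wc_components_locus <- function(d) {
  pops <- unique(d$pop)
  r <- length(pops)
  n_i <- as.numeric(table(factor(d$pop, levels = pops)))
  if (any(n_i == 0) || r < 2) return(c(0, 0, 0))
  nbar <- mean(n_i)
  ntot <- sum(n_i)
  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  alleles <- sort(unique(c(d$allele1, d$allele2)))
  if (length(alleles) < 2) return(c(0, 0, 0))
  A <- B <- C <- 0
  for (al in alleles) {
    x <- ((d$allele1 == al) + (d$allele2 == al)) / 2   # per-individual freq
    het <- (d$allele1 == al) != (d$allele2 == al)      # het for this allele
    p_i <- tapply(x, factor(d$pop, levels = pops), mean)
    h_i <- tapply(het, factor(d$pop, levels = pops), mean)
    pbar <- sum(n_i * p_i) / ntot
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / ntot
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(A, B, C)
}

#' Within-population inbreeding coefficient
#'
#' Weir--Cockerham \eqn{f} for a single population: components \code{b} and
#' \code{c} of the allele-frequency ANOVA, \eqn{f = b/(b + c)}, summed over
#' alleles and loci.
#'
#' @param gd genotype rows of one population.
#' @return the estimate (NA if all loci monomorphic).
#' @export
inbreeding_f <- function(gd) {
  gd <- as_genotype_data(gd)
  B <- C <- 0
  for (loc in unique(gd$locus)) {
    d <- gd[gd$locus == loc & !is.na(gd$allele1) & !is.na(gd$allele2), ]
    n <- nrow(d)
    if (n < 2) next
    alleles <- sort(unique(c(d$allele1, d$allele2)))
    if (length(alleles) < 2) next
    for (al in alleles) {
      x <- ((d$allele1 == al) + (d$allele2 == al)) / 2
      hbar <- mean((d$allele1 == al) != (d$allele2 == al))
      p <- mean(x)
      b <- (n / (n - 1)) * (p * (1 - p) - hbar * (2 * n - 1) / (4 * n))
      C <- C + hbar / 2
      B <- B + b
    }
  }
  if ((B + C) <= 0) return(NA_real_)
  B / (B + C)
}

#' Slatkin's RST
#'
#' Microsatellite analogue of FST based on allele-size variance:
#' \eqn{R_{ST} = (\bar S - S_w)/\bar S}, with \eqn{S_w} the mean squared
#' allele-size difference between gene copies within populations (pooled over
#' populations) and \eqn{\bar S} the analogue over all pairs in the total
#' sample.  Per-locus values are averaged over polymorphic loci
#' (\code{combine = "mean"}) or combined as a ratio of summed components.
#'
#' @param gd genotype data frame.
#' @param combine \code{"mean"} or \code{"ratio"}.
#' @return RST estimate (NA when all loci are monomorphic).
#' @export
rst_slatkin <- function(gd, combine = c("mean", "ratio")) {
  combine <- match.arg(combine)
  gd <- as_genotype_data(gd)
  num <- den <- per <- numeric(0)
  for (loc in unique(gd$locus)) {
    d <- gd[gd$locus == loc & !is.na(gd$allele1) & !is.na(gd$allele2), ]
    sizes <- c(d$allele1, d$allele2)
    pops <- c(d$pop, d$pop)
    if (length(unique(sizes)) < 2) next
    # mean squared pair difference = 2 * unbiased variance
    sbar <- 2 * stats::var(sizes)
    w_ss <- w_n <- 0
    for (p in unique(pops)) {
      s <- sizes[pops == p]
      np <- length(s)
      if (np < 2) next
      w_ss <- w_ss + stats::var(s) * 2 * choose(np, 2)
      w_n <- w_n + choose(np, 2)
    }
    if (w_n == 0) next
    sw <- w_ss / w_n
    per <- c(per, (sbar - sw) / sbar)
    num <- c(num, sbar - sw); den <- c(den, sbar)
  }
  if (!length(per)) return(NA_real_)
  if (combine == "mean") mean(per) else sum(num) / sum(den)
}

#' Permutation significance tests for differentiation statistics
#'
#' \describe{
#'   \item{\code{"fst"}}{permutes individuals among populations; tests
#'     \eqn{F_{ST} > 0}.}
#'   \item{\code{"fis"}}{re-pairs gene copies at random within each
#'     population and locus; tests \eqn{F_{IS} > 0}.}
#'   \item{\code{"fst_eq_rst"}}{permutes allele sizes among allelic states
#'     within each locus, destroying the size memory of stepwise mutation
#'     while keeping the frequency structure; tests whether the observed
#'     \eqn{R_{ST}} exceeds its distribution under \eqn{F_{ST} = R_{ST}}.}
#' }
#' p-values are \eqn{(1 + \#\{perm \ge obs\})/(n_{perm} + 1)}.
#'
#' @param statistic one of \code{"fst"}, \code{"fis"}, \code{"fst_eq_rst"}.
#' @param gd genotype data frame.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for reproducibility.
#' @return list with \code{observed}, \code{p}, and the permuted values.
#' @export
permutation_pvalue <- function(statistic, gd, n_perm = 999L, seed = NULL) {
  statistic <- match.arg(statistic, c("fst", "fis", "fst_eq_rst"))
  gd <- as_genotype_data(gd)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- switch(statistic,
    fst = function(d) unname(fstats_wc(d)["FST"]),
    fis = function(d) unname(fstats_wc(d)["FIS"]),
    fst_eq_rst = function(d) rst_slatkin(d))
  perm_fun <- switch(statistic,
    fst = function(d) { # permute population labels among individuals
      inds <- unique(d$individual)
      lab <- d$pop[match(inds, d$individual)]
      new <- sample(lab)
      d$pop <- new[match(d$individual, inds)]
      d
    },
    fis = function(d) { # re-pair gene copies within pop x locus
      for (key in unique(paste(d$pop, d$locus))) {
        i <- which(paste(d$pop, d$locus) == key)
        copies <- sample(c(d$allele1[i], d$allele2[i]))
        d$allele1[i] <- copies[seq_along(i)]
        d$allele2[i] <- copies[seq_along(i) + length(i)]
      }
      d
    },
    fst_eq_rst = function(d) { # shuffle size labels among allelic states
      for (loc in unique(d$locus)) {
        i <- which(d$locus == loc)
        sizes <- sort(unique(c(d$allele1[i], d$allele2[i])))
        new <- sample(sizes)
        d$allele1[i] <- new[match(d$allele1[i], sizes)]
        d$allele2[i] <- new[match(d$allele2[i], sizes)]
      }
      d
    })
  obs <- stat_fun(gd)
  perm <- vapply(seq_len(n_perm), function(k) stat_fun(perm_fun(gd)), numeric(1))
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  list(statistic = statistic, observed = obs, p = p, permuted = perm)
}

#' Pairwise FST matrix
#'
#' Weir--Cockerham FST for every population pair, optionally linearized as
#' \eqn{F_{ST}/(1 - F_{ST})} for isolation-by-distance analyses.
#'
#' @param gd genotype data frame.
#' @param linearize apply the linearizing transform (FST of exactly 1 maps to
#'   \code{Inf}).
#' @return symmetric matrix with zero diagonal, dimnames = population ids.
#' @export
pairwise_fst_matrix <- function(gd, linearize = FALSE) {
  gd <- as_genotype_data(gd)
  pops <- unique(gd$pop)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      sub <- gd[gd$pop %in% pops[c(i, j)], , drop = FALSE]
      fst <- unname(fstats_wc(sub)["FST"])
      if (linearize) fst <- if (isTRUE(all.equal(fst, 1))) Inf else fst / (1 - fst)
      m[i, j] <- m[j, i] <- fst
    }
  }
  m
}

#' Per-population summary table of genetic diversity
#'
#' One row per population with sample size, mean alleles per locus (A),
#' rarefied allelic richness at \code{g} gene copies (Ar), observed and
#' expected heterozygosity, and the inbreeding coefficient f; plus Mean, SD
#' and Overall rows (the Overall row carries the multi-population
#' F-statistics and RST).  A second richness column \code{Ar_star} is
#' rarefied at the largest g supported by the populations with at least
#' \code{min_n_star} individuals, and is NA for the excluded populations.
#'
#' @param gd genotype data frame.
#' @param g gene copies for the reference rarefaction (default 4 = two
#'   diploids).
#' @param min_n_star minimum diploids for inclusion in the \code{Ar_star}
#'   column (default 5).
#' @return data frame of class \code{"popgen_summary"}.
#' @export
summarise_populations <- function(gd, g = 4L, min_n_star = 5L) {
  gd <- as_genotype_data(gd)
  pops <- unique(gd$pop)
  counts <- .allele_counts(gd)  # per locus: pop x allele tables
  per_pop_counts <- function(p)
    lapply(counts, function(tab) {
      ct <- tab[match(as.character(p), rownames(tab)), ]
      ct[ct > 0]
    })
  n <- vapply(pops, function(p)
    max(table(gd$locus[gd$pop == p])), numeric(1))
  star_pops <- pops[n >= min_n_star]
  g_star <- if (length(star_pops)) 2L * as.integer(min(n[match(star_pops, pops)])) else NA
  rows <- lapply(pops, function(p) {
    cts <- per_pop_counts(p)
    sub <- gd[gd$pop == p, , drop = FALSE]
    data.frame(
      pop = as.character(p),
      n = as.integer(n[match(p, pops)]),
      A = mean(vapply(cts, length, numeric(1))),
      Ar = allelic_richness(cts, g = g)$mean,
      Ar_star = if (p %in% star_pops)
        allelic_richness(cts, g = g_star)$mean else NA_real_,
      Ho = observed_heterozygosity(sub)$mean,
      He = expected_heterozygosity(cts)$mean,
      f = inbreeding_f(sub),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- c("A", "Ar", "Ar_star", "Ho", "He", "f")
  mean_row <- data.frame(pop = "Mean", n = NA_integer_,
                         t(colMeans(tab[num], na.rm = TRUE)))
  sd_row <- data.frame(pop = "SD", n = NA_integer_,
                       t(apply(tab[num], 2, stats::sd, na.rm = TRUE)))
  fs <- if (length(pops) >= 2) fstats_wc(gd) else
    c(FIS = NA_real_, FST = NA_real_, FIT = NA_real_)
  overall <- data.frame(pop = "Overall", n = sum(tab$n),
                        A = NA_real_, Ar = NA_real_, Ar_star = NA_real_,
                        Ho = NA_real_, He = NA_real_, f = NA_real_)
  out <- rbind(tab, mean_row, sd_row, overall)
  rownames(out) <- NULL
  attr(out, "fstats") <- fs
  attr(out, "rst") <- if (length(pops) >= 2) rst_slatkin(gd) else NA_real_
  attr(out, "g") <- g
  attr(out, "g_star") <- g_star
  class(out) <- c("popgen_summary", "data.frame")
  out
}
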