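# Small genotype fixtures and independent brute-force oracles.  The oracles
# deliberately use a different computational route from the package code
# (explicit loops / sums of squares rather than closed-form components).

# long genotype table from a list: pops -> loci -> n x 2 allele matrix
make_genotypes <- function(pops) {
  rows <- list()
  ind <- 0
  for (p in names(pops)) {
    n_ind <- nrow(pops[[p]][[1]])
    ids <- paste0("i", ind + seq_len(n_ind))
    ind <- ind + n_ind
    for (l in names(pops[[p]])) {
      m <- pops[[p]][[l]]
      rows[[length(rows) + 1]] <- data.frame(
        individual = ids, pop = p, locus = l,
        allele1 = m[, 1], allele2 = m[, 2], stringsAsFactors = FALSE)
    }
  }
  as_genotype_data(do.call(rbind, rows))
}

# fixed 3-population, 2-locus fixture used for estimator oracles
fixture_3pop <- function() {
  make_genotypes(list(
    A = list(L1 = cbind(c(10, 10, 11, 12), c(10, 11, 11, 12)),
             L2 = cbind(c(20, 21, 21, 22), c(20, 20, 22, 22))),
    B = list(L1 = cbind(c(11, 12, 12, 13), c(12, 12, 13, 13)),
             L2 = cbind(c(21, 22, 22, 23), c(22, 22, 23, 24))),
    C = list(L1 = cbind(c(10, 13, 13, 14), c(13, 13, 14, 14)),
             L2 = cbind(c(24, 24, 25, 25), c(24, 25, 25, 26)))))
}

# random genotype table for property checks
random_genotypes <- function(n_pops = 3, n_ind = 6, n_loci = 2,
                             alleles = 8:14) {
  pops <- lapply(seq_len(n_pops), function(p) {
    loci <- lapply(seq_len(n_loci), function(l)
      cbind(sample(alleles, n_ind, TRUE), sample(alleles, n_ind, TRUE)))
    names(loci) <- paste0("L", seq_len(n_loci))
    loci
  })
  names(pops) <- paste0("P", seq_len(n_pops))
  make_genotypes(pops)
}

# Weir-Cockerham variance components by literal nested ANOVA on allele
# indicators: gene copy within individual within population; observed mean
# squares equated to their expectations.
wc_oracle <- function(gd) {
  A <- B <- C <- 0
  for (loc in unique(gd$locus)) {
    d <- gd[gd$locus == loc, ]
    pops <- unique(d$pop)
    r <- length(pops)
    n_i <- sapply(pops, function(p) sum(d$pop == p))
    ntot <- sum(n_i)
    nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
    alleles <- sort(unique(c(d$allele1, d$allele2)))
    if (length(alleles) < 2) next
    for (al in alleles) {
      ssp <- ssi <- ssg <- 0
      p_i <- numeric(r)
      for (k in seq_len(r)) {
        dd <- d[d$pop == pops[k], ]
        x <- ((dd$allele1 == al) + (dd$allele2 == al)) / 2
        p_i[k] <- mean(x)
        for (j in seq_len(nrow(dd))) {
          y <- c(dd$allele1[j] == al, dd$allele2[j] == al)
          ssg <- ssg + sum((y - x[j])^2)
          ssi <- ssi + 2 * (x[j] - p_i[k])^2
        }
      }
      pbar <- sum(n_i * p_i) / ntot
      ssp <- sum(2 * n_i * (p_i - pbar)^2)
      msp <- ssp / (r - 1)
      msi <- ssi / (ntot - r)
      msg <- ssg / ntot
      C <- C + msg
      B <- B + (msi - msg) / 2
      A <- A + (msp - msi) / (2 * nc)
    }
  }
  tot <- A + B + C
  c(FIS = B / (B + C), FST = A / tot, FIT = (A + B) / tot)
}

# Slatkin RST by explicit double loops over gene-copy pairs
rst_oracle <- function(gd) {
  per <- numeric(0)
  for (loc in unique(gd$locus)) {
    d <- gd[gd$locus == loc, ]
    sizes <- c(d$allele1, d$allele2)
    pops <- c(d$pop, d$pop)
    if (length(unique(sizes)) < 2) next
    tot_ss <- tot_n <- 0
    n <- length(sizes)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      tot_ss <- tot_ss + (sizes[i] - sizes[j])^2
      tot_n <- tot_n + 1
    }
    sbar <- tot_ss / tot_n
    w_ss <- w_n <- 0
    for (p in unique(pops)) {
      s <- sizes[pops == p]
      if (length(s) < 2) next
      for (i in seq_len(length(s) - 1)) for (j in seq(i + 1, length(s))) {
        w_ss <- w_ss + (s[i] - s[j])^2
        w_n <- w_n + 1
      }
    }
    sw <- w_ss / w_n
    per <- c(per, (sbar - sw) / sbar)
  }
  mean(per)
}

# tiny suitability stack built by hand
toy_stack <- function(values, algorithm, aogcm, period, nrow = 2, ncol = 2,
                      tss = NULL) {
  suitability_stack(values,
                    data.frame(algorithm = algorithm, aogcm = aogcm,
                               period = period, stringsAsFactors = FALSE),
                    grid = list(nrow = nrow, ncol = ncol, xll = 0, yll = 0,
                                cellsize = 0.5),
                    tss = tss)
}

as_map <- function(m, xll = 0, yll = 0, cellsize = 0.5) {
  attr(m, "grid") <- list(nrow = nrow(m), ncol = ncol(m), xll = xll,
                          yll = yll, cellsize = cellsize)
  m
}
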