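test_that("expected heterozygosity matches Nei's unbiased formula", {
  expect_equal(expected_heterozygosity(c(A = 4))$mean, 0) # monomorphic
  expect_equal(expected_heterozygosity(c(A = 1, B = 1))$mean, 1.0)
  expect_equal(expected_heterozygosity(c(A = 2, B = 2))$mean, 2 / 3,
               tolerance = 1e-12)
  expect_equal(expected_heterozygosity(c(A = 2, B = 2), unbiased = FALSE)$mean,
               0.5)
  # averages over loci
  both <- expected_heterozygosity(list(L1 = c(A = 2, B = 2), L2 = c(A = 4)))
  expect_equal(both$mean, (2 / 3 + 0) / 2)
})

test_that("He estimator is unbiased for a known allele pool", {
  p <- c(0.5, 0.3, 0.2)
  truth <- 1 - sum(p^2)
  set.seed(5)
  est <- replicate(3000, {
    draw <- table(sample(3, 10, TRUE, prob = p))
    expected_heterozygosity(draw)$mean
  })
  expect_lt(abs(mean(est) - truth), 4 * sd(est) / sqrt(3000))
})

test_that("observed heterozygosity counts heterozygous genotypes", {
  gd <- make_genotypes(list(P = list(
    L1 = cbind(c(1, 1, 2, 3), c(2, 1, 3, 4)),  # 3 of 4 heterozygous
    L2 = cbind(c(1, 1, 1, 1), c(1, 1, 1, 1)))))# all homozygous
  ho <- observed_heterozygosity(gd)
  expect_equal(unname(ho$per_locus["L1"]), 0.75)
  expect_equal(unname(ho$per_locus["L2"]), 0)
  het <- make_genotypes(list(P = list(L1 = cbind(1:4, 5:8))))
  expect_equal(observed_heterozygosity(het)$mean, 1)
})

test_that("allelic richness matches the combinatorial rarefaction formula", {
  expect_equal(allelic_richness(c(A = 9), g = 4)$mean, 1) # monomorphic
  expect_equal(allelic_richness(c(A = 2, B = 2), g = 2)$mean,
               2 * (1 - 1 / 6), tolerance = 1e-9)
  expect_equal(allelic_richness(c(A = 3, B = 1), g = 2)$mean, 1.5,
               tolerance = 1e-9) # choose(1,2) = 0 term
  expect_error(allelic_richness(c(A = 1, B = 1), g = 4))
  # monotone non-decreasing in g
  ct <- c(A = 5, B = 3, C = 2, D = 1)
  ar <- vapply(2:10, function(g) allelic_richness(ct, g)$mean, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("Weir-Cockerham F-statistics equal the nested-ANOVA oracle", {
  gd <- fixture_3pop()
  ours <- fstats_wc(gd)
  oracle <- wc_oracle(gd)
  expect_equal(unclass(ours)[c("FIS", "FST", "FIT")], oracle,
               tolerance = 1e-9, ignore_attr = TRUE)
  # on random tables too, including unequal sample sizes
  set.seed(9)
  for (k in 1:5) {
    g2 <- random_genotypes(n_pops = 2 + k %% 3, n_ind = 4 + k)
    expect_equal(unclass(fstats_wc(g2))[1:3], wc_oracle(g2),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("F-statistics obey (1-FIT) = (1-FIS)(1-FST) and limiting cases", {
  set.seed(13)
  for (k in 1:6) {
    gd <- random_genotypes(n_pops = 3, n_ind = 8)
    fs <- fstats_wc(gd)
    expect_equal(1 - fs[["FIT"]], (1 - fs[["FIS"]]) * (1 - fs[["FST"]]),
                 tolerance = 1e-12)
  }
  # two populations fixed for different alleles: complete differentiation
  fixed <- make_genotypes(list(
    A = list(L1 = cbind(rep(10, 6), rep(10, 6))),
    B = list(L1 = cbind(rep(20, 6), rep(20, 6)))))
  expect_equal(fstats_wc(fixed)[["FST"]], 1)
  # panmictic HWE data: FST centred on zero over replicates
  set.seed(14)
  fst0 <- replicate(40, {
    pool <- sample(5:9, 240, TRUE)
    gd <- data.frame(individual = paste0("i", 1:60),
                     pop = rep(c("A", "B"), each = 30), locus = "L1",
                     allele1 = pool[1:60], allele2 = pool[61:120])
    fstats_wc(as_genotype_data(gd))[["FST"]]
  })
  expect_lt(abs(mean(fst0)), 3 * sd(fst0) / sqrt(40))
})

test_that("Slatkin's RST equals the explicit pairwise oracle", {
  gd <- fixture_3pop()
  expect_equal(rst_slatkin(gd), rst_oracle(gd), tolerance = 1e-9)
  set.seed(17)
  for (k in 1:4) {
    g2 <- random_genotypes(n_pops = 3, n_ind = 5)
    expect_equal(rst_slatkin(g2), rst_oracle(g2), tolerance = 1e-9)
  }
  # fixed differences in size: RST -> 1
  fixed <- make_genotypes(list(
    A = list(L1 = cbind(rep(10, 8), rep(10, 8))),
    B = list(L1 = cbind(rep(20, 8), rep(20, 8)))))
  expect_gt(rst_slatkin(fixed), 0.9)
  # identical size distributions everywhere: RST ~ 0
  same <- make_genotypes(list(
    A = list(L1 = cbind(c(10, 11, 12, 13), c(11, 12, 13, 10))),
    B = list(L1 = cbind(c(10, 11, 12, 13), c(12, 13, 10, 11)))))
  expect_lt(abs(rst_slatkin(same)), 0.15)
  expect_true(is.na(rst_slatkin(make_genotypes(list(
    A = list(L1 = cbind(rep(1, 3), rep(1, 3))),
    B = list(L1 = cbind(rep(1, 3), rep(1, 3))))))))
})

test_that("permutation p-values are deterministic, bounded and calibrated", {
  gd <- fixture_3pop()
  p1 <- permutation_pvalue("fst", gd, n_perm = 99, seed = 3)
  p2 <- permutation_pvalue("fst", gd, n_perm = 99, seed = 3)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 100)
  expect_lte(p1$p, 1)
  expect_error(permutation_pvalue("nope", gd))
  # strong differentiation is detected
  fixed <- make_genotypes(list(
    A = list(L1 = cbind(rep(10, 8), rep(10, 8))),
    B = list(L1 = cbind(rep(20, 8), rep(20, 8)))))
  expect_lte(permutation_pvalue("fst", fixed, n_perm = 199, seed = 1)$p,
             2 / 200)
  # fis permutation preserves allele counts
  pf <- permutation_pvalue("fis", gd, n_perm = 99, seed = 5)
  expect_true(all(is.finite(pf$permuted)))
  pr <- permutation_pvalue("fst_eq_rst", gd, n_perm = 99, seed = 7)
  expect_gte(pr$p, 1 / 100)
})

test_that("pairwise FST matrices are symmetric with zero diagonals", {
  set.seed(23)
  gd <- random_genotypes(n_pops = 4, n_ind = 6)
  m <- pairwise_fst_matrix(gd)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 4), rownames(m)))
  lin <- pairwise_fst_matrix(gd, linearize = TRUE)
  off <- upper.tri(m)
  expect_equal(lin[off], m[off] / (1 - m[off]))
  # linearize algebra: 0.5 -> 1
  expect_equal(0.5 / (1 - 0.5), 1)
})

test_that("population summaries assemble the per-population table", {
  set.seed(29)
  sc <- build_scenario("Stability_21_0", n_demes = 4)
  cfg <- simulation_config(c(8, 8, 8, 3), n_loci = 5)
  gd <- simulate_dataset(sc, cfg)
  s <- summarise_populations(gd, g = 4, min_n_star = 5)
  expect_equal(nrow(s), 4 + 3) # pops + Mean/SD/Overall
  per <- s[seq_len(4), ]
  expect_true(all(per$Ar <= per$A + 1e-9))
  expect_true(all(per$He >= 0 & per$He <= 1))
  expect_true(all(per$Ho >= 0 & per$Ho <= 1))
  # the n = 3 population is excluded from Ar_star
  expect_true(is.na(per$Ar_star[per$n == 3]))
  expect_equal(s$n[s$pop == "Overall"], 27)
  expect_true(all(abs(attr(s, "fstats")) <= 1, na.rm = TRUE))
})

test_that("estimated inbreeding recovers the identity-by-descent probability", {
  spec0 <- synthetic_study_spec(n_populations = 4, sample_sizes = rep(30, 4),
                                n_loci = 6, inbreeding = 0, seed = 1)
  f0 <- vapply(1:8, function(i) {
    spec0$seed <- 200 + i
    gd <- gen_observed_dataset(spec0)
    mean(vapply(split(gd, gd$pop), inbreeding_f, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(f0)), 3 * sd(f0) / sqrt(8) + 0.01)
  spec <- synthetic_study_spec(n_populations = 4, sample_sizes = rep(30, 4),
                               n_loci = 6, inbreeding = 0.21, seed = 1)
  f <- vapply(1:10, function(i) {
    spec$seed <- 300 + i
    gd <- gen_observed_dataset(spec)
    mean(vapply(split(gd, gd$pop), inbreeding_f, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(f) - 0.21), 4 * sd(f) / sqrt(10) + 0.01)
})
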