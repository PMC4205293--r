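test_that("point extraction returns the containing cell's value", {
  m <- as_map(matrix(1:9, 3, 3, byrow = TRUE), xll = 0, yll = 0, cellsize = 1)
  # cell centres: row 1 is the northern band (lat in [2, 3))
  expect_equal(extract_at_points(m, data.frame(lon = 0.5, lat = 2.5)), 1)
  expect_equal(extract_at_points(m, data.frame(lon = 2.5, lat = 0.5)), 9)
  # two points in one cell extract the same value
  two <- extract_at_points(m, data.frame(lon = c(1.2, 1.8), lat = c(1.3, 1.7)))
  expect_equal(two[1], two[2])
  expect_warning(out <- extract_at_points(m, data.frame(lon = 9, lat = 9)))
  expect_true(is.na(out))
  flat <- as_map(matrix(0.4, 3, 3), xll = 0, yll = 0, cellsize = 1)
  expect_equal(extract_at_points(flat, data.frame(lon = runif(4, 0, 3),
                                                  lat = runif(4, 0, 3))),
               rep(0.4, 4))
})

test_that("mantel correlation is exact for linear relations and linear-invariant", {
  set.seed(3)
  m <- as.matrix(dist(cbind(runif(7), runif(7))))
  expect_equal(mantel_test(m, 2 * m, n_perm = 99, seed = 1)$r, 1)
  m2 <- as.matrix(dist(runif(7)))
  r0 <- mantel_test(m, m2, n_perm = 99, seed = 1)
  r_scaled <- mantel_test(m, 5 * m2 + 3 * (1 - diag(7)), n_perm = 99, seed = 1)
  expect_equal(r0$r, r_scaled$r, tolerance = 1e-12)
  expect_gte(r0$p, 1 / 100)
  # constant matrix: undefined
  expect_true(is.na(mantel_test(m, 0 * m, n_perm = 99)$r))
  expect_error(mantel_test(m, m2[1:6, 1:6]))
})

test_that("mantel matches the vegan statistic and the exhaustive 4x4 oracle", {
  skip_if_not_installed("vegan")
  set.seed(5)
  a <- as.matrix(dist(runif(8)))
  b <- as.matrix(dist(runif(8)))
  expect_equal(mantel_test(a, b, n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(a, b, permutations = 9)$statistic),
               tolerance = 1e-12)
  # 4 x 4: enumerate all 24 simultaneous permutations
  a4 <- as.matrix(dist(c(0, 1, 3, 6)))
  b4 <- as.matrix(dist(c(2, 1, 5, 4)))
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  ut <- upper.tri(a4)
  r_all <- apply(perms, 1, function(p) cor(a4[ut], b4[p, p][ut]))
  r_obs <- mantel_test(a4, b4, n_perm = 999, seed = 2)$r
  expect_equal(r_obs, r_all[1], tolerance = 1e-12)
  # exact two-sided enumeration p-value brackets the permutation estimate
  p_exact <- mean(abs(r_all) >= abs(r_obs))
  p_hat <- mantel_test(a4, b4, n_perm = 4999, seed = 2)$p
  expect_lt(abs(p_hat - p_exact), 0.05)
})

test_that("quantile fits are exact on noise-free lines and match LAD at the median", {
  set.seed(7)
  x <- runif(25)
  fit <- quantile_fit(x, 2 * x + 1, n_boot = 0)
  expect_equal(fit$slope, rep(2, 3), tolerance = 1e-9)
  expect_equal(fit$intercept, rep(1, 3), tolerance = 1e-9)
  y <- 2 * x + 1 + rnorm(25, 0, 0.4)
  med <- quantile_fit(x, y, taus = 0.5, n_boot = 0)
  lad <- optim(c(0, 0), function(p) sum(abs(y - p[1] - p[2] * x)),
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_lte(sum(abs(y - med$intercept - med$slope * x)), lad$value + 1e-6)
  expect_error(quantile_fit(rep(1, 10), rnorm(10)))
  expect_error(quantile_fit(x, y, taus = 1.2))
})

test_that("fitted quantile lines split the data near tau and do not cross", {
  set.seed(11)
  x <- runif(120)
  y <- 1 + x + rnorm(120, 0, 0.5)
  fit <- quantile_fit(x, y, taus = c(0.1, 0.5, 0.9), n_boot = 0)
  below <- vapply(seq_len(3), function(k)
    mean(y < fit$intercept[k] + fit$slope[k] * x), numeric(1))
  expect_true(all(abs(below - c(0.1, 0.5, 0.9)) < 0.07))
  at_med <- fit$intercept + fit$slope * median(x)
  expect_true(all(diff(at_med) > 0)) # ordered at the median predictor
})

test_that("envelope report flags planted triangular envelopes only", {
  set.seed(13)
  n <- 20
  x <- runif(n)
  geo <- data.frame(
    He = 0.9 - (1 - x) * runif(n),        # lower bound rises, upper flat
    Wedge = 0.2 + x * runif(n),           # upper bound rises, lower flat
    Ar_star = 1 + 2 * x + rnorm(n, 0, .1), # plain homoscedastic line
    suit_now = x)
  rep_env <- envelope_report(geo, responses = c("He", "Wedge", "Ar_star"),
                             predictors = "suit_now", n_boot = 299, seed = 1)
  expect_true(all(rep_env$envelope[rep_env$response == "He"]))
  expect_true(all(rep_env$envelope[rep_env$response == "Wedge"]))
  expect_false(any(rep_env$envelope[rep_env$response == "Ar_star"]))
  expect_equal(sort(unique(rep_env$tau)), c(0.1, 0.5, 0.9))
})

test_that("population geography assembles predictors for every population", {
  spec <- synthetic_map_spec(grid_shape = c(20L, 20L), n_algorithms = 3L,
                             n_aogcms = 2L, var_time = .3, var_aogcm = .3,
                             var_algorithm = .25, var_noise = .15,
                             base_radius = 5, seed = 3)
  st <- gen_suitability_stack(spec)
  set.seed(17)
  sc <- build_scenario("Stability_21_0", n_demes = 4)
  gd <- simulate_dataset(sc, simulation_config(rep(6, 4), n_loci = 3))
  summ <- summarise_populations(gd)
  g <- st$grid
  coords <- gen_population_coords(4, extent = c(g$xll, g$yll,
                                                g$xll + g$ncol * g$cellsize,
                                                g$yll + g$nrow * g$cellsize),
                                  seed = 23)
  coords$pop_id <- as.character(unique(gd$pop))
  geo <- population_geo(summ, coords, st)
  expect_equal(nrow(geo), 4)
  expect_true(all(c("suit_21ka", "suit_0ka", "delta_21ka_6ka",
                    "dist_refugium") %in% names(geo)))
  expect_true(all(geo$dist_refugium >= 0, na.rm = TRUE))
  # deltas are later minus earlier
  expect_equal(geo$delta_6ka_0ka, geo$suit_0ka - geo$suit_6ka)
})
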