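test_that("TSS is sensitivity plus specificity minus one", {
  expect_equal(compute_tss(10, 0, 10, 0), 1)  # perfect
  expect_equal(compute_tss(5, 5, 5, 5), 0)    # no skill
  expect_equal(compute_tss(40, 10, 30, 20), 0.4)
  expect_error(compute_tss(0, 0, 5, 5))
})

test_that("consensus maps are TSS-weighted means with floored weights", {
  vals <- cbind(rep(0.2, 4), rep(0.8, 4))
  st <- toy_stack(vals, algorithm = c("a1", "a2"), aogcm = c("g", "g"),
                  period = c("now", "now"),
                  tss = data.frame(algorithm = c("a1", "a2"),
                                   aogcm = c("g", "g"), tss = c(1, 3)))
  expect_equal(unique(as.vector(consensus_map(st, "now"))), 0.65)
  # equal weights = plain mean
  st$tss$tss <- c(2, 2)
  expect_equal(unique(as.vector(consensus_map(st, "now"))), 0.5)
  # negative skill contributes nothing
  st$tss$tss <- c(-0.5, 2)
  expect_equal(unique(as.vector(consensus_map(st, "now"))), 0.8)
  st$tss$tss <- c(0, 0)
  expect_error(consensus_map(st, "now"))
  expect_error(consensus_map(st, "never"))
  # no weights at all: arithmetic mean
  st$tss <- NULL
  expect_equal(unique(as.vector(consensus_map(st, "now"))), 0.5)
})

test_that("range size uses the inclusive threshold rule", {
  m <- as_map(matrix(c(0.31, 0.29, 0.30, 0), 2, 2))
  expect_equal(range_size(m, 0.3), 2)
  expect_equal(range_size(as_map(matrix(0, 2, 2)), 0.3), 0)
  expect_equal(range_size(m, 0), 4)
})

test_that("range dynamics classification honours the +/-199 cut-off", {
  expect_equal(classify_dynamics(1000, 1000), "Range Stability")
  expect_equal(classify_dynamics(1000, 1250), "Range Expansion") # diff -250
  expect_equal(classify_dynamics(1250, 1000), "Range Retraction")
  # boundaries are inclusive for stability
  expect_equal(classify_dynamics(1000, 1199), "Range Stability") # diff -199
  expect_equal(classify_dynamics(1199, 1000), "Range Stability")
  expect_equal(classify_dynamics(1000, 1200), "Range Expansion")
  # shifting both counts equally never changes the label
  expect_equal(classify_dynamics(1000 + 500, 1250 + 500), "Range Expansion")
})

test_that("refugium cells are suitable in every period", {
  m1 <- as_map(matrix(c(0.4, 0.4, 0.1, 1), 2, 2))
  m2 <- as_map(matrix(c(0.35, 0.1, 0.5, 1), 2, 2))
  m3 <- as_map(matrix(c(0.31, 0.5, 0.5, 1), 2, 2))
  ref <- refugium_map(list(m1, m2, m3))
  expect_equal(as.vector(ref), c(1, 0, 0, 1))
  expect_true(all(ref <= (m1 >= 0.3))) # refugium is a subset of each period
  ones <- as_map(matrix(1, 2, 2))
  expect_equal(as.vector(refugium_map(list(ones, ones, ones))), rep(1, 4))
  expect_error(refugium_map(list(m1, as_map(matrix(1, 3, 3)))))
})

test_that("variance partition isolates a pure time signal and sums to one", {
  lay <- expand.grid(algorithm = c("a1", "a2"), aogcm = c("g1", "g2"),
                     period = c("p1", "p2"), stringsAsFactors = FALSE)
  vals <- matrix(rep(ifelse(lay$period == "p1", 0.2, 0.8), each = 4), 4)
  st <- toy_stack(vals, lay$algorithm, lay$aogcm, lay$period)
  vp <- variance_partition(st)
  expect_equal(unname(vp$overall["time"]), 1)
  expect_equal(sum(vp$overall), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(vp$cell_proportions)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("variance partition matches aov sums of squares on one cell", {
  set.seed(59)
  lay <- expand.grid(algorithm = paste0("a", 1:3), aogcm = paste0("g", 1:2),
                     period = paste0("p", 1:3), stringsAsFactors = FALSE)
  vals <- matrix(runif(2 * nrow(lay)), 2)
  st <- suitability_stack(vals, lay,
                          grid = list(nrow = 1, ncol = 2, xll = 0, yll = 0,
                                      cellsize = 0.5))
  vp <- variance_partition(st)
  y <- vals[1, ]
  fit <- stats::aov(y ~ factor(lay$period) +
                      factor(lay$period):factor(lay$aogcm) +
                      factor(lay$period):factor(lay$algorithm))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(unname(vp$cell_proportions[1, ]), ss / sum(ss),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("variance partition recovers planted fractions and is shift-invariant", {
  spec <- synthetic_map_spec(grid_shape = c(30L, 30L),
                             planted_dynamic = "Stability", seed = 4)
  st <- gen_suitability_stack(spec)
  vp <- variance_partition(st)
  planted <- c(time = 0.25, aogcm = 0.35, algorithm = 0.18, residual = 0.22)
  expect_true(all(abs(vp$overall[names(planted)] - planted) < 0.05))
  # adding a constant to all layers leaves the proportions unchanged
  st2 <- st
  st2$values <- pmin(st$values + 0.05, 1)
  keep <- apply(st$values < 0.95, 1, all) # avoid clipped cells
  vp2 <- variance_partition(st2)
  expect_equal(vp2$cell_proportions[keep, ], vp$cell_proportions[keep, ],
               tolerance = 1e-9)
  # a missing layer is rejected with its index named
  st3 <- st
  st3$values <- st3$values[, -1]
  st3$layers <- st3$layers[-1, ]
  expect_error(variance_partition(st3), "missing layers")
})

test_that("planted range dynamics are recovered for nearly every ensemble member", {
  for (dyn in c("Expansion", "Retraction", "Stability")) {
    spec <- synthetic_map_spec(planted_dynamic = dyn, seed = 8)
    st <- gen_suitability_stack(spec)
    cls <- classify_stack_dynamics(st)
    per_pair <- cls[cls$pair != "21ka-0ka", ]
    hit <- mean(per_pair$label == paste("Range", dyn))
    expect_gte(hit, 0.95)
  }
})

test_that("association tests match the closed-form contingency computation", {
  prop <- matrix(c(10, 20, 20, 40), 2) # perfectly proportional
  res <- classification_association(prop)
  expect_equal(res$value[res$statistic == "pearson_chisq"], 0)
  expect_equal(res$p[res$statistic == "pearson_chisq"], 1)
  diag2 <- matrix(c(10, 0, 0, 10), 2)
  res2 <- classification_association(diag2)
  expect_equal(res2$value[res2$statistic == "pearson_chisq"], 20)
  expect_equal(unique(res2$df), 1)
  # hand computation on a 2 x 3 table
  tab <- matrix(c(8, 2, 5, 5, 3, 7), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res3 <- classification_association(tab)
  expect_equal(res3$value[1], sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res3$value[2], 2 * sum(tab * log(tab / E)), tolerance = 1e-12)
  # zero-marginal row is dropped with a warning
  expect_warning(classification_association(matrix(c(1, 2, 0, 3, 4, 0), 3)))
})

test_that("map centroids average suitable cell centres", {
  m <- as_map(matrix(0, 3, 3), xll = 0, yll = 0, cellsize = 1)
  m[2, 2] <- 1 # centre cell
  expect_equal(map_centroid(m, 0.5), c(lon = 1.5, lat = 1.5))
  m2 <- as_map(matrix(0, 1, 21), xll = 0, yll = 0, cellsize = 1)
  m2[1, c(10, 21)] <- 1 # lon centres 9.5 and 20.5
  expect_equal(map_centroid(m2, 0.5)[["lon"]], 15)
  expect_true(is.na(map_centroid(as_map(matrix(0, 2, 2)), 0.5)[["lon"]]))
  # symmetric disc: centroid at the disc centre within a cell width
  g <- as_map(matrix(0, 21, 21), xll = 0, yll = 0, cellsize = 1)
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 36) g[i, j] <- 1
  cen <- map_centroid(g, 0.5)
  expect_lt(abs(cen[["lon"]] - 10.5), 1)
  expect_lt(abs(cen[["lat"]] - 10.5), 1)
})
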