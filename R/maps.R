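#' Suitability map stacks
#'
#' Container for an ensemble of gridded suitability predictions indexed by
#' modelling algorithm, climate model (AOGCM) and time period, with optional
#' per-(algorithm, AOGCM) True Skill Statistic weights.  The grid is a
#' regular lon/lat raster; cell (1, 1) is the north-west corner.
#'
#' @param values numeric matrix, one row per grid cell (row-major from the
#'   north-west corner), one column per layer; values in \code{[0, 1]}.
#' @param layers data frame with columns \code{algorithm}, \code{aogcm},
#'   \code{period}, one row per column of \code{values}.
#' @param grid list with \code{nrow}, \code{ncol}, \code{xll}, \code{yll},
#'   \code{cellsize} (degrees).
#' @param tss optional data frame \code{algorithm}, \code{aogcm}, \code{tss}.
#' @return object of class \code{"suitability_stack"}.
#' @export
suitability_stack <- function(values, layers, grid, tss = NULL) {
  stopifnot(is.matrix(values), nrow(layers) == ncol(values),
            all(c("algorithm", "aogcm", "period") %in% names(layers)),
            all(c("nrow", "ncol", "xll", "yll", "cellsize") %in% names(grid)),
            grid$nrow * grid$ncol == nrow(values))
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  structure(list(values = values, layers = layers, grid = grid, tss = tss),
            class = "suitability_stack")
}

#' @export
print.suitability_stack <- function(x, ...) {
  cat(sprintf("Suitability stack: %d x %d grid (%.3g deg), %d layers\n",
              x$grid$nrow, x$grid$ncol, x$grid$cellsize, ncol(x$values)))
  cat(sprintf("  %d algorithms x %d AOGCMs x %d periods (%s)\n",
              length(unique(x$layers$algorithm)),
              length(unique(x$layers$aogcm)),
              length(unique(x$layers$period)),
              paste(unique(x$layers$period), collapse = ", ")))
  invisible(x)
}

# one layer as an nrow x ncol matrix carrying the grid as an attribute
.layer_map <- function(stack, j) {
  m <- matrix(stack$values[, j], nrow = stack$grid$nrow,
              ncol = stack$grid$ncol, byrow = TRUE)
  attr(m, "grid") <- stack$grid
  m
}

.map_values <- function(map) as.vector(t(map))

#' True Skill Statistic from a confusion table
#'
#' \eqn{TSS = sensitivity + specificity - 1 = TP/(TP+FN) + TN/(TN+FP) - 1}.
#'
#' @param tp,fn,tn,fp confusion-table counts.
#' @return TSS in \code{[-1, 1]}.
#' @examples
#' compute_tss(40, 10, 30, 20) # 0.4
#' @export
compute_tss <- function(tp, fn, tn, fp) {
  if ((tp + fn) <= 0 || (tn + fp) <= 0)
    stop("each observed class must contain at least one case")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' TSS-weighted consensus map for one period
#'
#' Cell-wise weighted mean of the period's layers,
#' \eqn{\sum_i w_i s_i / \sum_i w_i}, with weights equal to each member's
#' TSS floored at zero (negative-skill members do not contribute).  Without
#' TSS weights all members weigh equally.
#'
#' @param stack a \code{"suitability_stack"}.
#' @param period period label.
#' @return consensus map matrix (grid attached as attribute \code{"grid"}).
#' @export
consensus_map <- function(stack, period) {
  stopifnot(inherits(stack, "suitability_stack"))
  j <- which(stack$layers$period == period)
  if (!length(j)) stop("unknown period: ", period)
  if (is.null(stack$tss)) {
    w <- rep(1, length(j))
  } else {
    key <- paste(stack$layers$algorithm[j], stack$layers$aogcm[j])
    tkey <- paste(stack$tss$algorithm, stack$tss$aogcm)
    w <- pmax(stack$tss$tss[match(key, tkey)], 0)
  }
  if (sum(w) <= 0) stop("all consensus weights are zero")
  v <- as.vector(stack$values[, j, drop = FALSE] %*% w) / sum(w)
  m <- matrix(v, nrow = stack$grid$nrow, ncol = stack$grid$ncol, byrow = TRUE)
  attr(m, "grid") <- stack$grid
  m
}

#' Range size of a thresholded map
#'
#' Number of cells with suitability greater than or equal to the threshold
#' (inclusive rule).
#'
#' @param map suitability matrix.
#' @param threshold presence threshold in \code{[0, 1]} (default 0.3).
#' @export
range_size <- function(map, threshold = 0.3) {
  stopifnot(threshold >= 0, threshold <= 1)
  sum(map >= threshold, na.rm = TRUE)
}

#' Classify a range-size change between two periods
#'
#' The difference is taken as older-period cells minus recent-period cells:
#' a difference above the cut-off is "Range Retraction" (the range shrank
#' toward the present), below minus the cut-off "Range Expansion", and
#' anything in \code{[-cutoff, cutoff]} (boundaries inclusive) "Range
#' Stability".
#'
#' @param cells_old suitable-cell count in the older period.
#' @param cells_recent suitable-cell count in the more recent period.
#' @param cutoff cut-off in grid cells (default 199).
#' @return classification label (vectorised).
#' @export
classify_dynamics <- function(cells_old, cells_recent, cutoff = 199) {
  stopifnot(all(cells_old >= 0), all(cells_recent >= 0), cutoff >= 0)
  diff <- cells_old - cells_recent
  ifelse(diff > cutoff, "Range Retraction",
         ifelse(diff < -cutoff, "Range Expansion", "Range Stability"))
}

#' Per-model range dynamics classification
#'
#' For every (algorithm, AOGCM) combination, counts suitable cells in each
#' period's layer and classifies each period pair with
#' \code{\link{classify_dynamics}}.
#'
#' @param stack a \code{"suitability_stack"} whose period labels are ordered
#'   oldest to most recent.
#' @param threshold presence threshold.
#' @param cutoff stability cut-off in cells.
#' @return data frame with one row per (algorithm, aogcm, period pair):
#'   range sizes, difference and label.
#' @export
classify_stack_dynamics <- function(stack, threshold = 0.3, cutoff = 199) {
  stopifnot(inherits(stack, "suitability_stack"))
  periods <- unique(stack$layers$period)
  combos <- unique(stack$layers[c("algorithm", "aogcm")])
  pairs <- cbind(old = periods[-length(periods)], recent = periods[-1])
  if (length(periods) > 2)
    pairs <- rbind(pairs, c(periods[1], periods[length(periods)]))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- stack$layers$algorithm == combos$algorithm[i] &
      stack$layers$aogcm == combos$aogcm[i]
    sizes <- vapply(periods, function(p) {
      j <- which(sel & stack$layers$period == p)
      range_size(.layer_map(stack, j), threshold)
    }, numeric(1))
    for (k in seq_len(nrow(pairs))) {
      co <- sizes[pairs[k, 1]]; cr <- sizes[pairs[k, 2]]
      out[[length(out) + 1]] <- data.frame(
        algorithm = combos$algorithm[i], aogcm = combos$aogcm[i],
        pair = paste(pairs[k, 1], pairs[k, 2], sep = "-"),
        cells_old = co, cells_recent = cr, diff = co - cr,
        label = classify_dynamics(co, cr, cutoff),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Historical refugium map
#'
#' A cell is a refugium when its suitability reaches the threshold in every
#' period's map.
#'
#' @param maps list of per-period suitability matrices on the same grid.
#' @param threshold presence threshold (default 0.3).
#' @return binary matrix (1 = refugium).
#' @export
refugium_map <- function(maps, threshold = 0.3) {
  stopifnot(is.list(maps), length(maps) >= 2)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps are not on the same grid")
  ref <- Reduce(`&`, lapply(maps, function(m) m >= threshold))
  out <- ref * 1L
  attr(out, "grid") <- attr(maps[[1]], "grid")
  out
}

#' Hierarchical variance partition of a suitability ensemble
#'
#' Per grid cell, decomposes the total sum of squares of the predicted
#' suitability across all (algorithm x AOGCM x period) layers into a time
#' main effect, AOGCM-within-time, algorithm-within-time, and the residual
#' AOGCM x algorithm interaction within time -- the hierarchical design with
#' both modelling components nested in the time component and crossed
#' factorially within each period.  The design is balanced, so the type-I
#' sums of squares are unambiguous.
#'
#' @param stack a full-factorial \code{"suitability_stack"}.
#' @return list of class \code{"variance_partition"} with \code{overall}
#'   (proportional SS summed over cells) and \code{cell_proportions} (cells
#'   x components matrix) plus \code{maps} of per-component proportions.
#' @export
variance_partition <- function(stack) {
  stopifnot(inherits(stack, "suitability_stack"))
  lay <- stack$layers
  key <- table(lay$algorithm, lay$aogcm, lay$period)
  if (any(key != 1)) {
    miss <- which(key == 0, arr.ind = TRUE)
    stop("stack is not full factorial; missing layers: ",
         paste(apply(miss, 1, function(i)
           paste(dimnames(key)[[1]][i[1]], dimnames(key)[[2]][i[2]],
                 dimnames(key)[[3]][i[3]], sep = "/")), collapse = ", "))
  }
  Y <- stack$values
  n_lay <- ncol(Y)
  f_t <- factor(lay$period)
  f_ta <- factor(paste(lay$period, lay$aogcm))
  f_te <- factor(paste(lay$period, lay$algorithm))
  group_means <- function(f) {
    G <- stats::model.matrix(~ f - 1)
    sweep(Y %*% G, 2, colSums(G), "/")[, as.integer(f), drop = FALSE]
  }
  g <- rowMeans(Y)
  M_t <- group_means(f_t)
  M_ta <- group_means(f_ta)
  M_te <- group_means(f_te)
  ss_tot <- rowSums((Y - g)^2)
  ss_time <- rowSums((M_t - g)^2)
  ss_aogcm <- rowSums((M_ta - M_t)^2)
  ss_alg <- rowSums((M_te - M_t)^2)
  ss_res <- ss_tot - ss_time - ss_aogcm - ss_alg
  comp <- cbind(time = ss_time, aogcm = ss_aogcm, algorithm = ss_alg,
                residual = ss_res)
  overall <- colSums(comp) / sum(ss_tot)
  prop <- comp / ifelse(ss_tot > 0, ss_tot, NA)
  maps <- lapply(colnames(comp), function(nm)
    matrix(prop[, nm], stack$grid$nrow, stack$grid$ncol, byrow = TRUE))
  names(maps) <- colnames(comp)
  structure(list(overall = overall, cell_proportions = prop, maps = maps,
                 grid = stack$grid),
            class = "variance_partition")
}

#' Association tests for classification tables
#'
#' Pearson's chi-square and the likelihood-ratio G-square against the
#' independence expectation for a two-way table of classification counts,
#' with p-values from the chi-square distribution on \eqn{(r-1)(c-1)}
#' degrees of freedom.  Rows or columns with a zero marginal are dropped
#' with a warning.
#'
#' @param counts matrix or table of nonnegative integer counts.
#' @return data frame with the two statistics, df and p-values.
#' @export
classification_association <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping categories with zero marginal totals")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table after dropping empty categories")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chisq <- sum((counts - E)^2 / E)
  pos <- counts > 0
  g2 <- 2 * sum(counts[pos] * log(counts[pos] / E[pos]))
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  data.frame(statistic = c("pearson_chisq", "likelihood_ratio_g2"),
             value = c(chisq, g2), df = df,
             p = stats::pchisq(c(chisq, g2), df, lower.tail = FALSE))
}

#' Centroid of the suitable area
#'
#' Unweighted mean of the centre coordinates of all cells at or above the
#' threshold; optionally suitability-weighted.
#'
#' @param map suitability matrix with a \code{"grid"} attribute.
#' @param threshold presence threshold.
#' @param weighted weight cells by suitability instead of equally.
#' @return named vector \code{c(lon, lat)} (NA when no cell is suitable).
#' @export
map_centroid <- function(map, threshold = 0.3, weighted = FALSE) {
  grid <- attr(map, "grid")
  if (is.null(grid)) stop("map has no grid attribute")
  sel <- which(map >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) return(c(lon = NA_real_, lat = NA_real_))
  lon <- grid$xll + (sel[, "col"] - 0.5) * grid$cellsize
  lat <- grid$yll + (grid$nrow - sel[, "row"] + 0.5) * grid$cellsize
  w <- if (weighted) map[sel] else rep(1, nrow(sel))
  c(lon = sum(w * lon) / sum(w), lat = sum(w * lat) / sum(w))
}
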