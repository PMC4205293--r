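#' Extract map values at point coordinates
#'
#' Returns the value of the grid cell containing each point; points outside
#' the grid extent give NA with a warning.
#'
#' @param map matrix with a \code{"grid"} attribute.
#' @param coords data frame with \code{lon}, \code{lat}.
#' @return numeric vector, one value per point.
#' @export
extract_at_points <- function(map, coords) {
  grid <- attr(map, "grid")
  if (is.null(grid)) stop("map has no grid attribute")
  col <- floor((coords$lon - grid$xll) / grid$cellsize) + 1
  row <- grid$nrow - floor((coords$lat - grid$yll) / grid$cellsize)
  ok <- col >= 1 & col <= grid$ncol & row >= 1 & row <= grid$nrow
  if (!all(ok)) warning(sum(!ok), " point(s) outside the grid extent")
  out <- rep(NA_real_, nrow(coords))
  out[ok] <- map[cbind(row[ok], col[ok])]
  out
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances in kilometres.
#'
#' @param coords data frame with \code{lon}, \code{lat} (and optionally
#'   \code{pop_id} used for dimnames).
#' @return symmetric distance matrix (km).
#' @export
geo_distance_matrix <- function(coords) {
  m <- geosphere::distm(as.matrix(coords[, c("lon", "lat")]),
                        fun = geosphere::distHaversine) / 1000
  ids <- if ("pop_id" %in% names(coords)) coords$pop_id else
    as.character(seq_len(nrow(coords)))
  dimnames(m) <- list(ids, ids)
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles; significance by
#' simultaneous row/column permutation of the second matrix, with a
#' two-sided p-value \eqn{(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm}+1)}.
#'
#' @param matA,matB symmetric matrices with zero diagonals, same dimension
#'   (at least 3 x 3).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with \code{r}, \code{r2}, \code{p}, \code{n_perm}.
#' @export
mantel_test <- function(matA, matB, n_perm = 9999L, seed = NULL) {
  stopifnot(is.matrix(matA), is.matrix(matB), all(dim(matA) == dim(matB)),
            nrow(matA) >= 3)
  if (any(abs(matA - t(matA)) > 1e-8) || any(abs(matB - t(matB)) > 1e-8))
    stop("matrices must be symmetric")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(matA)
  a <- matA[ut]
  if (stats::sd(a) == 0 || stats::sd(matB[ut]) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n_perm = n_perm))
  r_obs <- stats::cor(a, matB[ut])
  n <- nrow(matA)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(a, matB[idx, idx][ut])
  }, numeric(1))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, r2 = r_obs^2, p = p, n_perm = n_perm)
}

#' Quantile regression by exact check-loss minimisation
#'
#' Fits \eqn{y = a + b x} at each quantile level by minimising the check
#' loss \eqn{\sum \rho_\tau(y - a - b x)}.  For a single covariate the
#' optimal slope passes through two data points, so the fit enumerates all
#' pairwise candidate slopes and, for each, sets the intercept to the
#' \eqn{\tau}-quantile of the residuals -- exact for the sample sizes this
#' package works with.  Slope p-values come from a case bootstrap (two-sided
#' sign test of the bootstrap slope distribution).
#'
#' @param x predictor values.
#' @param y response values.
#' @param taus quantile levels in \code{(0, 1)} (default 0.10, 0.50, 0.90).
#' @param n_boot bootstrap replicates for slope p-values (default 499; 0
#'   skips inference).
#' @param seed integer seed for the bootstrap.
#' @return data frame with \code{tau}, \code{intercept}, \code{slope},
#'   \code{p}.
#' @export
quantile_fit <- function(x, y, taus = c(0.1, 0.5, 0.9), n_boot = 499L,
                         seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete observations")
  if (length(unique(x)) < 2) stop("degenerate predictor")
  if (any(taus <= 0 | taus >= 1)) stop("taus must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(taus, function(tau) .rq_exact(x, y, tau))
  ps <- rep(NA_real_, length(taus))
  if (n_boot > 0) {
    boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), ncol = n_boot)
    for (k in seq_along(taus)) {
      bs <- apply(boot_idx, 2, function(i) {
        if (length(unique(x[i])) < 2) return(NA_real_)
        .rq_exact(x[i], y[i], taus[k])["slope"]
      })
      bs <- bs[!is.na(bs)]
      ps[k] <- min(1, 2 * min(mean(bs <= 0), mean(bs >= 0)) +
                     2 / (length(bs) + 1))
    }
  }
  data.frame(tau = taus,
             intercept = vapply(fits, `[`, numeric(1), "intercept"),
             slope = vapply(fits, `[`, numeric(1), "slope"),
             p = ps)
}

.check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

.rq_exact <- function(x, y, tau) {
  n <- length(x)
  cand <- c(0)
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    cand <- c(cand, dy[dx != 0] / dx[dx != 0])
  }
  cand <- unique(cand)
  best <- c(intercept = NA_real_, slope = NA_real_)
  best_loss <- Inf
  for (b in cand) {
    r <- y - b * x
    a <- unname(stats::quantile(r, tau, type = 1))
    loss <- .check_loss(r - a, tau)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- c(intercept = a, slope = b)
    }
  }
  best
}

#' Assemble the population geography table
#'
#' Joins the per-population genetic summaries with coordinates and the
#' map-derived predictors: consensus suitability in each period, suitability
#' deltas between successive periods (later minus earlier), and great-circle
#' distances to the period centroids and the refugium centroid.
#'
#' @param summary a \code{"popgen_summary"} (per-population rows only are
#'   used).
#' @param coords data frame \code{pop_id}, \code{lon}, \code{lat} matching
#'   the summary's population codes.
#' @param stack a \code{"suitability_stack"} with periods ordered oldest
#'   first.
#' @param threshold presence threshold for centroids and the refugium.
#' @return data frame, one row per population, with predictors as columns.
#' @export
population_geo <- function(summary, coords, stack, threshold = 0.3) {
  pops <- summary$pop[!summary$pop %in% c("Mean", "SD", "Overall")]
  idx <- match(pops, coords$pop_id)
  if (any(is.na(idx))) stop("coordinates missing for: ",
                            paste(pops[is.na(idx)], collapse = ", "))
  co <- coords[idx, , drop = FALSE]
  periods <- unique(stack$layers$period)
  cons <- lapply(periods, consensus_map, stack = stack)
  names(cons) <- periods
  out <- data.frame(pop_id = pops, lon = co$lon, lat = co$lat,
                    He = summary$He[match(pops, summary$pop)],
                    Ar_star = summary$Ar_star[match(pops, summary$pop)],
                    stringsAsFactors = FALSE)
  for (p in periods)
    out[[paste0("suit_", p)]] <- extract_at_points(cons[[p]], co)
  for (k in seq_len(length(periods) - 1)) {
    lab <- paste0("delta_", periods[k], "_", periods[k + 1])
    out[[lab]] <- out[[paste0("suit_", periods[k + 1])]] -
      out[[paste0("suit_", periods[k])]]
  }
  ref <- refugium_map(cons, threshold = threshold)
  cents <- c(lapply(cons, map_centroid, threshold = threshold),
             list(refugium = map_centroid(ref, threshold = 0.5)))
  for (nm in names(cents)) {
    cc <- cents[[nm]]
    out[[paste0("dist_", nm)]] <- if (anyNA(cc)) NA_real_ else
      geosphere::distHaversine(as.matrix(co[, c("lon", "lat")]),
                               cc[c("lon", "lat")]) / 1000
  }
  out
}

#' Quantile-regression envelope report
#'
#' Fits He and Ar* against every predictor column at the lower, median and
#' upper quantiles and flags a "triangular envelope" when exactly one of the
#' two extreme quantile slopes is significant, or when both are but with
#' opposite signs -- the signature of a predictor bounding the diversity a
#' population can attain (from above or from below) rather than fixing it.
#'
#' @param geo table from \code{\link{population_geo}} (or any data frame
#'   with response and predictor columns).
#' @param responses response column names (default \code{He}, \code{Ar_star};
#'   Ar* rows with NA -- e.g. excluded low-sample populations -- are dropped
#'   per fit).
#' @param predictors predictor column names (default: every \code{suit_},
#'   \code{delta_} and \code{dist_} column).
#' @param taus quantile levels (default 0.10, 0.50, 0.90; the first and last
#'   are used for the envelope flag).
#' @param alpha significance level for the envelope flag (default 0.05).
#' @param n_boot bootstrap replicates per fit.
#' @param seed integer seed.
#' @return data frame with one row per response x predictor x tau, plus an
#'   \code{envelope} flag repeated within each response x predictor.
#' @export
envelope_report <- function(geo, responses = c("He", "Ar_star"),
                            predictors = NULL, taus = c(0.1, 0.5, 0.9),
                            alpha = 0.05, n_boot = 499L, seed = NULL) {
  if (is.null(predictors))
    predictors <- grep("^(suit_|delta_|dist_)", names(geo), value = TRUE)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  lo_tau <- min(taus); hi_tau <- max(taus)
  for (resp in intersect(responses, names(geo))) {
    for (pred in predictors) {
      ok <- is.finite(geo[[resp]]) & is.finite(geo[[pred]])
      if (sum(ok) < 5 || length(unique(geo[[pred]][ok])) < 2) next
      ft <- quantile_fit(geo[[pred]][ok], geo[[resp]][ok], taus = taus,
                         n_boot = n_boot)
      hi <- ft[ft$tau == hi_tau, ]
      lo <- ft[ft$tau == lo_tau, ]
      hi_sig <- isTRUE(hi$p < alpha)
      lo_sig <- isTRUE(lo$p < alpha)
      env <- xor(hi_sig, lo_sig) ||
        (hi_sig && lo_sig && sign(hi$slope) != sign(lo$slope))
      ft$response <- resp
      ft$predictor <- pred
      ft$n <- sum(ok)
      ft$envelope <- env
      out[[length(out) + 1]] <- ft
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("response", "predictor", "n", "tau", "intercept", "slope", "p",
        "envelope")]
}
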