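# Spatially explicit analyses: geodesic distances, Mantel tests,
# palaeo-suitability stability, range centroids, quantile regressions and
# isolation by distance.

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param a,b numeric `c(lat, lon)` in decimal degrees, or two-column
#'   matrices (lat, lon) of equal height.
#' @return Distance in km.
#' @export
geodesic_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (any(abs(a[, 1]) > 90 | abs(b[, 1]) > 90) ||
      any(abs(a[, 2]) > 180 | abs(b[, 2]) > 180)) {
    stop_invalid("coordinates must be lat in [-90,90], lon in [-180,180]")
  }
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371000) / 1000
}

#' Pairwise geodesic distance matrix
#'
#' @param points data frame or matrix with columns `lat`, `lon` (or two
#'   unnamed columns in that order).
#' @return Symmetric matrix of distances in km.
#' @export
geodesic_distance_matrix <- function(points) {
  pts <- as.matrix(points[, intersect(c("lat", "lon"), colnames(points))])
  if (ncol(pts) != 2) pts <- as.matrix(points)[, 1:2]
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geodesic_distance(matrix(pts[i, ], n, 2, byrow = TRUE), pts)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(rownames(points))) dimnames(d) <- list(rownames(points), rownames(points))
  d
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' distance matrices; significance by random permutation of the
#' rows/columns of the second matrix. The test is two-sided on `|r|`.
#'
#' @param A,B square symmetric matrices with zero diagonals, same size
#'   `>= 3`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional integer seed.
#' @return List with `r`, `r_squared`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 10000, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (n < 3 || any(dim(A) != n) || any(dim(B) != n)) {
    stop_invalid("matrices must be square of the same dimension >= 3")
  }
  ut <- upper.tri(A)
  a <- A[ut]
  if (sd(a) == 0 || sd(B[ut]) == 0) {
    stop_invalid("constant distance matrix: correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- cor(a, B[ut])
  ge <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    if (abs(cor(a, B[p, p][ut])) >= abs(r_obs) - 1e-12) ge <- ge + 1L
  }
  list(r = r_obs, r_squared = r_obs^2,
       p_value = if (n_perm > 0) ge / n_perm else NA_real_,
       n_perm = n_perm, alternative = "two-sided on |r|")
}

#' Suitability stability across time slices and the refugium mask
#'
#' Stability per cell is minus the mean absolute pairwise difference of
#' suitability across the time slices (0 = perfectly stable, more
#' negative = less stable); the refugium mask marks cells suitable
#' (above `threshold`) in every slice.
#'
#' @param rasters list of `suitability_raster` objects on one grid.
#' @param threshold presence cutoff for the refugium mask (default 0.5).
#' @return List with `stability` (raster), `mean_abs_diff` (raster of raw
#'   mean absolute differences) and `refugium` (logical-valued raster).
#' @export
suitability_stability <- function(rasters, threshold = 0.5) {
  if (length(rasters) < 2) stop_invalid("need at least two time slices")
  hdr <- rasters[[1]][c("ncols", "nrows", "xll", "yll", "cellsize")]
  for (r in rasters[-1]) {
    if (!identical(hdr, r[c("ncols", "nrows", "xll", "yll", "cellsize")])) {
      stop_invalid("raster grids do not align")
    }
  }
  vals <- lapply(rasters, function(r) r$values)
  K <- length(vals)
  acc <- 0
  np <- 0
  suit <- vals[[1]] >= threshold
  for (i in 1:(K - 1)) {
    for (j in (i + 1):K) {
      acc <- acc + abs(vals[[i]] - vals[[j]])
      np <- np + 1
    }
  }
  for (k in seq_len(K)) suit <- suit & (vals[[k]] >= threshold)
  mad <- acc / np
  mk <- function(v, tag) {
    out <- rasters[[1]]
    out$values <- v
    out$tag <- tag
    out
  }
  list(stability = mk(-mad, "stability"),
       mean_abs_diff = mk(mad, "mean_abs_diff"),
       refugium = mk(suit * 1, "refugium"))
}

#' Centroid of the thresholded range of a suitability raster
#'
#' Unweighted mean of the cell-centre coordinates of all cells whose
#' suitability is at least `threshold`.
#'
#' @param raster a `suitability_raster`.
#' @param threshold presence cutoff.
#' @return `c(lat, lon)` of the centroid.
#' @export
range_centroid <- function(raster, threshold = 0.5) {
  cc <- raster_cell_centers(raster)
  sel <- raster$values >= threshold
  if (!any(sel)) stop_invalid("no cells above threshold: empty range")
  c(lat = mean(cc$lat[sel]), lon = mean(cc$lon[sel]))
}

#' Quantile regression of y on x (single predictor)
#'
#' Minimizes the pinball (check) loss
#' `sum(rho_tau(y - a - b x))` with
#' `rho_tau(u) = u * (tau - (u < 0))`. The minimum of the simple linear
#' quantile-regression problem is attained at a line through two data
#' points, so the fit enumerates all point pairs exactly; ties in loss
#' are broken deterministically by smaller `|slope|`, then smaller
#' intercept.
#'
#' @param x predictor, length `>= 3`, non-constant.
#' @param y response, same length.
#' @param tau quantile in `(0, 1)` (0.5 = least absolute deviations).
#' @return List with `intercept`, `slope`, `tau`, `loss` and fitted
#'   values.
#' @export
quantile_regression <- function(x, y, tau = 0.5) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("x and y must have equal length >= 3")
  }
  if (tau <= 0 || tau >= 1) stop_invalid("tau must be in (0, 1)")
  if (sd(x) == 0) stop_invalid("constant predictor: slope undefined")
  pin <- function(u) sum(u * (tau - (u < 0)))
  n <- length(x)
  best <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      loss <- pin(y - a - b * x)
      cand <- c(a = a, b = b, loss = loss)
      if (is.null(best) ||
          loss < best["loss"] - 1e-12 ||
          (abs(loss - best["loss"]) <= 1e-12 &&
           (abs(b) < abs(best["b"]) - 1e-12 ||
            (abs(abs(b) - abs(best["b"])) <= 1e-12 && a < best["a"])))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) stop_invalid("no valid point pair (constant predictor)")
  list(intercept = unname(best["a"]), slope = unname(best["b"]),
       tau = tau, loss = unname(best["loss"]),
       fitted = unname(best["a"] + best["b"] * x))
}

#' Isolation by distance: Mantel test of linearized phiST on log distance
#'
#' Correlates the linearized pairwise `phiST/(1 - phiST)` matrix with the
#' base-10 logarithm of the geodesic distance matrix. Zero distances are
#' floored at half the minimum positive distance before taking logs.
#'
#' @param phist_matrix symmetric pairwise phiST matrix (raw, not
#'   linearized).
#' @param points coordinates (`lat`, `lon`) in matrix/data-frame form,
#'   rows matching `phist_matrix`.
#' @param n_perm Mantel permutations.
#' @param seed optional integer seed.
#' @param linearize apply `phi/(1-phi)` (default `TRUE`; pass `FALSE` if
#'   the matrix is already linearized).
#' @return The [mantel_test()] result plus the two matrices used.
#' @export
isolation_by_distance <- function(phist_matrix, points, n_perm = 10000,
                                  seed = NULL, linearize = TRUE) {
  G <- as.matrix(phist_matrix)
  if (nrow(G) != nrow(points)) stop_invalid("matrix/points dimension mismatch")
  if (linearize) {
    G <- G / (1 - G)
    diag(G) <- 0
  }
  D <- geodesic_distance_matrix(points)
  pos <- D[upper.tri(D)]
  pos <- pos[pos > 0]
  if (!length(pos)) stop_invalid("all distances are zero")
  floor_km <- min(pos) / 2
  Dl <- log10(pmax(D, floor_km))
  diag(Dl) <- 0
  res <- mantel_test(G, Dl, n_perm = n_perm, seed = seed)
  res$linearized_phist <- G
  res$log10_distance <- Dl
  res
}
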