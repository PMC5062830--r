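test_that("great-circle distances match closed-form references", {
  expect_equal(geodesic_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(geodesic_distance(c(0, 0), c(0, 180)), pi * 6371,
               tolerance = 1e-3)
  expect_equal(geodesic_distance(c(0, 0), c(0, 1)), 2 * pi * 6371 / 360,
               tolerance = 1e-3)
  expect_error(geodesic_distance(c(95, 0), c(0, 0)), "coordinates")
})

test_that("distance matrices are symmetric and satisfy the triangle inequality", {
  set.seed(41)
  pts <- cbind(lat = runif(6, -30, 10), lon = runif(6, -70, -35))
  D <- geodesic_distance_matrix(pts)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("Mantel r hits its bounds on affine copies", {
  set.seed(43)
  pts <- cbind(lat = runif(5, -20, 0), lon = runif(5, -60, -40))
  A <- geodesic_distance_matrix(pts)
  expect_equal(mantel_test(A, A, n_perm = 50, seed = 1)$r, 1)
  B <- max(A) + 1 - A
  diag(B) <- 0
  expect_equal(mantel_test(A, B, n_perm = 50, seed = 1)$r, -1)
  expect_error(mantel_test(A, matrix(1, 5, 5) - diag(5) * 0, n_perm = 10),
               "constant")
})

test_that("Mantel permutation p matches exact enumeration on 4x4 matrices", {
  set.seed(47)
  mk <- function() {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- runif(6)
    m + t(m)
  }
  A <- mk(); B <- mk()
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  perms <- rbind(1:4)
  perms <- do.call(rbind, combinat_perms(4))
  r_all <- apply(perms, 1, function(p) cor(A[ut], B[p, p][ut]))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  res <- mantel_test(A, B, n_perm = 10000, seed = 2)
  expect_equal(res$r, r_obs, tolerance = 1e-12)
  # binomial 99% bound around the exact p
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), max(2.58 * se, 0.02))
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(res$r, unname(vg$statistic), tolerance = 1e-9)
})

test_that("suitability stability and refugium behave on constructed rasters", {
  v1 <- matrix(c(1, 0, 0.5, 0.2), 2, 2)
  r1 <- suitability_raster(v1, xll = -50, yll = -20, tag = "21ka")
  r2 <- suitability_raster(v1, xll = -50, yll = -20, tag = "present")
  st <- suitability_stability(list(r1, r2), threshold = 0.4)
  expect_true(all(st$stability$values == 0))
  expect_equal(st$refugium$values, (v1 >= 0.4) * 1)
  # one cell 1.0 / 0.0 / 1.0 across slices -> mean |diff| 2/3
  mk <- function(x, tag) suitability_raster(matrix(x, 1, 1), 0, 0, tag = tag)
  st3 <- suitability_stability(list(mk(1, "a"), mk(0, "b"), mk(1, "c")))
  expect_equal(st3$mean_abs_diff$values[1, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(st3$stability$values[1, 1], -2 / 3, tolerance = 1e-12)
  # refugium is a subset of each slice's suitable mask
  set.seed(51)
  rs <- lapply(1:3, function(i) {
    suitability_raster(matrix(runif(25), 5, 5), 0, 0, tag = paste0("t", i))
  })
  stn <- suitability_stability(rs, threshold = 0.5)
  for (r in rs) expect_true(all(stn$refugium$values <= (r$values >= 0.5)))
  r_off <- suitability_raster(matrix(0.5, 5, 5), 1, 0)
  expect_error(suitability_stability(list(rs[[1]], r_off)), "align")
})

test_that("range centroids average suprathreshold cell centres", {
  v <- matrix(0, 3, 3)
  v[2, 2] <- 1
  r <- suitability_raster(v, xll = -50, yll = -20, cellsize = 0.5)
  cen <- range_centroid(r, 0.5)
  expect_equal(unname(cen["lon"]), -50 + 1.5 * 0.5)
  expect_equal(unname(cen["lat"]), -20 + 1.5 * 0.5)
  # symmetric pair about a meridian
  v2 <- matrix(0, 1, 3); v2[1, 1] <- 1; v2[1, 3] <- 1
  r2 <- suitability_raster(v2, xll = 0, yll = 0, cellsize = 1)
  expect_equal(unname(range_centroid(r2, 0.5)["lon"]), 1.5)
  # three known cells -> arithmetic mean of their centres
  v3 <- matrix(0, 2, 2); v3[1, 1] <- v3[1, 2] <- v3[2, 1] <- 1
  r3 <- suitability_raster(v3, xll = 0, yll = 0, cellsize = 1)
  expect_equal(unname(range_centroid(r3, 0.5)),
               c(mean(c(1.5, 1.5, 0.5)), mean(c(0.5, 1.5, 0.5))))
  # threshold-invariance to subthreshold value changes
  v4 <- v3; v4[2, 2] <- 0.4
  r4 <- suitability_raster(v4, xll = 0, yll = 0, cellsize = 1)
  expect_equal(range_centroid(r4, 0.5), range_centroid(r3, 0.5))
  expect_error(range_centroid(suitability_raster(matrix(0, 2, 2), 0, 0), 0.5),
               "empty range")
})

test_that("quantile regression minimizes the pinball loss", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 2 * x + 1
  for (tau in c(0.1, 0.5, 0.9)) {
    fit <- quantile_regression(x, y, tau)
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-12)
    expect_equal(fit$loss, 0, tolerance = 1e-12)
  }
  # 6-point toy set vs brute-force grid search
  set.seed(53)
  y2 <- c(1.2, 2.1, 2.8, 4.4, 4.9, 6.3)
  for (tau in c(0.25, 0.5, 0.75)) {
    fit <- quantile_regression(x, y2, tau)
    pin <- function(u) sum(u * (tau - (u < 0)))
    grid <- expand.grid(a = seq(-2, 3, by = 0.01),
                        b = seq(0, 2, by = 0.01))
    gloss <- min(mapply(function(a, b) pin(y2 - a - b * x),
                        grid$a, grid$b))
    expect_lte(fit$loss, gloss + 1e-3)
  }
  expect_error(quantile_regression(rep(1, 5), 1:5, 0.5), "constant")
  expect_error(quantile_regression(x, y, 1.5), "tau")
})

test_that("isolation by distance composes phiST linearization with log distance", {
  # construct collinear populations whose linearized phiST is proportional
  # to log10 distance -> r = 1
  pts <- cbind(lat = rep(0, 5), lon = c(0, 1, 2, 4, 8))
  D <- geodesic_distance_matrix(pts)
  L <- log10(pmax(D, min(D[D > 0]) / 2)); diag(L) <- 0
  lin <- L / max(L)                      # target linearized phi in [0,1)
  phi <- lin / (1 + lin)                 # invert phi/(1-phi)
  diag(phi) <- 0
  res <- isolation_by_distance(phi, pts, n_perm = 200, seed = 3)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_lt(res$p_value, 0.1)
  # composition: identical to calling mantel_test on the same matrices
  direct <- mantel_test(res$linearized_phist, res$log10_distance,
                        n_perm = 200, seed = 3)
  expect_equal(res$r, direct$r)
  expect_equal(res$p_value, direct$p_value)
})
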