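test_that("haversine distances have the closed equatorial form and metric properties", {
  expect_equal(haversine_matrix(c(5, 5), c(10, 10))[1, 2], 0)
  d <- haversine_matrix(c(0, 1), c(0, 0))
  expect_equal(d[1, 2], 2 * pi * 6371 / 360, tolerance = 1e-6)
  set.seed(51)
  lon <- runif(3, -180, 180); lat <- runif(3, -60, 60)
  D <- haversine_matrix(lon, lat)
  expect_equal(D, t(D))
  expect_lte(D[1, 3], D[1, 2] + D[2, 3] + 1e-9)
  expect_error(haversine_matrix(200, 10), "range")
})

test_that("ANOSIM gives R = 1 under perfect separation and matches vegan", {
  # two tight clusters far apart
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
             matrix(rnorm(8, 50, 0.1), 4, 2))
  D <- as.matrix(dist(X))
  g <- rep(c("a", "b"), each = 4)
  res <- anosim(D, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p, 0.05)
  # statistic agrees with vegan and with the definition-level oracle
  set.seed(52)
  tab <- random_table(9, 15) + 1
  bc <- bray_curtis(tab)
  g2 <- rep(c("a", "b", "c"), each = 3)
  res2 <- anosim(bc, g2, n_perm = 49, seed = 2)
  vres <- vegan::anosim(stats::as.dist(bc), g2, permutations = 49)
  expect_equal(res2$statistic, unname(vres$statistic), tolerance = 1e-12)
  expect_equal(res2$statistic, oracle_anosim_R(bc, g2), tolerance = 1e-12)
  expect_error(anosim(bc, c("a", rep("b", 8))), "at least 2 members")
})

test_that("exhaustive ANOSIM p at n = 6 equals full label enumeration", {
  set.seed(53)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(D, g, exhaustive = TRUE)
  # independent enumeration over all choose(6,3) = 20 assignments of 3 a's
  stats_all <- vapply(two_group_assignments(6, 3),
                      function(gg) oracle_anosim_R(D, gg), numeric(1))
  p_oracle <- mean(stats_all >= res$statistic - 1e-12)
  expect_equal(res$p, p_oracle)
  expect_equal(res$n_perm, 20)
})

test_that("Mantel r is exact for identical matrices and matches vegan", {
  D <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  res <- mantel(D, D, n_perm = 49, seed = 1)
  expect_equal(res$statistic, 1)
  set.seed(54)
  D2 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  dimnames(D) <- dimnames(D2) <- list(paste0("s", 1:7), paste0("s", 1:7))
  res2 <- mantel(D, D2, n_perm = 49, seed = 2)
  vres <- vegan::mantel(stats::as.dist(D), stats::as.dist(D2),
                        method = "spearman", permutations = 49)
  expect_equal(res2$statistic, unname(vres$statistic), tolerance = 1e-12)
  # constant matrix flagged
  Dc <- matrix(1, 5, 5) - diag(5)
  expect_true(mantel(Dc, Dc)$undefined)
})

test_that("exhaustive Mantel p at n = 5 equals the 120-permutation value", {
  set.seed(55)
  D1 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  res <- mantel(D1, D2, exhaustive = TRUE)
  v1 <- rank(D1[lower.tri(D1)])
  perms <- all_perms_5()
  stats_all <- vapply(seq_len(nrow(perms)), function(i) {
    idx <- perms[i, ]
    stats::cor(v1, rank(D2[idx, idx][lower.tri(D1)]))
  }, numeric(1))
  expect_equal(res$n_perm, 120)
  expect_equal(res$p, mean(stats_all >= res$statistic - 1e-12))
})

test_that("environmental distances follow the transformed, standardized Euclidean form", {
  env <- rbind(c(4, 9), c(1, 1), c(9, 4))
  # sqrt then scale by column sd
  X <- scale(sqrt(env))
  want <- as.matrix(dist(X))
  got <- env_distance(env)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_equal(env_distance(rbind(c(2, 3), c(2, 3), c(5, 7)))[1, 2], 0)
  expect_error(env_distance(cbind(c(1, 1, 1), c(1, 2, 3))), "constant")
  # no transform, no standardization: plain Euclidean
  got2 <- env_distance(env, transform = "none", standardize = FALSE)
  expect_equal(unname(got2), unname(as.matrix(dist(env))))
})

test_that("PCNM reduces to plain PCoA when the truncation is inactive", {
  set.seed(56)
  lon <- runif(8, 120, 127); lat <- runif(8, 27, 33)
  D <- haversine_matrix(lon, lat)
  basis <- pcnm(D, truncation = max(D))
  plain <- pcoa(D)
  expect_equal(unname(abs(basis$vectors)), unname(abs(plain$scores)),
               tolerance = 1e-9)
})

test_that("PCNM on a regular transect yields orthogonal, centered, wave-like axes", {
  lon <- seq(0, 0.9, by = 0.1); lat <- rep(0, 10)
  D <- haversine_matrix(lon, lat)
  basis <- pcnm(D)
  V <- basis$vectors
  expect_lte(ncol(V), 9)
  expect_true(all(basis$values > 0))
  expect_true(all(diff(basis$values) <= 1e-9))
  expect_true(max(abs(colMeans(V))) < 1e-12)
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # leading axis is the half-wave: one sign change along the transect
  lead <- V[, 1]
  expect_equal(sum(diff(sign(lead)) != 0), 1)
  # truncation threshold equals vegan's spanning-tree choice
  vref <- vegan::pcnm(stats::as.dist(D))
  expect_equal(basis$truncation, vref$threshold, tolerance = 1e-9)
  expect_equal(length(basis$values), length(vref$values[vref$values > 1e-8]))
})

test_that("distance decay recovers a constructed linear relationship", {
  # dyadic spacing: all 28 pairwise distances distinct, no float ties
  x <- 2^(0:7) / 128
  lonlike <- cbind(x, 0)
  D_pred <- as.matrix(dist(lonlike))
  D_comm <- 0.1 * D_pred          # similarity = 1 - 0.1 * distance
  dimnames(D_comm) <- dimnames(D_pred) <-
    list(paste0("s", 1:8), paste0("s", 1:8))
  res <- distance_decay(D_comm, D_pred, n_perm = 99, seed = 1)
  expect_equal(res$slope, -0.1, tolerance = 1e-10)
  expect_equal(res$intercept, 1, tolerance = 1e-10)
  expect_equal(res$rho, -1)
  expect_equal(res$n_pairs, 28)
})

test_that("distance decay finds no slope when the predictor is uninformative", {
  set.seed(57)
  slopes <- replicate(30, {
    tab <- random_table(8, 20) + 1
    D_comm <- bray_curtis(tab)
    D_pred <- as.matrix(dist(runif(8)))
    dimnames(D_pred) <- dimnames(D_comm)
    distance_decay(D_comm, D_pred, n_perm = 9, seed = 1)$slope
  })
  expect_lt(abs(mean(slopes)), 0.15)
})

test_that("ANOSIM R is invariant under monotone transforms of the distances", {
  set.seed(58)
  tab <- random_table(8, 12) + 1
  D <- bray_curtis(tab)
  g <- rep(c("a", "b"), each = 4)
  r1 <- anosim(D, g, n_perm = 9, seed = 1)$statistic
  r2 <- anosim(D^2, g, n_perm = 9, seed = 1)$statistic
  r3 <- anosim(sqrt(D), g, n_perm = 9, seed = 1)$statistic
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})
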