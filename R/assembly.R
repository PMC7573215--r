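# Spatial and environmental inference: geographic distances, ANOSIM, Mantel
# tests, environmental distances, PCNM spatial eigenvectors and
# distance-decay regression.

#' Great-circle distance matrix
#'
#' Haversine distances between coordinate pairs, Earth radius 6371.0 km.
#' Depth is ignored; the vertical design enters analyses only as a grouping
#' factor.
#'
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Symmetric distance matrix in km.
#' @export
haversine_matrix <- function(lon, lat) {
  if (length(lon) != length(lat)) stop("lon/lat length mismatch", call. = FALSE)
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of range", call. = FALSE)
  R <- 6371.0
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  n <- length(lon)
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  a <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  d <- 2 * R * asin(pmin(sqrt(a), 1))
  diag(d) <- 0
  if (!is.null(names(lon))) dimnames(d) <- list(names(lon), names(lon))
  d
}

# ANOSIM R statistic on ranked dissimilarities
anosim_stat <- function(rank_d, between) {
  n_pairs <- length(rank_d)
  n <- (1 + sqrt(1 + 8 * n_pairs)) / 2
  (mean(rank_d[between]) - mean(rank_d[!between])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group dissimilarities:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' with significance by permutation of group labels. `R = 1` means complete
#' separation, values near 0 mean none.
#'
#' @param D Distance matrix (or `dist`).
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   members).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all distinct label assignments (exact p; only
#'   feasible for small n).
#' @return List with `statistic` (R), `p`, `n_perm`, `seed`.
#' @export
anosim <- function(D, groups, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  D <- as_distance_matrix(D)
  groups <- as.character(groups)
  if (length(groups) != nrow(D)) stop("one label per sample", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)
  rank_d <- rank(lower_tri(D))
  between_of <- function(g) lower_tri(outer(g, g, "!="))
  obs <- anosim_stat(rank_d, between_of(groups))
  if (exhaustive) {
    perms <- multiset_permutations(groups)
    stats_p <- vapply(perms, function(g) anosim_stat(rank_d, between_of(g)),
                      numeric(1))
    p <- perm_pvalue(obs, stats_p, exhaustive = TRUE)
    n_perm <- length(perms)
  } else {
    stats_p <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      anosim_stat(rank_d, between_of(sample(groups))), numeric(1)))
    p <- perm_pvalue(obs, stats_p, exhaustive = FALSE)
  }
  list(statistic = obs, p = p, n_perm = n_perm, seed = seed)
}

#' Mantel test
#'
#' Correlation between the lower triangles of two distance matrices, with
#' significance by simultaneous row/column permutation of the second matrix.
#' One-sided (`r >= observed`) by default, matching directional hypotheses
#' about distance decay; `alternative = "two.sided"` uses `|r|`.
#'
#' @param D1,D2 Distance matrices with matching labels/order.
#' @param method Correlation method (`"spearman"` default, or `"pearson"`).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations (exact p).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `statistic` (r), `p`, `n_perm`, `seed`; `undefined` is
#'   `TRUE` when either matrix is constant.
#' @export
mantel <- function(D1, D2, method = c("spearman", "pearson"),
                   n_perm = 999, seed = NULL, exhaustive = FALSE,
                   alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  D1 <- as_distance_matrix(D1); D2 <- as_distance_matrix(D2)
  if (nrow(D1) != nrow(D2)) stop("matrix size mismatch", call. = FALSE)
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("matrix labels do not match", call. = FALSE)
  v1 <- lower_tri(D1)
  if (method == "spearman") v1 <- rank(v1)
  v2 <- lower_tri(D2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n_perm = 0, seed = seed,
                undefined = TRUE))
  r_of <- function(idx) {
    v <- lower_tri(D2[idx, idx])
    if (method == "spearman") stats::cor(v1, rank(v)) else stats::cor(v1, v)
  }
  n <- nrow(D1)
  obs <- r_of(seq_len(n))
  side <- function(x) if (alternative == "two.sided") abs(x) else x
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_p <- apply(perms, 1, r_of)
    p <- perm_pvalue(side(obs), side(stats_p), exhaustive = TRUE)
    n_perm <- nrow(perms)
  } else {
    stats_p <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      r_of(sample.int(n)), numeric(1)))
    p <- perm_pvalue(side(obs), side(stats_p), exhaustive = FALSE)
  }
  list(statistic = obs, p = p, n_perm = n_perm, seed = seed,
       undefined = FALSE)
}

#' Environmental distance matrix
#'
#' Euclidean distances between samples on (optionally square-root
#' transformed and column-standardized) environmental variables. Square-root
#' transformation reduces non-normality and heteroscedasticity of
#' concentration-like variables.
#'
#' @param env Samples x variables matrix or data frame (finite values).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @param standardize Scale columns to zero mean and unit variance.
#' @return Symmetric distance matrix.
#' @export
env_distance <- function(env, transform = c("sqrt", "none"),
                         standardize = TRUE) {
  transform <- match.arg(transform)
  X <- as.matrix(env)
  if (any(!is.finite(X))) stop("non-finite environmental values", call. = FALSE)
  if (transform == "sqrt") {
    if (any(X < 0))
      stop("sqrt transform requires non-negative values", call. = FALSE)
    X <- sqrt(X)
  }
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column cannot be standardized: ",
           colnames(X)[sds == 0][1], call. = FALSE)
    X <- scale(X)
  }
  as.matrix(stats::dist(X))
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated (distances beyond the threshold replaced by four
#' times the threshold), then subjected to principal coordinates analysis;
#' eigenvectors with positive eigenvalues, scaled by the square root of
#' their eigenvalue, form the spatial basis. The default threshold is the
#' longest edge of the minimum spanning tree, the smallest value keeping all
#' sites connected.
#'
#' @param D_geo Geographic distance matrix (km).
#' @param truncation Threshold distance, or `NULL` for the MST default.
#' @return List with `vectors` (n x q, centered, orthogonal), `values`
#'   (positive, non-increasing) and `truncation` used.
#' @export
pcnm <- function(D_geo, truncation = NULL) {
  D_geo <- as_distance_matrix(D_geo)
  if (nrow(D_geo) < 3) stop("at least 3 sites are required", call. = FALSE)
  if (max(D_geo) == 0) stop("all sites are coincident", call. = FALSE)
  if (is.null(truncation)) {
    mst <- vegan::spantree(stats::as.dist(D_geo))
    truncation <- max(mst$dist)
  }
  Dmod <- D_geo
  Dmod[Dmod > truncation] <- 4 * truncation
  diag(Dmod) <- 0
  fit <- pcoa(Dmod)
  pos <- fit$eigenvalues > max(abs(fit$eigenvalues)) * 1e-9
  vec <- fit$scores
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  list(vectors = vec, values = fit$eigenvalues[pos], truncation = truncation)
}

#' Distance-decay regression
#'
#' Linear regression of community similarity (1 - dissimilarity) on a
#' predictor distance over all sample pairs, with Spearman correlation and a
#' Mantel-style permutation p-value (pairs are not independent, so ordinary
#' regression inference does not apply).
#'
#' @param D_comm Community dissimilarity matrix.
#' @param D_pred Predictor distance matrix (geographic or environmental).
#' @param n_perm,seed Permutation control.
#' @return List with `slope`, `intercept`, `rho`, `p`, `n_pairs`.
#' @export
distance_decay <- function(D_comm, D_pred, n_perm = 999, seed = NULL) {
  D_comm <- as_distance_matrix(D_comm); D_pred <- as_distance_matrix(D_pred)
  sim <- 1 - lower_tri(D_comm)
  x <- lower_tri(D_pred)
  if (stats::sd(x) == 0) stop("constant predictor distances", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), sim)
  rho <- stats::cor(x, sim, method = "spearman")
  Dsim <- D_comm # permute community matrix rows/columns
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(Dsim))
    stats::cor(x, 1 - lower_tri(Dsim[idx, idx]), method = "spearman")
  }, numeric(1)))
  p <- perm_pvalue(abs(rho), abs(r_perm), exhaustive = FALSE)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rho = rho, p = p, n_pairs = length(x))
}
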