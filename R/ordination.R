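# Unconstrained and constrained ordination, and configuration comparison by
# Procrustes superimposition with its permutation test (PROTEST).

ord_result <- function(method, scores, eigenvalues = NULL, proportion = NULL,
                       ...) {
  structure(c(list(method = method, scores = scores,
                   eigenvalues = eigenvalues, proportion = proportion),
              list(...)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d points, %d axes\n", x$method,
              nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$proportion))
    cat("axis variance proportions:",
        paste(sprintf("%.3f", utils::head(x$proportion, 5)), collapse = " "),
        "\n")
  if (!is.null(x$stress)) cat(sprintf("stress: %.5f\n", x$stress))
  invisible(x)
}

#' Principal component analysis
#'
#' Centered (and optionally standardized) eigen-decomposition of a
#' samples-by-variables matrix via singular value decomposition.
#'
#' @param X Numeric matrix or data frame (samples x variables).
#' @param scale. Standardize columns to unit variance.
#' @return `ordination` with site `scores`, `eigenvalues`, per-axis variance
#'   `proportion` (sums to 1) and variable `loadings`.
#' @export
pca <- function(X, scale. = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least 2 samples are required", call. = FALSE)
  if (scale. && any(apply(X, 2, stats::sd) == 0))
    stop("constant column cannot be scaled to unit variance", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = scale.)
  sv <- svd(Xc)
  eig <- sv$d^2 / (nrow(X) - 1)
  keep <- sv$d > max(sv$d) * 1e-12
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(sum(keep))))
  loadings <- sv$v[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  ord_result("PCA", scores, eigenvalues = eig,
             proportion = eig / sum(eig), loadings = loadings)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by eigen-decomposition. Axes
#' with positive eigenvalues are returned scaled by the square root of the
#' eigenvalue; negative eigenvalues (non-Euclidean input) are reported, not
#' silently dropped.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @return `ordination` with `scores` on positive axes, all `eigenvalues`,
#'   and `proportion` relative to the sum of positive eigenvalues.
#' @export
pcoa <- function(D) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - rowMeans(A)
  G <- t(t(G) - colMeans(G))   # row centering already absorbed the grand mean
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  eps <- max(abs(e$values)) * 1e-9
  pos <- e$values > eps
  scores <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  dimnames(scores) <- list(rownames(D), paste0("Axis", seq_len(sum(pos))))
  ord_result("PCoA", scores, eigenvalues = e$values,
             proportion = e$values[pos] / sum(e$values[pos]))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimization (iterative majorization with monotone
#' regression, via `vegan::monoMDS`) from the best of a PCoA-derived start
#' plus `n_starts` random starts.
#'
#' @param D Distance matrix (or `dist`).
#' @param k Number of dimensions.
#' @param n_starts Number of random starts in addition to the PCoA start.
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed for the random starts.
#' @return `ordination` with `scores`, `stress` (in `[0, 1]`) and a
#'   `converged` flag (non-convergence is flagged, not an error).
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 200, seed = NULL) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (n < k + 1) stop("need at least k + 1 points", call. = FALSE)
  d <- stats::as.dist(D)
  init <- pcoa(D)$scores
  if (ncol(init) < k)
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  starts <- with_seed(seed, c(
    list(init[, 1:k, drop = FALSE]),
    lapply(seq_len(n_starts), function(i) matrix(stats::runif(n * k), n, k))
  ))
  best <- NULL
  for (y0 in starts) {
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                          maxit = max_iter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  scores <- best$points
  dimnames(scores) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  # monoMDS icause 1 means the iteration limit was hit without convergence
  ord_result("NMDS", scores, stress = best$stress,
             converged = best$icause != 1L)
}

#' Redundancy analysis
#'
#' Multivariate least-squares regression of the centered community matrix on
#' the (centered) explanatory matrix, followed by a PCA of the fitted
#' values. Collinear explanatory columns are dropped with a warning.
#'
#' @param Y Community matrix (typically Hellinger-transformed), samples x
#'   species.
#' @param X Explanatory matrix or data frame (numeric), samples x variables.
#' @return `ordination` with constrained site `scores`, constrained-axis
#'   `eigenvalues`, `proportion` (of constrained variance per axis) and
#'   `constrained_fraction` = constrained / total variance.
#' @export
rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("row mismatch between Y and X", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("more explanatory variables than residual degrees of freedom",
         call. = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrx$pivot[(qrx$rank + 1):ncol(Xc)]]
    warning("dropping collinear explanatory column(s): ",
            paste(drop, collapse = ", "))
    Xc <- Xc[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(Xc)
  }
  fitted <- qr.fitted(qrx, Yc)
  sv <- svd(fitted)
  keep <- sv$d > max(sv$d, 1e-300) * 1e-9
  eig <- sv$d[keep]^2 / (nrow(Y) - 1)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  dimnames(scores) <- list(rownames(Y), paste0("RDA", seq_len(sum(keep))))
  total <- sum(Yc^2)
  ord_result("RDA", scores, eigenvalues = eig,
             proportion = if (length(eig)) eig / sum(eig) else numeric(0),
             constrained_fraction = sum(fitted^2) / total,
             biplot = crossprod(scale(Xc), sv$u[, keep, drop = FALSE]))
}

#' Procrustes superimposition
#'
#' Optimal translation, rotation/reflection (via singular value
#' decomposition of the cross-product) and scaling of `Y` onto `X`,
#' minimizing the sum of squared deviations `M2`. In symmetric mode both
#' configurations are first scaled to unit sum of squares, making `M2`
#' comparable across pairs (then `M2 = 1 - (sum of singular values)^2`).
#'
#' @param X Reference configuration (rows are points).
#' @param Y Configuration to be superimposed; narrower matrices are padded
#'   with zero columns to a common width.
#' @param symmetric Use the symmetric scaling convention (default `TRUE`).
#' @return List with `M2`, per-point `residuals`, the rotation matrix, scale
#'   factor and translation used.
#' @export
procrustes <- function(X, Y, symmetric = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("row mismatch", call. = FALSE)
  if (nrow(X) < 2) stop("at least 2 points are required", call. = FALSE)
  k <- max(ncol(X), ncol(Y))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  if (ncol(Y) < k) Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (symmetric) {
    Xc <- Xc / sqrt(sum(Xc^2))
    Yc <- Yc / sqrt(sum(Yc^2))
  }
  sol <- svd(crossprod(Xc, Yc))            # t(Xc) %*% Yc
  rotation <- sol$v %*% t(sol$u)           # applied as Yc %*% rotation
  scale_f <- sum(sol$d) / sum(Yc^2)
  Yrot <- scale_f * Yc %*% rotation
  resid <- sqrt(rowSums((Xc - Yrot)^2))
  list(M2 = sum((Xc - Yrot)^2), residuals = resid,
       rotation = rotation, scale = scale_f,
       translation = attr(Yc, "scaled:center"),
       symmetric = symmetric)
}

#' PROTEST: Procrustean randomization test
#'
#' Significance of the Procrustes concordance between two configurations.
#' The statistic is `sqrt(1 - M2)` under symmetric scaling; the null
#' distribution permutes the rows of `Y`.
#'
#' @param X,Y Configurations with equal row counts.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` row permutations instead (exact p).
#' @return List with `statistic`, `M2`, `p`, `n_perm`.
#' @export
protest <- function(X, Y, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stat <- function(Yp) sqrt(max(0, 1 - procrustes(X, Yp, symmetric = TRUE)$M2))
  obs <- stat(Y)
  if (exhaustive) {
    perms <- all_permutations(nrow(Y))
    stats_p <- apply(perms, 1, function(idx) stat(Y[idx, , drop = FALSE]))
    p <- perm_pvalue(obs, stats_p, exhaustive = TRUE)
    n_perm <- nrow(perms)
  } else {
    stats_p <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat(Y[sample.int(nrow(Y)), , drop = FALSE]), numeric(1)))
    p <- perm_pvalue(obs, stats_p, exhaustive = FALSE)
  }
  list(statistic = obs, M2 = 1 - obs^2, p = p, n_perm = n_perm)
}
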