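# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded operations never perturb the global random stream. A
#' `NULL` seed evaluates `code` with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# lower-triangle vector of a symmetric matrix, column-major (matches dist order)
lower_tri <- function(m) m[lower.tri(m)]

# assert a symmetric, zero-diagonal distance matrix with labels; returns matrix
as_distance_matrix <- function(d, arg = deparse(substitute(d))) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d))
    stop(sprintf("`%s` must be a numeric matrix or 'dist' object", arg), call. = FALSE)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  d
}

# all permutations of seq_len(n); n! rows. Only sensible for small n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# all distinct orderings of a label vector (multiset permutations)
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(lab) {
    if (length(lab) <= 1L) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      i <- match(u, lab)
      for (rest in recurse(lab[-i])) out[[length(out) + 1L]] <- c(u, rest)
    }
    out
  }
  recurse(labels)
}

# permutation p-value: exhaustive uses plain proportion (identity included);
# sampled uses the (1 + exceedances) / (1 + n_perm) estimator so p > 0.
perm_pvalue <- function(stat_obs, stat_perm, exhaustive, tol = 1e-12) {
  hits <- sum(stat_perm >= stat_obs - tol)
  if (exhaustive) hits / length(stat_perm)
  else (1 + hits) / (1 + length(stat_perm))
}
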