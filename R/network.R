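# Thresholded Spearman co-occurrence networks over OTUs, with Storey
# q-value control of the correlation screen and the topological indices used
# to characterize community networks.

# exact permutation p for a Spearman correlation (two-sided), n! permutations
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- all_permutations(n)
  stats_p <- apply(perms, 1, function(idx) abs(stats::cor(rx, ry[idx])))
  mean(stats_p >= obs - 1e-12)
}

#' Pairwise Spearman correlation screen
#'
#' Computes Spearman's rho (midranks for ties) and a p-value for every pair
#' of OTUs present in at least `min_prevalence` samples. Constant OTU
#' vectors are excluded (their correlations are undefined) and counted.
#'
#' Three p-value methods are available. `"pooled"` (default) permutes
#' sample order within each OTU and pools the permuted correlations of all
#' pairs into one null distribution — pairs are exchangeable under the
#' null, so pooling gives `n_perm * n_pairs` null draws and the fine tail
#' resolution an FDR screen over thousands of pairs needs. `"t"` is the
#' classical t approximation, whose tail is anticonservative at the small
#' sample sizes (about 10) typical of per-group screens. `"exact"`
#' enumerates all n! permutations per pair (n <= 9 samples only).
#'
#' @param table OTU table (>= 4 samples); rarefied counts are the intended
#'   input.
#' @param min_prevalence Minimum number of samples an OTU must occur in
#'   (>= 3).
#' @param p_method `"pooled"`, `"t"` or `"exact"`.
#' @param n_perm Whole-table permutations for the pooled null.
#' @param seed Integer seed for the pooled null.
#' @return Tibble: `otu1`, `otu2`, `rho`, `p`; attributes `n_samples`,
#'   `n_excluded_constant`.
#' @export
correlation_screen <- function(table, min_prevalence = 3,
                               p_method = c("pooled", "t", "exact"),
                               n_perm = 200, seed = NULL) {
  p_method <- match.arg(p_method)
  n <- nrow(table)
  if (n < 4) stop("at least 4 samples are required", call. = FALSE)
  if (min_prevalence < 3) stop("min_prevalence must be >= 3", call. = FALSE)
  if (p_method == "exact" && n > 9)
    stop("exact permutation p only supported for n <= 9 samples", call. = FALSE)
  keep <- colSums(table > 0) >= min_prevalence
  x <- table[, keep, drop = FALSE]
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  n_const <- sum(const)
  if (n_const > 0) x <- x[, !const, drop = FALSE]
  m <- ncol(x)
  if (m < 2) stop("fewer than 2 OTUs survive the prevalence screen",
                  call. = FALSE)
  rx <- apply(x, 2, rank)                       # midranks once
  rho <- stats::cor(rx)
  idx <- which(lower.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  p <- switch(p_method,
    t = {
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      pp <- 2 * stats::pt(-abs(tt), df = n - 2)
      pp[abs(r) >= 1 - 1e-12] <- 0
      pp
    },
    exact = vapply(seq_len(nrow(idx)), function(k)
      spearman_exact_p(x[, idx[k, 2]], x[, idx[k, 1]]), numeric(1)),
    pooled = {
      null_abs <- with_seed(seed, {
        unlist(lapply(seq_len(n_perm), function(b) {
          rp <- apply(rx, 2, sample)            # independent sample orders
          abs(stats::cor(rp)[idx])
        }), use.names = FALSE)
      })
      null_sorted <- sort(null_abs)
      n_null <- length(null_sorted)
      hits <- n_null - findInterval(abs(r) - 1e-12, null_sorted)
      (1 + hits) / (1 + n_null)
    })
  out <- tibble::tibble(otu1 = colnames(x)[idx[, 2]],
                        otu2 = colnames(x)[idx[, 1]],
                        rho = r, p = p)
  attr(out, "n_samples") <- n
  attr(out, "n_excluded_constant") <- n_const
  out
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion estimated as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) M))`, followed by the
#' step-up minimum `q_(i) = min_(j >= i) pi0 M p_(j) / j`. With `pi0 = 1`
#' (set `lambda = NULL`) this reduces to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param lambda Tuning parameter for the null-proportion estimate, or
#'   `NULL` for the BH special case.
#' @return Q-values in the input order.
#' @export
storey_qvalues <- function(pvals, lambda = 0.5) {
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  M <- length(pvals)
  pi0 <- if (is.null(lambda)) 1
         else min(1, sum(pvals > lambda) / ((1 - lambda) * M))
  ord <- order(pvals)
  q_sorted <- pi0 * M * pvals[ord] / seq_len(M)
  q_sorted <- rev(cummin(rev(q_sorted)))        # enforce monotonicity
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(M)
  q[ord] <- q_sorted
  q
}

#' Build a co-occurrence network from screened correlations
#'
#' Keeps edges with `|rho| > r_cut` and `q < q_cut`; isolated nodes are
#' dropped. The correlation sign is retained as an edge attribute.
#'
#' @param correlations Tibble from [correlation_screen()] with a `q` column
#'   (attach one via [storey_qvalues()]).
#' @param r_cut Absolute-correlation threshold (default 0.6).
#' @param q_cut Q-value threshold (default 0.05).
#' @param node_data Optional data frame of node annotations (first column
#'   OTU id), e.g. category and lineage.
#' @return Undirected `igraph` graph with edge attributes `rho`, `q`,
#'   `sign`; an empty graph (with a warning) if no edge survives.
#' @export
build_network <- function(correlations, r_cut = 0.6, q_cut = 0.05,
                          node_data = NULL) {
  if (!("q" %in% names(correlations)))
    stop("attach q-values before thresholding (see storey_qvalues)",
         call. = FALSE)
  keep <- abs(correlations$rho) > r_cut & correlations$q < q_cut
  edges <- correlations[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    warning("no correlation survives the thresholds; returning empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  vertices <- NULL
  if (!is.null(node_data)) {
    used <- unique(c(edges$otu1, edges$otu2))
    vertices <- node_data[node_data[[1]] %in% used, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Louvain module detection
#'
#' Greedy modularity optimization on the unweighted graph (edge presence
#' only) by default; set `weighted = TRUE` to weight by `|rho|`.
#' Deterministic for a fixed seed.
#'
#' @param net igraph network with >= 1 edge.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @param weighted Use `|rho|` edge weights.
#' @param min_module_size Modules with at least this many nodes count as
#'   sub-modules.
#' @return List: `membership` (named), `modularity`, `n_modules`,
#'   `n_submodules`.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = NULL,
                           weighted = FALSE, min_module_size = 3) {
  if (igraph::ecount(net) < 1) stop("network has no edges", call. = FALSE)
  # NA tells cluster_louvain to ignore weights; modularity needs NULL (the
  # graphs built here never carry a 'weight' attribute, so NULL is unweighted)
  w_cl <- if (weighted) abs(igraph::E(net)$rho) else NA
  w_mod <- if (weighted) abs(igraph::E(net)$rho) else NULL
  cl <- with_seed(seed,
    igraph::cluster_louvain(net, weights = w_cl, resolution = resolution))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  list(membership = memb,
       modularity = igraph::modularity(net, memb, weights = w_mod),
       n_modules = length(sizes),
       n_submodules = sum(sizes >= min_module_size))
}

#' Topological indices of a co-occurrence network
#'
#' Average degree `2E/V`, density `2E/(V(V-1))`, average local clustering
#' coefficient (nodes of degree < 2 contribute 0), diameter and average
#' path length on the largest connected component (its node share is
#' reported), Freeman degree and betweenness centralization (normalized by
#' the star maximum), and Louvain modularity with the sub-module count.
#'
#' @param net igraph network with >= 1 edge.
#' @param seed Seed passed to module detection.
#' @param min_module_size Minimum size for a module to count as a
#'   sub-module.
#' @return Tibble of metrics (one row).
#' @export
topology <- function(net, seed = NULL, min_module_size = 3) {
  V <- igraph::vcount(net); E <- igraph::ecount(net)
  if (E < 1) stop("network has no edges", call. = FALSE)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  mods <- detect_modules(net, seed = seed, min_module_size = min_module_size)
  tibble::tibble(
    n_vertices = V,
    n_edges = E,
    average_degree = 2 * E / V,
    betweenness_centralization =
      igraph::centr_betw(net, directed = FALSE)$centralization,
    average_clustering_coefficient = mean(cc),
    diameter = igraph::diameter(sub, weights = NA),
    average_path_length = igraph::mean_distance(sub, weights = NA),
    density = 2 * E / (V * (V - 1)),
    degree_centralization =
      igraph::centr_degree(net, loops = FALSE)$centralization,
    modularity = mods$modularity,
    n_submodules = mods$n_submodules,
    lcc_fraction = comp$csize[big] / V
  )
}

#' Export a network as a weighted edge list (TSV)
#'
#' Columns: source, target, rho, q, sign.
#'
#' @param net igraph network from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net igraph network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
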