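# Alpha diversity, rarefaction and accumulation curves, abundance-occupancy
# relationships, Bray-Curtis dissimilarity and shared-OTU summaries.

# single-sample estimators; counts is one sample's count vector
alpha_one <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  N <- sum(counts)
  S <- length(counts)
  p <- counts / N
  H <- -sum(p * log(p))
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  chao1 <- S + F1 * (F1 - 1) / (2 * (F2 + 1))          # bias-corrected
  chao1_classic <- if (F2 > 0) S + F1^2 / (2 * F2) else NA_real_
  # ACE, rare/abundant threshold 10
  rare <- counts[counts <= 10]
  S_rare <- length(rare)
  S_abund <- S - S_rare
  N_rare <- sum(rare)
  if (S_rare == 0) {
    ace <- S
  } else {
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      ace <- NA_real_                                   # all rare are singletons
    } else {
      i <- seq_len(10)
      Fi <- vapply(i, function(k) sum(counts == k), numeric(1))
      g2 <- max(S_rare / C_ace * sum(i * (i - 1) * Fi) /
                  (N_rare * (N_rare - 1)) - 1, 0)
      ace <- S_abund + S_rare / C_ace + F1 / C_ace * g2
    }
  }
  D <- sum(p^2)
  c(sobs = S,
    chao1 = chao1, chao1_classic = chao1_classic, ace = ace,
    shannon = H,
    simpson_D = D, simpson = 1 - D,
    pielou = if (S > 1) H / log(S) else NA_real_,
    goods_coverage = 1 - F1 / N)
}

#' Alpha-diversity estimators
#'
#' Computes, per sample: observed richness (Sobs), bias-corrected and classic
#' Chao1, ACE (rare/abundant threshold 10), Shannon H (natural log by
#' default), Simpson's concentration D and diversity 1-D, Pielou's evenness
#' H/ln(Sobs) and Good's coverage 1 - F1/N.
#'
#' @param table OTU table, or a single sample's count vector.
#' @param base Logarithm base for Shannon and Pielou (default `exp(1)`;
#'   use 2 for bits).
#' @return A tibble with one row per sample.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  if (is.null(dim(table))) table <- matrix(table, nrow = 1,
                                           dimnames = list("sample1", NULL))
  out <- t(apply(table, 1, alpha_one))
  out <- tibble::as_tibble(out)
  if (!isTRUE(all.equal(base, exp(1)))) {
    out$shannon <- out$shannon / log(base)
    # pielou is a ratio of logs, base-invariant
  }
  tibble::add_column(out, sample_id = rownames(table), .before = 1)
}

#' Analytic rarefaction curve
#'
#' Expected richness in a without-replacement subsample of size n:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#'
#' @param counts One sample's count vector.
#' @param depths Subsample sizes (each <= total reads).
#' @return Tibble with `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds the total read count", call. = FALSE)
  er <- vapply(depths, function(n) {
    miss <- ifelse(N - counts >= n,
                   exp(lchoose(N - counts, n) - lchoose(N, n)), 0)
    sum(1 - miss)
  }, numeric(1))
  tibble::tibble(depth = depths, expected_richness = er)
}

#' Species accumulation curve
#'
#' Permutation-averaged cumulative richness as samples are added in random
#' order. An explicit matrix of sample orderings can be supplied (rows are
#' orderings), e.g. for exhaustive averaging over all orders of a small
#' table.
#'
#' @param table OTU table with >= 2 samples.
#' @param n_perm Number of random orderings.
#' @param seed Integer seed.
#' @param permutations Optional integer matrix of orderings overriding
#'   `n_perm`.
#' @return Tibble with `n_samples`, `mean_richness`, `sd_richness`.
#' @export
species_accumulation <- function(table, n_perm = 100, seed = NULL,
                                 permutations = NULL) {
  n <- nrow(table)
  if (n < 2) stop("at least 2 samples are required", call. = FALSE)
  pres <- table > 0
  if (is.null(permutations))
    permutations <- with_seed(seed,
      t(replicate(n_perm, sample.int(n))))
  rich <- apply(permutations, 1, function(ord) {
    seen <- rep(FALSE, ncol(table))
    vapply(ord, function(i) {
      seen <<- seen | pres[i, ]
      sum(seen)
    }, numeric(1))
  })                                     # n x n_perm
  tibble::tibble(n_samples = seq_len(n),
                 mean_richness = rowMeans(rich),
                 sd_richness = apply(rich, 1, stats::sd))
}

#' Abundance-occupancy relationship
#'
#' Per-OTU occupancy (number of samples with a detection) against total
#' reads, with Spearman's rank correlation of occupancy on log10 total reads
#' and a two-sided permutation p-value (pairing shuffled).
#'
#' @param table OTU table with >= 3 OTUs.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `otus` (tibble: otu_id, occupancy, total_reads), `rho`,
#'   `p`, and `undefined` flag (constant occupancy or abundance).
#' @export
occupancy_abundance <- function(table, n_perm = 999, seed = NULL) {
  if (ncol(table) < 3) stop("at least 3 OTUs are required", call. = FALSE)
  occ <- colSums(table > 0)
  tot <- colSums(table)
  keep <- tot > 0
  occ <- occ[keep]; tot <- tot[keep]
  otus <- tibble::tibble(otu_id = colnames(table)[keep],
                         occupancy = occ, total_reads = tot)
  x <- log10(tot)
  if (stats::sd(occ) == 0 || stats::sd(x) == 0)
    return(list(otus = otus, rho = NA_real_, p = NA_real_, undefined = TRUE))
  rho <- stats::cor(x, occ, method = "spearman")
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    abs(stats::cor(x, sample(occ), method = "spearman")), numeric(1)))
  p <- perm_pvalue(abs(rho), perm, exhaustive = FALSE)
  list(otus = otus, rho = rho, p = p, undefined = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y)`, in `[0, 1]`.
#'
#' @param table OTU table or relative-abundance matrix with positive row sums.
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  if (any(rowSums(table) == 0)) stop("all-zero sample row", call. = FALSE)
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Shared-OTU counts over a group lattice
#'
#' Counts OTUs by the exact combination of groups they occur in
#' (presence/absence), i.e. the exclusive regions of a Venn diagram.
#'
#' @param table OTU table.
#' @param grouping Group label per sample (named by sample id or in row
#'   order).
#' @return Tibble with `region` (group names joined by `&`) and `n_otus`;
#'   regions with zero OTUs for observed combinations are included only if
#'   observed.
#' @export
shared_otu_counts <- function(table, grouping) {
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(table))
    stop("one group label per sample is required", call. = FALSE)
  if (anyNA(grouping)) stop("unknown group label (NA)", call. = FALSE)
  groups <- sort(unique(grouping))
  if (length(groups) < 2) stop("at least 2 groups are required", call. = FALSE)
  pres <- vapply(groups, function(g)
    colSums(table[grouping == g, , drop = FALSE]) > 0,
    logical(ncol(table)))                       # OTU x group
  member <- apply(pres, 1, function(z)
    paste(groups[z], collapse = "&"))
  member <- member[member != ""]                # OTUs absent everywhere
  tab <- table(member)
  tibble::tibble(region = names(tab), n_otus = as.integer(tab))
}
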