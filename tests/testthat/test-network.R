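test_that("the correlation screen finds exact rank relationships", {
  set.seed(71)
  x <- c(3, 7, 1, 9, 4, 6)
  tab <- cbind(a = x, b = 2 * x + 1, c = 100 - x^3, d = rpois(6, 20) + 1)
  rownames(tab) <- paste0("s", 1:6)
  cors <- correlation_screen(tab, min_prevalence = 3)
  get <- function(i, j) cors$rho[(cors$otu1 == i & cors$otu2 == j) |
                                 (cors$otu1 == j & cors$otu2 == i)]
  expect_equal(get("a", "b"), 1)
  expect_equal(get("a", "c"), -1)
  # low-prevalence OTUs are dropped
  tab2 <- cbind(tab, e = c(0, 0, 0, 0, 5, 0))
  cors2 <- correlation_screen(tab2, min_prevalence = 3)
  expect_false("e" %in% c(cors2$otu1, cors2$otu2))
  # constant OTUs are excluded with a count
  tab3 <- cbind(tab, f = rep(4, 6))
  cors3 <- correlation_screen(tab3, min_prevalence = 3)
  expect_equal(attr(cors3, "n_excluded_constant"), 1L)
})

test_that("exact Spearman permutation p at n = 6 matches cor.test's exact value", {
  set.seed(72)
  x <- c(12, 5, 9, 21, 2, 15)
  y <- c(3, 8, 1, 14, 6, 11)
  tab <- cbind(a = x, b = y)
  rownames(tab) <- paste0("s", 1:6)
  cors <- correlation_screen(tab, min_prevalence = 3, p_method = "exact")
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE,
                         alternative = "two.sided")
  expect_equal(cors$p, unname(ref$p.value), tolerance = 1e-12)
  expect_error(correlation_screen(random_table(10, 4), p_method = "exact"),
               "n <= 9")
})

test_that("t-approximation p-values agree with cor.test", {
  set.seed(73)
  tab <- random_table(15, 6) + 1
  cors <- correlation_screen(tab, min_prevalence = 3, p_method = "t")
  for (k in seq_len(nrow(cors))) {
    ref <- suppressWarnings(
      stats::cor.test(tab[, cors$otu1[k]], tab[, cors$otu2[k]],
                      method = "spearman", exact = FALSE))
    expect_equal(cors$p[k], unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(storey_qvalues(p, lambda = NULL), rep(0.04, 4))
  set.seed(74)
  pr <- runif(50)
  expect_equal(storey_qvalues(pr, lambda = NULL),
               stats::p.adjust(pr, "BH"), tolerance = 1e-12)
  # pi0 shrinks q-values, never below pi0 * BH
  q <- storey_qvalues(pr, lambda = 0.5)
  pi0 <- min(1, mean(pr > 0.5) / 0.5)
  expect_equal(q, pi0 * stats::p.adjust(pr, "BH"), tolerance = 1e-12)
  expect_lte(storey_qvalues(0.03), 0.03)
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("network thresholds apply to both correlation strength and q-value", {
  cors <- tibble::tibble(
    otu1 = c("a", "a", "b"), otu2 = c("b", "c", "c"),
    rho = c(0.61, 0.61, 0.59), p = c(0.001, 0.02, 0.0001),
    q = c(0.01, 0.06, 0.001))
  net <- build_network(cors)
  el <- igraph::as_data_frame(net)
  expect_equal(nrow(el), 1)
  expect_setequal(unlist(el[1, c("from", "to")]), c("a", "b"))
  expect_equal(el$sign, "positive")
  # nothing surviving: empty network with a warning, not an error
  expect_warning(net0 <- build_network(cors, r_cut = 0.99), "no correlation")
  expect_equal(igraph::vcount(net0), 0)
  expect_error(build_network(cors[, 1:4]), "q-values")
})

test_that("co-varying abundances produce all-positive edge signs", {
  set.seed(75)
  base <- rpois(12, 30) + 1
  tab <- sapply(1:6, function(i) base + rpois(12, 2))
  colnames(tab) <- paste0("o", 1:6); rownames(tab) <- paste0("s", 1:12)
  cors <- correlation_screen(tab, min_prevalence = 3, seed = 5)
  cors$q <- storey_qvalues(cors$p)
  net <- suppressWarnings(build_network(cors, r_cut = 0.6, q_cut = 0.05))
  if (igraph::ecount(net) > 0)
    expect_true(all(igraph::E(net)$sign == "positive"))
})

test_that("topology metrics match closed forms on canonical graphs", {
  # complete graph K4
  k4 <- toy_network(t(utils::combn(4, 2)), 4)
  m <- topology(k4, seed = 1)
  expect_equal(m$average_degree, 3)
  expect_equal(m$density, 1)
  expect_equal(m$average_clustering_coefficient, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$average_path_length, 1)
  expect_equal(m$degree_centralization, 0)
  # path A-B-C-D
  p4 <- toy_network(cbind(1:3, 2:4), 4)
  mp <- topology(p4, seed = 1)
  expect_equal(mp$average_degree, 1.5)
  expect_equal(mp$diameter, 3)
  expect_equal(mp$average_path_length, 10 / 6)
  expect_equal(mp$average_clustering_coefficient, 0)
  # star: hub plus 4 leaves maximizes both centralizations
  star <- toy_network(cbind(1, 2:5), 5)
  ms <- topology(star, seed = 1)
  expect_equal(ms$degree_centralization, 1)
  expect_equal(ms$betweenness_centralization, 1)
})

test_that("topology metrics match brute force on small random graphs", {
  set.seed(76)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    all_e <- t(utils::combn(n, 2))
    edges <- all_e[runif(nrow(all_e)) < 0.45, , drop = FALSE]
    if (nrow(edges) < 2) next
    # restrict to one connected component for path-based metrics
    g <- toy_network(edges, n)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      keep_v <- which(comp$membership == which.max(comp$csize))
      edges <- edges[edges[, 1] %in% keep_v & edges[, 2] %in% keep_v,
                     , drop = FALSE]
      relab <- match(seq_len(n), keep_v)
      edges <- cbind(relab[edges[, 1]], relab[edges[, 2]])
      n <- length(keep_v)
      if (nrow(edges) < 2 || n < 4) next
      g <- toy_network(edges, n)
    }
    want <- bf_metrics(edges, n)
    got <- topology(g, seed = 1)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                   info = paste("metric", nm, "rep", i))
  }
})

test_that("module detection splits bridged cliques with the hand-computed Q", {
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  net <- toy_network(edges, 8)
  mods <- detect_modules(net, seed = 1)
  expect_equal(mods$n_modules, 2)
  memb <- mods$membership
  expect_true(all(memb[1:4] == memb[1]) && all(memb[5:8] == memb[5]))
  expect_true(memb[1] != memb[5])
  q_hand <- bf_modularity(edges, 8, c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(mods$modularity, q_hand, tolerance = 1e-12)
  expect_equal(q_hand, 12 / 13 - 0.5, tolerance = 1e-12)
  # single clique: trivial partition, Q about 0
  k5 <- toy_network(t(utils::combn(5, 2)), 5)
  mods5 <- detect_modules(k5, seed = 1)
  expect_equal(mods5$n_modules, 1)
  expect_lte(abs(mods5$modularity), 1e-12)
  # determinism
  mods_b <- detect_modules(net, seed = 1)
  expect_identical(mods$membership, mods_b$membership)
})

test_that("network construction is invariant to OTU input order", {
  set.seed(77)
  tab <- random_table(10, 12) + 1
  cors <- correlation_screen(tab, min_prevalence = 3, p_method = "t")
  cors$q <- storey_qvalues(cors$p)
  net1 <- suppressWarnings(build_network(cors, r_cut = 0.3, q_cut = 0.5))
  perm <- sample(ncol(tab))
  cors2 <- correlation_screen(tab[, perm], min_prevalence = 3, p_method = "t")
  cors2$q <- storey_qvalues(cors2$p)
  net2 <- suppressWarnings(build_network(cors2, r_cut = 0.3, q_cut = 0.5))
  e1 <- igraph::as_data_frame(net1)
  e2 <- igraph::as_data_frame(net2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(e1), key(e2))
})

test_that("networks export to edge-list TSV and GraphML", {
  net <- toy_network(cbind(1:3, 2:4), 4)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  export_edgelist(net, p1)
  el <- utils::read.table(p1, header = TRUE, sep = "\t")
  expect_identical(names(el)[1:2], c("source", "target"))
  expect_equal(nrow(el), 3)
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, p2)
  expect_true(any(grepl("graphml", readLines(p2, n = 3), ignore.case = TRUE)))
})
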