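test_that("alpha diversity is exact on an even community", {
  a <- alpha_diversity(c(4, 4, 4))
  expect_equal(a$sobs, 3)
  expect_equal(a$shannon, log(3))
  expect_equal(a$pielou, 1)
  expect_equal(a$simpson_D, 1 / 3)
  expect_equal(a$chao1, 3)
})

test_that("alpha diversity matches hand-derived values on [5,3,1,1]", {
  a <- alpha_diversity(c(5, 3, 1, 1))
  p <- c(5, 3, 1, 1) / 10
  expect_equal(a$shannon, -sum(p * log(p)), tolerance = 1e-10)
  expect_equal(a$shannon, 1.16826, tolerance = 1e-4)
  expect_equal(a$simpson, 0.64, tolerance = 1e-10)
  expect_equal(a$pielou, a$shannon / log(4), tolerance = 1e-10)
  expect_equal(a$pielou, 0.84270, tolerance = 1e-4)
  # F1 = 2, F2 = 0: bias-corrected Chao1 = 4 + 2*1/2 = 5
  expect_equal(a$chao1, 5)
  expect_equal(a$goods_coverage, 0.8)
})

test_that("both Chao1 variants are reported", {
  # S = 5, F1 = 2, F2 = 1
  v <- c(1, 1, 2, 5, 9)
  a <- alpha_diversity(v)
  expect_equal(a$chao1_classic, 5 + 2^2 / (2 * 1))
  expect_equal(a$chao1, 5 + 2 * 1 / (2 * 2))
  expect_gte(a$chao1, a$sobs)   # equality iff F1 = 0
  a0 <- alpha_diversity(c(5, 9, 22))
  expect_equal(a0$chao1, a0$sobs)
})

test_that("estimators agree with vegan on random samples", {
  set.seed(21)
  for (i in 1:5) {
    v <- rpois(60, 3)
    v[sample(60, 20)] <- 0
    v <- v[v >= 0]
    if (sum(v) == 0 || sum(v > 0) < 3) next
    a <- alpha_diversity(v)
    est <- vegan::estimateR(v)
    expect_equal(a$sobs, unname(est["S.obs"]))
    expect_equal(a$chao1, unname(est["S.chao1"]), tolerance = 1e-8)
    if (is.finite(est["S.ACE"]))
      expect_equal(a$ace, unname(est["S.ACE"]), tolerance = 1e-8)
    expect_equal(a$shannon, unname(vegan::diversity(v, "shannon")))
    expect_equal(a$simpson, unname(vegan::diversity(v, "simpson")))
  }
})

test_that("Shannon can be reported in bits without changing evenness", {
  a_nats <- alpha_diversity(c(5, 3, 1, 1))
  a_bits <- alpha_diversity(c(5, 3, 1, 1), base = 2)
  expect_equal(a_bits$shannon, a_nats$shannon / log(2))
  expect_equal(a_bits$pielou, a_nats$pielou)
})

test_that("analytic rarefaction matches binomial-coefficient arithmetic", {
  rc <- rarefaction_curve(c(2, 2), 2)
  expect_equal(rc$expected_richness, 2 * (1 - 1 / 6))   # 5/3
  v <- c(10, 5, 2, 1)
  expect_equal(rarefaction_curve(v, sum(v))$expected_richness, 4)
  expect_equal(rarefaction_curve(v, 1)$expected_richness, 1)
  expect_error(rarefaction_curve(v, sum(v) + 1), "exceeds")
  # agreement with vegan's analytic form
  expect_equal(rarefaction_curve(v, 7)$expected_richness,
               unname(c(vegan::rarefy(v, 7))), tolerance = 1e-10)
})

test_that("analytic rarefaction matches Monte-Carlo subsampling", {
  v <- c(40, 12, 5, 3, 2, 1, 1)
  n <- 20
  n_rep <- 3000
  tab <- matrix(rep(v, each = n_rep), n_rep, length(v),
                dimnames = list(paste0("s", 1:n_rep),
                                paste0("o", seq_along(v))))
  r <- rarefy(tab, n, seed = 5)
  rich <- rowSums(r > 0)
  se <- stats::sd(rich) / sqrt(n_rep)
  expect_lt(abs(mean(rich) - rarefaction_curve(v, n)$expected_richness),
            3 * se)
})

test_that("species accumulation handles degenerate and exhaustive cases", {
  # identical samples: flat after the first
  tab <- matrix(rep(c(3, 2, 0, 1), each = 4), 4, 4,
                dimnames = list(paste0("s", 1:4), paste0("o", 1:4)))
  sac <- species_accumulation(tab, n_perm = 10, seed = 1)
  expect_true(all(sac$mean_richness == 3))
  # disjoint samples: cumulative sum of per-sample richness
  tab2 <- otu_table(diag(c(5, 5, 5)) ,
                    sample_ids = paste0("s", 1:3), otu_ids = paste0("o", 1:3))
  sac2 <- species_accumulation(tab2, n_perm = 5, seed = 1)
  expect_equal(sac2$mean_richness, c(1, 2, 3))
  # exhaustive orderings equal the same set passed as explicit permutations
  tab3 <- random_table(3, 8)
  perms <- do.call(rbind, lapply(
    list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
    identity))
  s_a <- species_accumulation(tab3, permutations = perms)
  s_b <- species_accumulation(tab3, permutations = perms[sample(6), ])
  expect_equal(s_a$mean_richness, s_b$mean_richness)
  # monotone non-decreasing mean curve
  tab4 <- random_table(6, 30)
  sac4 <- species_accumulation(tab4, n_perm = 30, seed = 2)
  expect_true(all(diff(sac4$mean_richness) >= 0))
})

test_that("abundance-occupancy relationships are detected and calibrated", {
  # perfectly monotone pairing
  tab <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("o", 1:6)))
  for (j in 1:6) tab[seq_len(j), j] <- 10 * j
  oa <- occupancy_abundance(tab, n_perm = 99, seed = 1)
  expect_equal(oa$rho, 1)
  expect_equal(unname(oa$otus$occupancy), 1:6)
  # constant occupancy flagged
  tabc <- matrix(c(1, 2, 4, 8, 16, 32), 1, 6,
                 dimnames = list("s1", paste0("o", 1:6)))
  tabc <- rbind(s1 = tabc[1, ], s2 = tabc[1, ])
  oac <- occupancy_abundance(tabc, n_perm = 9, seed = 1)
  expect_true(oac$undefined)
})

test_that("Bray-Curtis has its closed form and semimetric properties", {
  x <- c(3, 0, 1); y <- c(1, 2, 0)
  tab <- rbind(a = x, b = y)
  colnames(tab) <- paste0("o", 1:3)
  bc <- bray_curtis(tab)
  expect_equal(bc["a", "b"], 5 / 7)   # 1 - 2*min-sum/(4+3) = 1 - 2/7
  expect_equal(unname(diag(bc)), c(0, 0))
  tab2 <- rbind(a = c(5, 5, 0), b = c(5, 5, 0), c = c(0, 0, 7))
  colnames(tab2) <- paste0("o", 1:3)
  bc2 <- bray_curtis(tab2)
  expect_equal(bc2["a", "b"], 0)
  expect_equal(bc2["a", "c"], 1)
  # invariant to joint rescaling of a pair of rows
  tab3 <- rbind(a = c(3, 1, 2), b = c(1, 4, 0))
  tab4 <- tab3 * 10
  colnames(tab3) <- colnames(tab4) <- paste0("o", 1:3)
  expect_equal(bray_curtis(tab3)[1, 2], bray_curtis(tab4)[1, 2])
  # symmetry and range on random tables
  tab5 <- random_table(6, 20)
  tab5 <- tab5[rowSums(tab5) > 0, ]
  b5 <- bray_curtis(tab5)
  expect_equal(b5, t(b5))
  expect_true(all(b5 >= 0 & b5 <= 1))
})

test_that("shared-OTU counts match exhaustive set arithmetic", {
  tab <- matrix(c(1, 1, 0, 0, 0, 0,
                  1, 0, 1, 0, 1, 0,
                  0, 0, 1, 1, 1, 0,
                  1, 1, 1, 0, 0, 0), 4, 6, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), paste0("o", 1:6)))
  grouping <- c("A", "A", "B", "C")
  out <- shared_otu_counts(tab, grouping)
  # o1: A,B? s3 has o1? row3 = (0,0,1,1,1,0) -> o1 absent; o1 in A (s1,s2), C (s4)
  expect_equal(out$n_otus[out$region == "A&C"], 2)       # o1, o2
  expect_equal(out$n_otus[out$region == "A&B&C"], 1)     # o3
  expect_equal(out$n_otus[out$region == "B"], 1)         # o4
  expect_equal(out$n_otus[out$region == "A&B"], 1)       # o5
  expect_false("o6" %in% unlist(strsplit(out$region, "&")))
  # identical groups share everything
  tab2 <- rbind(tab[1:2, ], tab[1:2, ])
  rownames(tab2) <- paste0("s", 1:4)
  out2 <- shared_otu_counts(tab2, c("X", "X", "Y", "Y"))
  expect_identical(out2$region, "X&Y")
  # disjoint groups share nothing
  tab3 <- otu_table(rbind(c(2L, 0L), c(0L, 3L)),
                    sample_ids = c("s1", "s2"), otu_ids = c("o1", "o2"))
  out3 <- shared_otu_counts(tab3, c("P", "Q"))
  expect_false(any(grepl("&", out3$region)))
})
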