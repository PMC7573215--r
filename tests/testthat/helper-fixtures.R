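# Small fixtures and independent oracles used across test files.

# random integer OTU table with dimnames
random_table <- function(n_samples, n_otus, max_count = 50) {
  m <- matrix(sample.int(max_count + 1, n_samples * n_otus, replace = TRUE) - 1L,
              n_samples, n_otus)
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("Otu", seq_len(n_otus)))
  m
}

# brute-force abundance-category classifier: literal six predicates
brute_classify <- function(v, rare = 0.001, abund = 0.01) {
  Mn <- min(v); Mx <- max(v)
  if (Mn >= abund) return("AT")
  if (Mn > rare && Mx >= abund) return("CAT")
  if (Mn > rare && Mx < abund) return("MT")
  if (Mn <= rare && Mx >= abund) return("CRAT")
  if (Mn <= rare && Mx > rare && Mx < abund) return("CRT")
  if (Mx <= rare) return("RT")
  NA_character_
}

# ANOSIM R computed directly from the definition (independent of package code)
oracle_anosim_R <- function(D, groups) {
  n <- nrow(D)
  r <- rank(D[lower.tri(D)])
  between <- outer(groups, groups, "!=")[lower.tri(D)]
  (mean(r[between]) - mean(r[!between])) / (n * (n - 1) / 4)
}

# independent enumeration of all permutations of 1..n (test-side oracle)
enumerate_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- enumerate_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix((seq_len(n))[-i][sub], nrow(sub), n - 1))))
}
all_perms_5 <- function() enumerate_perms(5)

# all distinct two-group label assignments of sizes (k, n - k)
two_group_assignments <- function(n, k) {
  pos <- utils::combn(n, k)
  lapply(seq_len(ncol(pos)), function(j) {
    g <- rep("b", n); g[pos[, j]] <- "a"; g
  })
}
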