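#!/usr/bin/env Rscript
# Ordination of the mixed fixture: NMDS of Bray-Curtis distances on
# Hellinger-transformed counts, PCA of the square-root-transformed
# environmental table, and the Procrustes/PROTEST comparison of the two
# configurations.

library(otuassembly)

seed <- 20260926
tab <- read_otu_table("results/data/mixed.shared", format = "shared")
tab <- filter_artifacts(tab)
samples <- sample_frame(read.table("results/data/mixed_samples.tsv",
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE))
samples <- samples[match(rownames(tab), samples$sample_id), ]

bc <- bray_curtis(hellinger(tab))
nm <- nmds(bc, k = 2, seed = seed)
cat(sprintf("NMDS stress = %.4f (converged: %s)\n", nm$stress, nm$converged))
write.table(data.frame(sample_id = rownames(nm$scores), nm$scores,
                       month = samples$month, habitat = samples$habitat),
            "results/nmds_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

env <- as.matrix(samples[, intersect(env_variables, names(samples))])
env_pca <- pca(sqrt(env), scale. = TRUE)
cat(sprintf("environmental PCA: first two axes explain %.1f%% of variance\n",
            100 * sum(env_pca$proportion[1:2])))

comm <- pcoa(bray_curtis(tab))$scores
pr <- procrustes(env_pca$scores, comm, symmetric = TRUE)
pt <- protest(env_pca$scores, comm, n_perm = 999, seed = seed)
cat(sprintf("Procrustes M2 = %.3f, PROTEST correlation = %.3f, p = %.4f\n",
            pr$M2, pt$statistic, pt$p))
write.table(data.frame(M2 = pr$M2, correlation = pt$statistic, p = pt$p,
                       mean_residual = mean(pr$residuals)),
            "results/procrustes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
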