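#!/usr/bin/env Rscript
# Classify OTUs of each fixture into the six abundance/rarity categories
# (0.1% and 1% relative-abundance cuts) and summarize the sub-communities.

library(otuassembly)

for (mode in c("neutral", "niche", "mixed")) {
  tab <- read_otu_table(file.path("results/data", paste0(mode, ".shared")),
                        format = "shared")
  tab <- filter_artifacts(tab)
  cls <- classify_otus(to_relative(tab))
  summ <- category_summary(cls, tab)
  write.table(as.data.frame(cls),
              file.path("results", paste0("classification_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(summ),
              file.path("results",
                        paste0("classification_summary_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s:\n", mode))
  print(as.data.frame(summ), digits = 3)
  ubiquitous <- sum(cls$occupancy == nrow(tab))
  cat(sprintf("  OTUs present in all %d samples: %d%s\n\n", nrow(tab),
              ubiquitous,
              if (ubiquitous == 0) " (AT/CAT/MT necessarily empty)" else ""))
}
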