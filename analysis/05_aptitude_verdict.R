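#!/usr/bin/env Rscript
# Stage 5: productive-aptitude classification.
#
# Classifies the population mean index vector: each aptitude-bearing index
# gets a dairy/beef/dual label from its threshold rule, and the overall
# verdict is the majority vote of the nine voters (CEI is descriptive only).

library(zoometry)

idx <- read.csv("results/index_table.csv")
mean_idx <- colMeans(idx[, index_codes()])
profile <- classify_indices(mean_idx)
verdict <- overall_verdict(profile)

dir.create("results/aptitude", showWarnings = FALSE, recursive = TRUE)
write.csv(as.data.frame(profile), "results/aptitude/classification.csv",
          row.names = FALSE, quote = FALSE)
writeLines(verdict, "results/aptitude/verdict.txt")

cat("Per-index classification of the population means:\n")
print(as.data.frame(profile)[, c("index", "value", "label", "block", "tag")],
      row.names = FALSE, digits = 4)
cat("\nOverall verdict:", verdict, "\n")
cat("Wrote results/aptitude/classification.csv and verdict.txt\n")
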