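#!/usr/bin/env Rscript
# Randomness indices (CB, IB, RNG) of the simulated digit-task output.

suppressPackageStartupMessages(library(hrvtriad))

rows <- lapply(c("reactive", "blunted"), function(profile) {
  s <- read_digit_sequence(sprintf("results/digits_%s.txt", profile))
  data.frame(subject = profile, t(randomness_indices(s)))
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/randomness_indices.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat("For reference, a uniform random sequence gives CB 0.18 and IB 0.05;\n",
    "100-digit human output typically concentrates digrams (higher RNG).\n")
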