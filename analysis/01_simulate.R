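#!/usr/bin/env Rscript
# Step 1 — simulate one FAERS-dialect quarter with the study-like default
# design: two levodopa/DCI combination products with planted
# motor-complication associations, concomitant anti-parkinsonian drugs,
# duplicated case versions, and full demographics. Writes the six
# dollar-delimited tables plus the ground-truth sidecars.

suppressMessages(library(faersignal))

seed <- 20240
out_dir <- "results/synthetic_faers"
cfg <- synthetic_config(n_cases = 20000)

g <- generate_synthetic_faers(cfg, seed = seed, dir = out_dir,
                              quarter = "24Q1")

write.table(g$truth$eligibility, file.path(out_dir, "ground_truth_eligibility.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(g$truth$pair_counts, file.path(out_dir, "ground_truth_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", g$truth$n_unique, "unique cases ->", out_dir, "\n")
cat("Emitted rows: DEMO", nrow(g$raw$demo), "| DRUG", nrow(g$raw$drug),
    "| REAC", nrow(g$raw$reac), "\n")
cat("Planted associations:\n")
print(as.data.frame(g$truth$pair_counts[, c("drug_pattern", "pt", "lambda",
                                            "a", "b", "c", "d")]),
      row.names = FALSE)
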