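#!/usr/bin/env Rscript
# Step 5 — final report assembly: cross-drug comparisons per endpoint
# (CI overlap and 2x2 chi-square/Fisher p), the forest plot of RORs, and a
# run manifest. Equivalent to run_pipeline(), kept step-wise here so each
# artifact is inspectable.

suppressMessages(library(faersignal))

scr_dir <- "results/screening"
out_dir <- "results/report"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cases <- read_case_store(file.path(scr_dir, "cases_dedup.tsv"))
scr <- run_cascade(cases)
sig <- disproportionality_table(scr$cohorts, cases)

fd <- forest_data(sig)
write.table(fd, file.path(out_dir, "forest_data.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ggplot2::ggsave(file.path(out_dir, "forest.pdf"), plot_forest(fd),
                width = 7, height = 4)

cat("Cross-drug comparison per endpoint (BSZ vs CD):\n")
print(as.data.frame(fd[, c("drug", "endpoint", "point", "low", "high",
                           "ci_overlap", "p_vs_other",
                           "significant_vs_other")]), row.names = FALSE)

jsonlite::write_json(list(
  n_cases = n_cases(cases),
  cohort_sizes = lapply(scr$cohorts, function(co) n_cases(co$cases)),
  n_signals = sum(sig$signal),
  r_version = as.character(getRversion()),
  package_version = as.character(utils::packageVersion("faersignal"))),
  file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

cat("\nWrote forest data, figure and manifest to", out_dir, "\n")
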