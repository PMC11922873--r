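#!/usr/bin/env Rscript
# Step 2 — read the simulated quarter back through the FAERS reader,
# deduplicate case versions, and run the screening cascade (suspect-drug
# match, oral route, Parkinson's indication with dementia/psychosis
# exclusions, motor-complication SOC restriction) for the benserazide and
# carbidopa cohorts.

suppressMessages(library(faersignal))

in_dir <- "results/synthetic_faers"
out_dir <- "results/screening"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

raw <- read_quarter(faers_quarter_paths(in_dir, "24Q1"))
cases <- deduplicate(raw)
cat("Read", nrow(raw$demo), "DEMO rows ->", n_cases(cases),
    "unique cases after version deduplication\n")

scr <- run_cascade(cases)
for (lab in names(scr$cohorts)) {
  co <- scr$cohorts[[lab]]
  cat("\nCohort", lab, "—", n_cases(co$cases), "cases\n")
  print(as.data.frame(co$trace), row.names = FALSE)
  write.table(co$trace, file.path(out_dir, sprintf("trace_%s.tsv", lab)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(co$cases$demo$case_id,
             file.path(out_dir, sprintf("cohort_%s_case_ids.txt", lab)))
}
write.table(scr$trace, file.path(out_dir, "trace_combined.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# screened case store for the downstream steps
write_case_store(cases, file.path(out_dir, "cases_dedup.tsv"))
cat("\nWrote traces, cohort id lists and the deduplicated case store to",
    out_dir, "\n")
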