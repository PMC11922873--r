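#!/usr/bin/env Rscript
# Step 3 — descriptive analysis of the screened cohorts: demographics and
# serious outcomes (with the summed-outcome-code denominator), top
# concomitant anti-parkinsonian drugs, endpoint frequencies with AE-total
# denominators, female-vs-male endpoint comparisons, and per-quarter
# report counts.

suppressMessages(library(faersignal))

scr_dir <- "results/screening"
out_dir <- "results/descriptive"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cases <- read_case_store(file.path(scr_dir, "cases_dedup.tsv"))
scr <- run_cascade(cases)

w <- function(d, name) write.table(d, file.path(out_dir, name), sep = "\t",
                                   quote = FALSE, row.names = FALSE, na = "")

for (lab in names(scr$cohorts)) {
  co <- scr$cohorts[[lab]]
  w(demographics_table(co), sprintf("demographics_%s.tsv", lab))
  w(concomitant_ranking(co), sprintf("concomitant_top5_%s.tsv", lab))
  w(quarter_counts(co), sprintf("quarter_counts_%s.tsv", lab))
  cat("Top concomitant anti-parkinsonian drugs,", lab, "\n")
  print(as.data.frame(concomitant_ranking(co)), row.names = FALSE)
}

freq <- endpoint_frequency_table(scr$cohorts)
w(freq, "endpoint_frequencies.tsv")
cat("\nEndpoint frequencies (Total rows, % of all cohort AEs):\n")
print(as.data.frame(freq[freq$drug == "Total", ]), row.names = FALSE)

sex_tests <- endpoint_sex_tests(scr$cohorts)
w(sex_tests, "endpoint_sex_tests.tsv")
cat("\nFemale-vs-male endpoint comparisons:\n")
print(as.data.frame(sex_tests[, c("drug", "endpoint", "method", "p_value",
                                  "stars")]), row.names = FALSE)
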