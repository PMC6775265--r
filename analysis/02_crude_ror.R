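#!/usr/bin/env Rscript

# Stage 2 — deduplicate, define the event, and screen for signals.
#
# Reads the canonical snapshot from stage 1, keeps the most recent version
# of every case, builds the hemorrhage event definition as the SMQ-by-SOC
# term intersection, and computes crude and age-stratified reporting odds
# ratios with the signal criterion (CI lower limit > 1 and at least two
# exposed cases).

suppressPackageStartupMessages(library(pvror))
suppressPackageStartupMessages(library(readr))

in_dir <- "results/simulated"
stopifnot(dir.exists(file.path(in_dir, "data")))  # run 01_simulate.R first

rs <- read_canonical(file.path(in_dir, "data"))
message("read ", n_reports(rs), " report versions")

rs <- deduplicate(rs)
message("after deduplication: ", n_reports(rs), " reports (",
        rs$provenance$dedup_removed, " removed)")

smq <- load_term_table(file.path(in_dir, "term_tables.csv"),
                       set_name = "smq_hemorrhage")
soc <- load_term_table(file.path(in_dir, "term_tables.csv"),
                       set_name = "soc_target")
def <- define_event(smq, soc, name = "hemorrhage")
print(def)

cases <- flag_cases(rs, def)
message(sum(cases), " case reports (",
        sprintf("%.2f%%", 100 * mean(cases)), ")")

drugs <- c("apixaban", "rivaroxaban", "edoxaban", "dabigatran")
ror <- ror_table(rs, drugs, cases, event_name = "hemorrhage")
write_csv(ror, "results/ror_crude_stratified.csv", na = "")

crude <- ror[ror$stratum == "all", ]
message("crude RORs (all ages):")
for (i in seq_len(nrow(crude))) {
  message(sprintf("  %-12s %6.2f (%.2f-%.2f)%s", crude$drug[i], crude$ror[i],
                  crude$ci_low[i], crude$ci_high[i],
                  ifelse(crude$signal[i], "  SIGNAL", "")))
}
message("table written to results/ror_crude_stratified.csv")
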