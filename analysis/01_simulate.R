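#!/usr/bin/env Rscript

# Stage 1 — simulate a spontaneous-reporting snapshot.
#
# Draws a four-drug anticoagulant scenario with known effects (strong drug
# main effects, female-by-drug interactions of 1.5, an elderly and a female
# main effect), demographic missingness and 10% duplicate case versions,
# then writes it in the canonical CSV schema together with the term tables
# and the ground-truth ledger.

suppressPackageStartupMessages(library(pvror))
suppressPackageStartupMessages(library(readr))

n <- 50000
seed <- 2024
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cf <- scenario_preset("paper_like", n_reports = n, seed = seed)
sim <- generate_reports(cf)

write_canonical(sim$report_set, file.path(out, "data"))
write_csv(sim$ledger$term_tables, file.path(out, "term_tables.csv"))
write_csv(sim$ledger$truth, file.path(out, "ground_truth.csv"))
write_csv(sim$ledger$duplicate_map, file.path(out, "duplicate_map.csv"))

message("simulated ", n_reports(sim$report_set), " report versions (",
        nrow(sim$ledger$duplicate_map), " injected duplicates) with ",
        sum(sim$ledger$truth$event), " true event cases")
message("true odds ratios: ",
        paste(names(cf$event_model$drug),
              sprintf("%.1f", exp(cf$event_model$drug)),
              sep = "=", collapse = ", "))
message("canonical data, term tables and ledger written under ", out)
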