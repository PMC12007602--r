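#!/usr/bin/env Rscript

# Step 2: per-lead iERP statistics.
#
# Reads the epoched recording and lead table from step 1, applies the
# consecutive-bin responsiveness criterion per emotional condition, then
# the Condition-by-Time selectivity ANOVA (gated on responsiveness) with
# peak-latency classification, and writes the per-lead results table.

suppressPackageStartupMessages(library(faceseeg))

dataset <- "results/dataset"
leads <- read_leads_table(file.path(dataset, "leads.tsv"))
rec <- read_epochs(file.path(dataset, "epochs"))
cfg <- analysis_config()

res <- analyze_leads(rec, leads, cfg)
utils::write.table(res, "results/lead_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

n <- nrow(res)
message(sprintf("%d grey-matter leads analysed", n))
message(sprintf("responsive (either emotional condition): %d (%.0f%%)",
                sum(res$responsive_any), 100 * mean(res$responsive_any)))
message(sprintf("selective smiling vs neutral: %d of %d responsive",
                sum(res$selective_smiling_vs_neutral),
                sum(res$responsive_any)))
message(sprintf("selective fearful vs neutral: %d of %d responsive",
                sum(res$selective_fearful_vs_neutral),
                sum(res$responsive_any)))
cls <- table(res$peak_class_smiling_vs_neutral)
message("peak latency classes (smiling vs neutral): ",
        paste(sprintf("%s ms: %d", names(cls), cls), collapse = ", "))
message("wrote results/lead_results.tsv")
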