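#!/usr/bin/env Rscript

# Step 4: parcellation-level regional summaries.
#
# Labels each lead by the majority region among its seven mesh nodes,
# counts significant leads per region and hemisphere, applies the
# selection rule (>= 10% of recording leads, on >= 4 significant leads)
# and tests hemispheric lateralization of the pooled selectivity counts
# with a chi-squared test.

suppressPackageStartupMessages(library(faceseeg))

dataset <- "results/dataset"
mesh <- read_mesh(file.path(dataset, "mesh.off"))
leads <- read_leads_table(file.path(dataset, "leads.tsv"))
assignment <- utils::read.table(file.path(dataset, "lead_nodes.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
parc <- read_parcellation(file.path(dataset, "parcellation.tsv"),
                          n_nodes = nrow(mesh$node_positions))
res <- utils::read.table("results/lead_results.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
cfg <- analysis_config()

labelled <- assign_regions(grey_matter_leads(leads), mesh, assignment, parc)

tables <- list()
for (ct in c("smiling_vs_neutral", "fearful_vs_neutral")) {
  sig <- stats::setNames(res[[paste0("selective_", ct)]], res$lead_id)
  summ <- regional_summary(labelled, sig, cfg)
  summ$contrast <- ct
  tables[[ct]] <- summ
  message(sprintf("%s: %d region-hemisphere cells, %d selected",
                  ct, nrow(summ), sum(summ$selected)))
  # pooled lateralization across regions
  byside <- tapply(sig[labelled$lead_id], labelled$hemisphere, sum)
  tot <- table(labelled$hemisphere)
  if (all(c("L", "R") %in% names(tot))) {
    lt <- chi2_lateralization(c(byside[["L"]], tot[["L"]]),
                              c(byside[["R"]], tot[["R"]]))
    message(sprintf("  pooled lateralization: chi2 = %.3f, p = %.3f",
                    lt$chi2, lt$p))
  }
}
out <- do.call(rbind, tables)
utils::write.table(out, "results/regional_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/regional_summary.tsv")
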